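#' @import methods
NULL

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' One subject's image, optional label mask and grid metadata
#'
#' `ImageSample` is the unit of data flowing through a voxseg pipeline: a
#' numeric image array with spatial axes (2 or 3) plus a trailing channel
#' axis, an optional integer segmentation mask over the same spatial grid,
#' the physical voxel spacing (millimetres per voxel, per spatial axis), and
#' a record of the grid at load time (`originalShape`, `originalSpacing`) so
#' predictions can be restored to the source geometry after resampling.
#'
#' @slot id character sample identifier.
#' @slot image numeric array, spatial axes plus trailing channel axis.
#' @slot segmentation integer array over the spatial axes, labels in
#'   `[0, C)`, or `NULL` for unlabeled samples.
#' @slot spacing numeric, physical voxel size per spatial axis, all `> 0`.
#' @slot originalShape integer spatial shape at load time.
#' @slot originalSpacing numeric spacing at load time.
#' @slot meta list, open key-value store (e.g. phantom ground-truth counts).
#'
#' @seealso [imageSample()] for construction, [loadNiftiSample()],
#'   [generatePhantom()].
#' @export
setClass("ImageSample",
  representation(id = "character", image = "array",
                 segmentation = "arrayOrNULL", spacing = "numeric",
                 originalShape = "integer", originalSpacing = "numeric",
                 meta = "list"))

setValidity("ImageSample", function(object) {
  msg <- character()
  nd <- length(dim(object@image)) - 1L
  if (!nd %in% c(2L, 3L))
    msg <- c(msg, "image must have 2 or 3 spatial axes plus a channel axis")
  if (length(object@spacing) != nd)
    msg <- c(msg, "spacing must have one entry per spatial axis")
  if (any(object@spacing <= 0))
    msg <- c(msg, "all spacing entries must be > 0")
  if (!is.null(object@segmentation)) {
    if (!identical(dim(object@segmentation)[seq_len(nd)],
                   dim(object@image)[seq_len(nd)]))
      msg <- c(msg, "segmentation spatial shape must equal image spatial shape")
    if (any(object@segmentation < 0) ||
        !isWholeNumber(object@segmentation))
      msg <- c(msg, "segmentation values must be non-negative integers")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ImageSample
#'
#' @param id sample identifier.
#' @param image numeric array with 2 or 3 spatial axes; a trailing channel
#'   axis of size 1 is added when absent (`nd` disambiguates: a 3D array is
#'   by default a scalar 3D volume, not a multi-channel 2D image).
#' @param segmentation optional integer label array over the spatial axes.
#' @param spacing physical voxel size per spatial axis; default all 1.
#' @param nd number of spatial axes; inferred as `length(dim(image))` when
#'   image has no channel axis.
#' @param meta list of free-form metadata.
#' @return an [ImageSample-class] object.
#' @examples
#' img <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
#' s <- imageSample("s1", img, spacing = c(1, 1, 2.5))
#' sampleShape(s)
#' @export
imageSample <- function(id, image, segmentation = NULL, spacing = NULL,
                        nd = NULL, meta = list()) {
  if (is.null(nd)) {
    nd <- length(dim(image))
    if (nd == 4L) nd <- 3L      # already has a channel axis
  }
  image <- ensureChannelAxis(image, nd)
  if (is.null(spacing)) spacing <- rep(1, nd)
  if (!is.null(segmentation)) {
    segmentation <- array(as.integer(round(segmentation)),
                          dim(segmentation))
    if (length(dim(segmentation)) == nd + 1L &&
        dim(segmentation)[nd + 1L] == 1L)
      dim(segmentation) <- dim(segmentation)[seq_len(nd)]
  }
  shape <- dim(image)[seq_len(nd)]
  new("ImageSample", id = as.character(id), image = image,
      segmentation = segmentation, spacing = as.numeric(spacing),
      originalShape = as.integer(shape),
      originalSpacing = as.numeric(spacing), meta = meta)
}

#' @describeIn ImageSample-class sample identifier.
#' @param object,x an `ImageSample`.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @export
setMethod("sampleId", "ImageSample", function(x) x@id)

#' @describeIn ImageSample-class image array (with channel axis).
#' @export
setGeneric("sampleImage", function(x) standardGeneric("sampleImage"))
#' @export
setMethod("sampleImage", "ImageSample", function(x) x@image)

#' @describeIn ImageSample-class segmentation mask or `NULL`.
#' @export
setGeneric("sampleSegmentation",
           function(x) standardGeneric("sampleSegmentation"))
#' @export
setMethod("sampleSegmentation", "ImageSample", function(x) x@segmentation)

#' @describeIn ImageSample-class per-axis voxel spacing.
#' @export
setGeneric("sampleSpacing", function(x) standardGeneric("sampleSpacing"))
#' @export
setMethod("sampleSpacing", "ImageSample", function(x) x@spacing)

#' @describeIn ImageSample-class spatial shape (channel axis excluded).
#' @export
setGeneric("sampleShape", function(x) standardGeneric("sampleShape"))
#' @export
setMethod("sampleShape", "ImageSample",
          function(x) spatialShape(x@image))

setMethod("show", "ImageSample", function(object) {
  nd <- length(object@spacing)
  cat(sprintf("ImageSample '%s': %s voxels, spacing %s mm, %d channel(s), %s\n",
              object@id,
              paste(spatialShape(object@image), collapse = "x"),
              paste(format(object@spacing, digits = 4), collapse = "x"),
              dim(object@image)[nd + 1L],
              if (is.null(object@segmentation)) "unlabeled"
              else sprintf("labels {%s}",
                           paste(sort(unique(as.vector(object@segmentation))),
                                 collapse = ","))))
})

#' Extracted patches with their source offsets
#'
#' A `PatchSet` records patches cut from one parent volume: the 0-based
#' per-axis start offsets (half-open windows `[start, start + P)`), the
#' patch arrays themselves (channel axis carried through) and the parent's
#' spatial shape, so overlapping predictions can be merged back.
#'
#' @slot offsets integer matrix, one row per patch, 0-based start indices.
#' @slot patches list of patch arrays.
#' @slot sourceShape integer spatial shape of the parent volume.
#' @seealso [extractPatches()], [mergePatchPredictions()]
#' @export
setClass("PatchSet",
  representation(offsets = "matrix", patches = "list",
                 sourceShape = "integer"))

setValidity("PatchSet", function(object) {
  msg <- character()
  if (nrow(object@offsets) != length(object@patches))
    msg <- c(msg, "one offset row per patch required")
  if (length(object@patches)) {
    nd <- ncol(object@offsets)
    P <- dim(object@patches[[1]])[seq_len(nd)]
    ends <- sweep(object@offsets, 2, P, `+`)
    if (any(object@offsets < 0) ||
        any(sweep(ends, 2, object@sourceShape, `>`)))
      msg <- c(msg, "every window must lie inside sourceShape")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn PatchSet-class number of patches.
#' @param x,object a `PatchSet`.
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))
#' @export
setMethod("nPatches", "PatchSet", function(x) length(x@patches))

#' @describeIn PatchSet-class 0-based offset matrix.
#' @export
setGeneric("patchOffsets", function(x) standardGeneric("patchOffsets"))
#' @export
setMethod("patchOffsets", "PatchSet", function(x) x@offsets)

#' @describeIn PatchSet-class list of patch arrays.
#' @export
setGeneric("patchArrays", function(x) standardGeneric("patchArrays"))
#' @export
setMethod("patchArrays", "PatchSet", function(x) x@patches)

setMethod("show", "PatchSet", function(object) {
  P <- if (length(object@patches))
    paste(dim(object@patches[[1]])[seq_len(ncol(object@offsets))],
          collapse = "x") else "?"
  cat(sprintf("PatchSet: %d patch(es) of %s from a %s volume\n",
              length(object@patches), P,
              paste(object@sourceShape, collapse = "x")))
})
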