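#' Preprocessing specification
#'
#' Bundles the per-sample preprocessing parameters.  Subfunctions are applied
#' in a fixed order: intensity clipping, resampling to the target voxel
#' spacing, intensity normalization; label masks are one-hot encoded at the
#' model boundary.  Clipping precedes resampling so interpolation cannot
#' re-introduce out-of-range values; normalization runs last so its
#' statistics describe the analysis grid.
#'
#' @param clipRange optional numeric pair `c(lo, hi)`, image intensity
#'   units, `lo < hi`; e.g. `c(-79, 304)` for abdominal CT Hounsfield units.
#' @param normalization one of `"zscore"` (per-channel mean 0 / population
#'   sd 1), `"minmax01"`, `"minmax11"`, `"none"`.
#' @param targetSpacing optional per-axis physical voxel size to resample to.
#' @param nClasses number of segmentation classes `C >= 2`.
#' @param interpolation image interpolation scheme for resampling:
#'   `"cubic"` (Keys cubic convolution, default), `"linear"` or
#'   `"nearest"`.  Label masks are always resampled nearest-neighbour.
#' @return a `preprocSpec` list.
#' @export
preprocSpec <- function(clipRange = NULL, normalization = "zscore",
                        targetSpacing = NULL, nClasses = 2L,
                        interpolation = "cubic") {
  normalization <- match.arg(normalization,
                             c("zscore", "minmax01", "minmax11", "none"))
  interpolation <- match.arg(interpolation, c("cubic", "linear", "nearest"))
  if (!is.null(clipRange)) {
    if (length(clipRange) != 2 || clipRange[1] >= clipRange[2])
      voxsegError("validationError", "clipRange must be c(lo, hi) with lo < hi")
  }
  if (!is.null(targetSpacing) && any(targetSpacing <= 0))
    voxsegError("validationError", "targetSpacing entries must be > 0")
  if (nClasses < 2)
    voxsegError("validationError", "nClasses must be >= 2")
  structure(list(clipRange = clipRange, normalization = normalization,
                 targetSpacing = targetSpacing,
                 nClasses = as.integer(nClasses),
                 interpolation = interpolation),
            class = "preprocSpec")
}

#' Clip image intensities to a range
#'
#' Values below `lo` are set to `lo`, values above `hi` to `hi`; values
#' inside the range pass through unchanged.  Used e.g. to restrict CT scans
#' to an organ-specific Hounsfield window before normalization.
#'
#' @param image numeric array (any shape).
#' @param lo,hi clip bounds, `lo < hi`.
#' @return array of the same shape with all values in `[lo, hi]`.
#' @examples
#' clipIntensities(c(-100, 0, 500), -79, 304)   # -79 0 304
#' @export
clipIntensities <- function(image, lo, hi) {
  if (lo >= hi)
    voxsegError("validationError", "clip range requires lo < hi (got %g >= %g)",
                lo, hi)
  image[image < lo] <- lo
  image[image > hi] <- hi
  image
}

#' Normalize image intensities
#'
#' Per-channel normalization of an image carrying a trailing channel axis
#' (arrays without one are treated as a single channel).  `"zscore"` centers
#' each channel to mean 0 and population (divide-by-n) standard deviation 1;
#' a constant channel maps to all zeros.  `"minmax01"` / `"minmax11"`
#' project the observed range onto `[0, 1]` / `[-1, 1]`.
#'
#' @param image numeric array.
#' @param mode `"zscore"`, `"minmax01"`, `"minmax11"` or `"none"`.
#' @param nd number of spatial axes; defaults to treating the last axis as
#'   channels when the array has more than one dimension.
#' @return array of the same shape.
#' @export
normalizeIntensities <- function(image, mode = "zscore", nd = NULL) {
  if (!mode %in% c("zscore", "minmax01", "minmax11", "none"))
    voxsegError("configurationError", "unknown normalization mode '%s'", mode)
  if (mode == "none") return(image)
  d <- dim(image)
  if (is.null(d)) d <- length(image)
  if (is.null(nd)) nd <- max(1L, length(d) - 1L)
  nch <- if (length(d) > nd) d[nd + 1L] else 1L
  x <- matrix(as.numeric(image), ncol = nch)
  for (c in seq_len(nch)) {
    v <- x[, c]
    if (mode == "zscore") {
      mu <- mean(v)
      sd0 <- sqrt(mean((v - mu)^2))
      x[, c] <- if (sd0 == 0) 0 else (v - mu) / sd0
    } else {
      lo <- min(v); hi <- max(v)
      u <- if (hi == lo) rep(0, length(v)) else (v - lo) / (hi - lo)
      x[, c] <- if (mode == "minmax01") u else 2 * u - 1
    }
  }
  if (is.null(dim(image))) as.vector(x) else array(x, d)
}

## ---- separable grid resampling ---------------------------------------------

## Keys cubic convolution kernel, a = -0.5 (Catmull-Rom)
keysCubic <- function(s) {
  s <- abs(s)
  ifelse(s < 1, 1.5 * s^3 - 2.5 * s^2 + 1,
         ifelse(s < 2, -0.5 * s^3 + 2.5 * s^2 - 4 * s + 2, 0))
}

## nOut x nIn interpolation weight matrix for one axis.
## Output center i maps to input coordinate (i - 0.5) * nIn/nOut + 0.5
## (1-based voxel centers); borders replicate.
resampleAxisMatrix <- function(nIn, nOut, method) {
  xin <- (seq_len(nOut) - 0.5) * (nIn / nOut) + 0.5
  W <- matrix(0, nOut, nIn)
  clampIdx <- function(i) pmin(pmax(i, 1L), nIn)
  if (method == "nearest") {
    W[cbind(seq_len(nOut), clampIdx(as.integer(floor(xin + 0.5))))] <- 1
  } else if (method == "linear") {
    i0 <- floor(xin); f <- xin - i0
    for (k in 0:1) {
      w <- if (k == 0) 1 - f else f
      idx <- clampIdx(as.integer(i0 + k))
      W[cbind(seq_len(nOut), idx)] <- W[cbind(seq_len(nOut), idx)] + w
    }
  } else {  # cubic
    i0 <- floor(xin); f <- xin - i0
    for (k in -1:2) {
      w <- keysCubic(f - k)
      idx <- clampIdx(as.integer(i0 + k))
      W[cbind(seq_len(nOut), idx)] <- W[cbind(seq_len(nOut), idx)] + w
    }
  }
  W
}

## nearest-neighbour input index map for one axis
nearestIndexMap <- function(nIn, nOut) {
  xin <- (seq_len(nOut) - 0.5) * (nIn / nOut) + 0.5
  pmin(pmax(as.integer(floor(xin + 0.5)), 1L), nIn)
}

## apply a weight matrix along axis `axis` of array x
applyAlongAxis <- function(x, W, axis) {
  d <- dim(x)
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = d[axis])
  ym <- W %*% m
  y <- array(ym, c(nrow(W), d[-axis]))
  aperm(y, order(perm))
}

## resize a numeric array's spatial axes to newShape (channel axis untouched)
resizeImage <- function(image, newShape, method) {
  nd <- length(newShape)
  out <- image
  for (a in seq_len(nd)) {
    if (dim(out)[a] == newShape[a] && method != "cubic") next
    if (dim(out)[a] != newShape[a])
      out <- applyAlongAxis(out, resampleAxisMatrix(dim(out)[a], newShape[a],
                                                   method), a)
  }
  out
}

## resize an integer label array by per-axis nearest-neighbour index maps
resizeLabels <- function(seg, newShape) {
  maps <- lapply(seq_along(newShape),
                 function(a) nearestIndexMap(dim(seg)[a], newShape[a]))
  arraySubset(seg, maps)
}

#' Resample a sample to a target voxel spacing
#'
#' Training a single model across subjects requires a common voxel spacing;
#' this resizes the image (and optional label mask) so that each axis
#' covers the same physical extent at the target spacing.  The output shape
#' per axis is `round(shape * spacing / target)` (at least 1).  The image is
#' interpolated with the scheme in `method`; labels always use
#' nearest-neighbour, the only label-preserving choice.  A grid record of
#' the pre-resampling geometry is returned so predictions can be mapped back
#' (see [restoreToOriginalGrid()]).
#'
#' @param image numeric array with trailing channel axis.
#' @param segmentation optional integer label array (spatial axes only).
#' @param spacing current per-axis voxel size (> 0).
#' @param target desired per-axis voxel size (> 0).
#' @param method `"cubic"`, `"linear"` or `"nearest"` for the image.
#' @return list with elements `image`, `segmentation` (or `NULL`) and
#'   `record` (a `gridRecord` with the pre-resample shape and spacing).
#' @export
resampleToSpacing <- function(image, segmentation = NULL, spacing, target,
                              method = "cubic") {
  if (any(spacing <= 0) || any(target <= 0))
    voxsegError("validationError", "spacing and target must be > 0")
  nd <- length(spacing)
  shape <- dim(image)[seq_len(nd)]
  newShape <- pmax(1L, as.integer(round(shape * spacing / target)))
  record <- gridRecord(shape, spacing)
  out <- if (all(newShape == shape)) image else
    resizeImage(image, newShape, method)
  segOut <- NULL
  if (!is.null(segmentation)) {
    segOut <- if (all(newShape == shape)) segmentation else
      resizeLabels(segmentation, newShape)
  }
  list(image = out, segmentation = segOut, record = record)
}

#' Grid record: the voxel grid before resampling
#'
#' @param shape integer spatial shape.
#' @param spacing numeric per-axis voxel size.
#' @return a `gridRecord` list.
#' @export
gridRecord <- function(shape, spacing) {
  if (any(shape < 1) || any(spacing <= 0))
    voxsegError("validationError", "gridRecord requires positive shape/spacing")
  structure(list(preResampleShape = as.integer(shape),
                 preResampleSpacing = as.numeric(spacing)),
            class = "gridRecord")
}

#' Restore a predicted mask to the original voxel grid
#'
#' Nearest-neighbour resize of an integer mask back to the grid recorded
#' before resampling, so the prediction has the identical shape as the
#' original image.
#'
#' @param mask integer label array (spatial axes only).
#' @param record a `gridRecord` from [resampleToSpacing()].
#' @return integer array of shape `record$preResampleShape`.
#' @export
restoreToOriginalGrid <- function(mask, record) {
  stopifnot(inherits(record, "gridRecord"))
  if (identical(dim(mask), record$preResampleShape)) return(mask)
  resizeLabels(mask, record$preResampleShape)
}

#' One-hot encode a label mask
#'
#' Expands an integer mask with labels in `[0, C)` into a binary array with
#' a trailing class axis; exactly one 1 per voxel across that axis.  Binary
#' problems are encoded the same way so every loss sees a uniform class
#' axis.
#'
#' @param segmentation integer array, labels in `[0, C)`.
#' @param nClasses class count `C >= 2`.
#' @return binary array of shape `c(dim(segmentation), nClasses)`.
#' @export
oneHotEncode <- function(segmentation, nClasses) {
  shape <- dim(segmentation)
  if (is.null(shape)) shape <- length(segmentation)
  v <- as.integer(segmentation)
  if (any(v < 0) || any(v >= nClasses))
    voxsegError("validationError",
                "labels must lie in [0, %d); found range [%d, %d]",
                nClasses, min(v), max(v))
  oh <- matrix(0, length(v), nClasses)
  oh[cbind(seq_along(v), v + 1L)] <- 1
  array(oh, c(shape, nClasses))
}

#' Decode per-class probabilities to a label mask
#'
#' Per-voxel argmax along the trailing class axis; ties break toward the
#' lowest class index.
#'
#' @param probabilities numeric array, trailing class axis of size `>= 2`.
#' @return integer label array over the spatial axes, labels 0-based.
#' @export
oneHotDecode <- function(probabilities) {
  d <- dim(probabilities)
  C <- d[length(d)]
  if (is.null(C) || C < 2)
    voxsegError("validationError", "class axis must have size >= 2")
  m <- matrix(probabilities, ncol = C)
  lab <- max.col(m, ties.method = "first") - 1L
  array(as.integer(lab), d[-length(d)])
}

#' Run the preprocessing chain on one sample
#'
#' Applies, in order: intensity clipping (when `clipRange` is set),
#' resampling to `targetSpacing` (when set), and intensity normalization.
#' The grid record of the pre-resampling geometry is stored in
#' `meta$gridRecord` of the returned sample.
#'
#' @param sample an [ImageSample-class].
#' @param spec a [preprocSpec()].
#' @return the preprocessed `ImageSample`.
#' @export
preprocessSample <- function(sample, spec) {
  stopifnot(is(sample, "ImageSample"), inherits(spec, "preprocSpec"))
  img <- sample@image
  seg <- sample@segmentation
  spacing <- sample@spacing
  if (!is.null(spec$clipRange))
    img <- clipIntensities(img, spec$clipRange[1], spec$clipRange[2])
  record <- gridRecord(spatialShape(img), spacing)
  if (!is.null(spec$targetSpacing)) {
    res <- resampleToSpacing(img, seg, spacing, spec$targetSpacing,
                             method = spec$interpolation)
    img <- res$image; seg <- res$segmentation
    record <- res$record
    spacing <- as.numeric(spec$targetSpacing)
  }
  img <- normalizeIntensities(img, spec$normalization)
  out <- sample
  out@image <- img
  out@segmentation <- seg
  out@spacing <- spacing
  out@meta$gridRecord <- record
  validObject(out)
  out
}
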