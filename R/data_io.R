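#' Load a NIfTI image (and optional segmentation) as an ImageSample
#'
#' Reads a NIfTI-1 file (`.nii` or `.nii.gz`; compression is transparent)
#' into the pipeline's uniform sample representation: the image gets an
#' explicit trailing channel axis (size 1 for scalar volumes) and the voxel
#' spacing is taken from the header voxel-dimension fields (`pixdim`) —
#' this is where slice-thickness metadata lives.  The affine's rotation
#' component is deliberately ignored: arrays are processed in stored voxel
#' order and only the per-axis zooms are consumed.
#'
#' @param path path to the image file.
#' @param segmentationPath optional path to an integer label mask over the
#'   same grid.
#' @param id sample identifier; defaults to the file's base name.
#' @return an [ImageSample-class] with `originalShape`/`originalSpacing`
#'   recorded for later grid restoration.
#' @export
loadNiftiSample <- function(path, segmentationPath = NULL, id = NULL) {
  img <- readNiftiChecked(path)
  spacing <- as.numeric(RNifti::pixdim(img))
  arr <- array(as.numeric(img), dim(img))
  nd <- length(dim(arr))
  if (!nd %in% c(2L, 3L))
    voxsegError("formatError",
                "expected a 2D or 3D image, got %d axes in '%s'", nd, path)
  seg <- NULL
  if (!is.null(segmentationPath)) {
    segImg <- readNiftiChecked(segmentationPath)
    seg <- array(as.integer(round(as.numeric(segImg))), dim(segImg))
    if (!identical(dim(seg), dim(arr)))
      voxsegError("validationError",
                  "segmentation shape (%s) does not match image shape (%s)",
                  paste(dim(seg), collapse = "x"),
                  paste(dim(arr), collapse = "x"))
  }
  if (is.null(id))
    id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  imageSample(id, arr, segmentation = seg,
              spacing = spacing[seq_len(nd)], nd = nd)
}

readNiftiChecked <- function(path) {
  if (!file.exists(path))
    voxsegError("ioError", "file not found: '%s'", path)
  tryCatch(suppressWarnings(RNifti::readNifti(path)),
           error = function(e)
             voxsegError("formatError", "'%s' is not a readable NIfTI file: %s",
                         path, conditionMessage(e)))
}

#' Save a predicted segmentation mask as NIfTI
#'
#' Writes an integer label mask with the sample's original voxel spacing in
#' the header zooms and no further metadata; an identity orientation is
#' used (only the zooms are meaningful, matching what the loader consumes).
#' The on-disk datatype is integer; probability maps are never written by
#' this operation.
#'
#' @param mask integer label array; spatial shape must equal the sample's
#'   `originalShape`.
#' @param sample the source [ImageSample-class] (provides the grid record).
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
saveNiftiSegmentation <- function(mask, sample, path) {
  stopifnot(is(sample, "ImageSample"))
  if (!identical(as.integer(dim(mask)), sample@originalShape))
    voxsegError("validationError",
                "mask shape (%s) does not match the sample's original shape (%s)",
                paste(dim(mask), collapse = "x"),
                paste(sample@originalShape, collapse = "x"))
  img <- RNifti::asNifti(array(as.integer(round(mask)), dim(mask)))
  RNifti::pixdim(img) <- sample@originalSpacing
  RNifti::writeNifti(img, path, datatype = "int32")
  invisible(path)
}

## ---- data interface contract ----------------------------------------------

#' Create a directory-layout NIfTI data interface
#'
#' The bundled dataset convention is one directory per sample id under a
#' common root, each containing the image file and (optionally) the label
#' file:
#' \preformatted{<root>/<sample_id>/imaging.nii.gz
#' <root>/<sample_id>/segmentation.nii.gz}
#' File names are configurable.  The returned object satisfies the data
#' interface contract: `listSamples()` (ordered identifiers), `load(id,
#' withSegmentation)` returning an [ImageSample-class], and
#' `savePrediction(id, mask, sample, dir)` writing a NIfTI mask.
#'
#' @param root dataset root directory.
#' @param imageFile,segmentationFile file names inside each sample
#'   directory.
#' @return a `dataInterface` list.
#' @export
niftiInterface <- function(root, imageFile = "imaging.nii.gz",
                           segmentationFile = "segmentation.nii.gz") {
  force(root); force(imageFile); force(segmentationFile)
  structure(list(
    listSamples = function() {
      dirs <- list.dirs(root, recursive = FALSE, full.names = FALSE)
      sort(dirs[file.exists(file.path(root, dirs, imageFile))])
    },
    load = function(id, withSegmentation = TRUE) {
      ip <- file.path(root, id, imageFile)
      sp <- file.path(root, id, segmentationFile)
      loadNiftiSample(ip,
                      segmentationPath =
                        if (withSegmentation && file.exists(sp)) sp else NULL,
                      id = id)
    },
    savePrediction = function(id, mask, sample, dir) {
      dir.create(file.path(dir, id), recursive = TRUE, showWarnings = FALSE)
      saveNiftiSegmentation(mask, sample,
                            file.path(dir, id, "prediction.nii.gz"))
    }),
    class = "dataInterface")
}

validateDataInterface <- function(interface) {
  need <- c("listSamples", "load", "savePrediction")
  miss <- need[!vapply(need, function(m)
    is.function(interface[[m]]), logical(1))]
  if (length(miss))
    voxsegError("validationError",
                "data interface is missing contract method(s): %s",
                paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Register a data interface under a name
#'
#' Custom imaging formats plug into the pipeline by registering an object
#' with the three contract methods (`listSamples`, `load`,
#' `savePrediction`); the pipeline configuration then resolves it by name.
#'
#' @param name interface name (e.g. `"nifti"`).
#' @param interface a `dataInterface`-like list.
#' @param overwrite replace an existing entry instead of erroring.
#' @return the name, invisibly.
#' @export
registerDataInterface <- function(name, interface, overwrite = FALSE) {
  if (!overwrite &&
      exists(name, envir = .voxseg$interfaces, inherits = FALSE))
    voxsegError("configurationError",
                "data interface '%s' is already registered", name)
  validateDataInterface(interface)
  assign(name, interface, envir = .voxseg$interfaces)
  invisible(name)
}

#' Resolve a registered data interface by name
#' @param name interface name.
#' @return the interface object.
#' @export
resolveDataInterface <- function(name) {
  if (!exists(name, envir = .voxseg$interfaces, inherits = FALSE))
    voxsegError("configurationError",
                "no data interface registered under '%s'", name)
  get(name, envir = .voxseg$interfaces)
}

#' Names of all registered data interfaces
#' @return character vector.
#' @export
listDataInterfaces <- function() sort(ls(.voxseg$interfaces))
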