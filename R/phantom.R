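#' Synthetic labeled phantom configuration
#'
#' Desk-scale stand-in for abdominal CT segmentation data: a dominant
#' background, an "organ" ellipsoid (class 1) at a random interior
#' position, and — for three-class problems — a smaller "lesion" ellipsoid
#' (class 2) placed fully inside the organ, mirroring a
#' background/kidney/tumor class structure.  Voxel intensities are the
#' class means plus white Gaussian noise, so the noiseless phantom is
#' exactly threshold-separable and bounds what a trained model can reach.
#'
#' Defaults (32 cubed voxels, class means 0 / 0.5 / 1.0, noise sd 0.05,
#' organ semi-axes 6-10 voxels, lesion 2-4) are chosen so a tiny U-Net
#' separates the classes in minutes on one CPU.
#'
#' @param shape integer spatial shape (2 or 3 axes).
#' @param nClasses 2 (background + organ) or 3 (+ lesion).
#' @param intensityMeans strictly increasing per-class means.
#' @param noiseSd Gaussian noise standard deviation, `>= 0`.
#' @param organSemiAxes range (voxels) of the organ ellipsoid semi-axes.
#' @param lesionSemiAxes range (voxels) of the lesion semi-axes (smaller).
#' @param spacing per-axis voxel size.
#' @return a `phantomConfig` list.
#' @export
phantomConfig <- function(shape = c(32L, 32L, 32L), nClasses = 3L,
                          intensityMeans = c(0, 0.5, 1.0), noiseSd = 0.05,
                          organSemiAxes = c(6, 10), lesionSemiAxes = c(2, 4),
                          spacing = NULL) {
  shape <- as.integer(shape)
  if (!nClasses %in% c(2L, 3L))
    voxsegError("validationError", "phantom supports 2 or 3 classes")
  mu <- intensityMeans[seq_len(nClasses)]
  if (any(diff(mu) <= 0))
    voxsegError("validationError", "class means must be strictly increasing")
  if (noiseSd < 0)
    voxsegError("validationError", "noiseSd must be >= 0")
  if (max(organSemiAxes) * 2 + 2 > min(shape))
    voxsegError("validationError", "organ semi-axes do not fit inside shape")
  if (is.null(spacing)) spacing <- rep(1, length(shape))
  structure(list(shape = shape, nClasses = as.integer(nClasses),
                 intensityMeans = mu, noiseSd = noiseSd,
                 organSemiAxes = organSemiAxes,
                 lesionSemiAxes = lesionSemiAxes,
                 spacing = as.numeric(spacing)),
            class = "phantomConfig")
}

## boolean ellipsoid mask over a voxel grid
ellipsoidMask <- function(shape, center, semiAxes) {
  co <- coordGrid(shape)
  q <- rep(0, nrow(co))
  for (a in seq_along(shape))
    q <- q + ((co[, a] - center[a]) / semiAxes[a])^2
  array(q <= 1, shape)
}

#' Generate one labeled phantom
#'
#' Paints the organ ellipsoid, then (for 3 classes) rejection-samples a
#' lesion center until the lesion ellipsoid lies fully inside the organ
#' (up to 100 tries).  The image is the per-class intensity mean plus
#' Gaussian noise; exact per-class voxel counts are stored in
#' `meta$classCounts`.
#'
#' @param config a [phantomConfig()].
#' @param seed optional integer; fixed seeds reproduce the phantom exactly.
#' @param id sample identifier.
#' @return an [ImageSample-class] with ground-truth segmentation.
#' @export
generatePhantom <- function(config = phantomConfig(), seed = NULL,
                            id = "phantom") {
  stopifnot(inherits(config, "phantomConfig"))
  shape <- config$shape
  nd <- length(shape)
  withSeed(seed, {
    ax <- stats::runif(nd, config$organSemiAxes[1], config$organSemiAxes[2])
    ctr <- vapply(seq_len(nd), function(a)
      stats::runif(1, ax[a] + 1, shape[a] - ax[a]), numeric(1))
    organ <- ellipsoidMask(shape, ctr, ax)
    mask <- array(0L, shape)
    mask[organ] <- 1L
    if (config$nClasses == 3L) {
      placed <- FALSE
      for (try in seq_len(100)) {
        lax <- stats::runif(nd, config$lesionSemiAxes[1],
                            config$lesionSemiAxes[2])
        lctr <- ctr + stats::runif(nd, -1, 1) * (ax - lax) * 0.6
        lesion <- ellipsoidMask(shape, lctr, lax)
        if (any(lesion) && all(organ[lesion])) { placed <- TRUE; break }
      }
      if (!placed)
        voxsegError("generationError",
                    "could not place the lesion inside the organ")
      mask[lesion] <- 2L
    }
    img <- config$intensityMeans[mask + 1L]
    if (config$noiseSd > 0)
      img <- img + stats::rnorm(length(img), 0, config$noiseSd)
    img <- array(img, c(shape, 1L))
    counts <- tabulate(mask + 1L, nbins = config$nClasses)
    geom <- list(organ = list(center = ctr, semiAxes = ax))
    if (config$nClasses == 3L)
      geom$lesion <- list(center = lctr, semiAxes = lax)
    imageSample(id, img, segmentation = mask, spacing = config$spacing,
                nd = nd, meta = list(classCounts = counts,
                                     geometry = geom))
  })
}

#' Write a phantom dataset in the on-disk NIfTI layout
#'
#' Generates `n` independent phantoms and writes them through the NIfTI
#' layout of [niftiInterface()] (`<root>/<id>/imaging.nii.gz` +
#' `segmentation.nii.gz`), so they load through the pipeline with no
#' special casing.  A tab-separated manifest of ground-truth class counts
#' is written alongside.
#'
#' @param root output directory (created if needed).
#' @param n number of phantoms.
#' @param config a [phantomConfig()] template.
#' @param seed integer master seed; per-sample seeds are derived from it.
#' @return the manifest data.frame (sample_id, class, count), invisibly.
#' @export
generatePhantomDataset <- function(root, n, config = phantomConfig(),
                                   seed = 1L) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(n)) {
    id <- sprintf("phantom_%03d", i)
    s <- generatePhantom(config, seed = deriveSeed(seed, i), id = id)
    dir.create(file.path(root, id), showWarnings = FALSE)
    img <- RNifti::asNifti(array(s@image, sampleShape(s)))
    RNifti::pixdim(img) <- s@spacing
    RNifti::writeNifti(img, file.path(root, id, "imaging.nii.gz"))
    seg <- RNifti::asNifti(s@segmentation)
    RNifti::pixdim(seg) <- s@spacing
    RNifti::writeNifti(seg, file.path(root, id, "segmentation.nii.gz"),
                       datatype = "int32")
    rows[[i]] <- data.frame(sample_id = id,
                            class = seq_len(config$nClasses) - 1L,
                            count = s@meta$classCounts)
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(root, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
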