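#' Patch analysis configuration
#'
#' Controls how a volume is decomposed for model analysis: full image,
#' deterministic overlapping grid, or random crops at training time.  The
#' per-axis stride is `S = P - O` and must be at least 1.
#'
#' @param patchShape integer per-axis patch size `P`.
#' @param overlap integer per-axis overlap `O`, `0 <= O < P`; at prediction
#'   time overlapping windows are mean-merged, which counters the weaker
#'   prediction quality at patch edges.
#' @param analysis `"patchwise-grid"`, `"patchwise-crop"` or `"fullimage"`.
#' @param skipBlanks drop training patches whose label window is entirely
#'   background (grid mode).
#' @param cropsPerSample random crops drawn per sample per epoch (crop mode).
#' @return a `patchConfig` list.
#' @export
patchConfig <- function(patchShape, overlap = NULL,
                        analysis = "patchwise-grid", skipBlanks = TRUE,
                        cropsPerSample = 1L) {
  analysis <- match.arg(analysis,
                        c("patchwise-grid", "patchwise-crop", "fullimage"))
  patchShape <- as.integer(patchShape)
  if (is.null(overlap)) overlap <- rep(0L, length(patchShape))
  overlap <- as.integer(overlap)
  if (length(overlap) != length(patchShape))
    voxsegError("validationError", "overlap and patchShape lengths differ")
  if (any(overlap < 0) || any(overlap >= patchShape))
    voxsegError("validationError",
                "overlap must satisfy 0 <= O[a] < P[a] on every axis")
  structure(list(patchShape = patchShape, overlap = overlap,
                 analysis = analysis, skipBlanks = isTRUE(skipBlanks),
                 cropsPerSample = as.integer(cropsPerSample)),
            class = "patchConfig")
}

#' Compute the deterministic patch grid
#'
#' Per axis, window start offsets run `0, S, 2S, ...` with stride
#' `S = P - O`; if the last regular window does not reach the boundary, a
#' final edge-aligned offset `shape - P` is added so every voxel is covered
#' without padding.  Offsets are the full Cartesian product across axes in
#' lexicographic order (first axis slowest), 0-based.
#'
#' @param shape integer spatial shape of the volume.
#' @param patchShape integer per-axis patch size `P`, `P[a] <= shape[a]`.
#' @param overlap integer per-axis overlap `O`, `0 <= O[a] < P[a]`.
#' @return integer matrix of 0-based offsets, one row per window.
#' @examples
#' computePatchGrid(c(8, 8), c(4, 4), c(2, 2))  # 9 windows, stride 2
#' @export
computePatchGrid <- function(shape, patchShape, overlap = NULL) {
  shape <- as.integer(shape)
  P <- as.integer(patchShape)
  if (is.null(overlap)) overlap <- rep(0L, length(P))
  O <- as.integer(overlap)
  if (any(O < 0) || any(O >= P))
    voxsegError("validationError", "overlap must satisfy 0 <= O[a] < P[a]")
  if (any(P > shape))
    voxsegError("patchTooLargeError",
                "patch shape (%s) exceeds volume shape (%s); pad the volume or use fullimage analysis",
                paste(P, collapse = "x"), paste(shape, collapse = "x"))
  S <- P - O
  axisOffsets <- lapply(seq_along(shape), function(a) {
    off <- seq.int(0L, shape[a] - P[a], by = S[a])
    if (off[length(off)] + P[a] < shape[a])
      off <- c(off, shape[a] - P[a])
    unique(off)
  })
  ## expand.grid varies the first factor fastest; reverse for lexicographic
  g <- do.call(expand.grid, rev(axisOffsets))
  g <- as.matrix(g[, rev(seq_along(shape)), drop = FALSE])
  dimnames(g) <- NULL
  storage.mode(g) <- "integer"
  g
}

#' Extract patches at given offsets
#'
#' Cuts voxel-exact copies of the half-open windows `[offset, offset + P)`
#' from an array; a trailing channel axis is carried through when present.
#'
#' @param image numeric or integer array, spatial axes (+ optional channel
#'   axis).
#' @param offsets 0-based offset matrix from [computePatchGrid()].
#' @param patchShape integer per-axis patch size.
#' @return a [PatchSet-class].
#' @export
extractPatches <- function(image, offsets, patchShape) {
  P <- as.integer(patchShape)
  nd <- length(P)
  d <- dim(image)
  shape <- d[seq_len(nd)]
  hasChannel <- length(d) > nd
  ends <- sweep(offsets, 2, P, `+`)
  if (any(offsets < 0) || any(sweep(ends, 2, shape, `>`)))
    voxsegError("validationError", "window outside the volume")
  patches <- lapply(seq_len(nrow(offsets)), function(i) {
    idx <- lapply(seq_len(nd),
                  function(a) seq.int(offsets[i, a] + 1L, offsets[i, a] + P[a]))
    if (hasChannel) idx <- c(idx, list(seq_len(d[nd + 1L])))
    arraySubset(image, idx)
  })
  new("PatchSet", offsets = offsets, patches = patches,
      sourceShape = as.integer(shape))
}

#' Drop patches whose label window is pure background
#'
#' Heavily unbalanced medical volumes produce many windows labeled entirely
#' as background; these carry no training signal and are excluded.  Image
#' and segmentation patch sets must be aligned (same offsets); alignment is
#' preserved in the output.
#'
#' @param imageSet,segSet aligned [PatchSet-class] objects.
#' @param backgroundClass background label, default 0.
#' @return list with filtered `image` and `segmentation` patch sets and the
#'   integer vector `kept` of retained indices.
#' @export
filterBlankPatches <- function(imageSet, segSet, backgroundClass = 0L) {
  if (!identical(imageSet@offsets, segSet@offsets))
    voxsegError("validationError",
                "image and segmentation patch sets are not aligned")
  keep <- vapply(segSet@patches,
                 function(p) any(p != backgroundClass), logical(1))
  kept <- which(keep)
  list(image = new("PatchSet", offsets = imageSet@offsets[kept, , drop = FALSE],
                   patches = imageSet@patches[kept],
                   sourceShape = imageSet@sourceShape),
       segmentation = new("PatchSet",
                          offsets = segSet@offsets[kept, , drop = FALSE],
                          patches = segSet@patches[kept],
                          sourceShape = segSet@sourceShape),
       kept = kept)
}

#' Random crop of an image/label pair
#'
#' Draws a uniformly random valid window offset and cuts the same window
#' from image and segmentation.  Used as the training-time patch source in
#' `"patchwise-crop"` analysis, which doubles as an implicit translation
#' augmentation.
#'
#' @param image numeric array with trailing channel axis.
#' @param segmentation integer label array over the spatial axes.
#' @param patchShape integer per-axis patch size.
#' @param seed optional integer; when given, the crop is drawn from a local
#'   RNG stream seeded with it (the caller's RNG state is untouched).
#' @return list with `image`, `segmentation` and the 0-based `offset`.
#' @export
randomCrop <- function(image, segmentation, patchShape, seed = NULL) {
  P <- as.integer(patchShape)
  nd <- length(P)
  shape <- dim(image)[seq_len(nd)]
  if (any(P > shape))
    voxsegError("patchTooLargeError", "crop shape exceeds volume shape")
  off <- withSeed(seed, {
    vapply(seq_len(nd),
           function(a) sample.int(shape[a] - P[a] + 1L, 1L) - 1L, integer(1))
  })
  idx <- lapply(seq_len(nd), function(a) seq.int(off[a] + 1L, off[a] + P[a]))
  imgIdx <- c(idx, list(seq_len(dim(image)[nd + 1L])))
  list(image = arraySubset(image, imgIdx),
       segmentation = arraySubset(segmentation, idx),
       offset = off)
}

#' Merge overlapping per-class probability patches
#'
#' Reassembles patch-level class probabilities into a full volume: each
#' voxel's class-c value is the arithmetic mean over all windows containing
#' that voxel (sum and count accumulators in double precision, so the result
#' is invariant to patch order).  Every voxel must be covered by at least
#' one window.
#'
#' @param probSet a [PatchSet-class] of probability patches with trailing
#'   class axis.
#' @param sourceShape integer spatial shape of the parent volume.
#' @param nClasses class count `C`.
#' @return numeric array of shape `c(sourceShape, nClasses)`.
#' @export
mergePatchPredictions <- function(probSet, sourceShape, nClasses) {
  shape <- as.integer(sourceShape)
  nd <- length(shape)
  acc <- array(0, c(shape, nClasses))
  cnt <- array(0, shape)
  offsets <- probSet@offsets
  for (i in seq_len(length(probSet@patches))) {
    p <- probSet@patches[[i]]
    P <- spatialShape(p)
    idx <- lapply(seq_len(nd),
                  function(a) seq.int(offsets[i, a] + 1L, offsets[i, a] + P[a]))
    accIdx <- c(idx, list(seq_len(nClasses)))
    acc <- arrayAssign(acc, accIdx, arraySubset(acc, accIdx) + p)
    cnt <- arrayAssign(cnt, idx, arraySubset(cnt, idx) + 1)
  }
  if (any(cnt == 0))
    voxsegError("coverageError",
                "%d voxel(s) not covered by any window", sum(cnt == 0))
  ## class axis is last, so the count array recycles across classes
  array(as.vector(acc) / as.vector(cnt), c(shape, nClasses))
}
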