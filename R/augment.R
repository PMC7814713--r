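#' Data augmentation specification
#'
#' Training-time stochastic transforms that expand a small medical data set
#' with plausible variants.  Spatial operators (mirror, rotation, scaling,
#' elastic deformation) move image and label mask through the same
#' geometric map — image linearly interpolated, labels nearest-neighbour;
#' intensity operators (brightness, contrast, gamma, Gaussian noise) touch
#' the image only.  Each operator fires independently with its probability.
#' Translations are realized implicitly by random cropping in
#' `"patchwise-crop"` analysis rather than as a resampling operator.
#'
#' Default ranges are conservative; all are configurable.
#'
#' @param pMirror,pRotate,pScale,pElastic,pBrightness,pContrast,pGamma,pNoise
#'   per-operator firing probabilities in `[0, 1]` (0 disables).
#' @param rotationRange rotation angle range in degrees (in-plane).
#' @param scaleRange multiplicative zoom factor range, `> 0`.
#' @param elasticAmplitude maximum displacement after smoothing, voxels.
#' @param elasticSigma Gaussian smoothing width of the displacement field,
#'   voxels.
#' @param brightnessRange additive offset range as a fraction of the image
#'   intensity standard deviation.
#' @param contrastRange contrast factor range (scaling about the mean),
#'   `> 0`.
#' @param gammaRange gamma exponent range, `> 0`.
#' @param noiseSdRange Gaussian noise standard deviation range, `>= 0`.
#' @return an `augmentSpec` list.
#' @export
augmentSpec <- function(pMirror = 0.15, pRotate = 0.15, pScale = 0.15,
                        pElastic = 0.15, pBrightness = 0.15,
                        pContrast = 0.15, pGamma = 0.15, pNoise = 0.15,
                        rotationRange = c(-15, 15),
                        scaleRange = c(0.85, 1.15),
                        elasticAmplitude = 2, elasticSigma = 8,
                        brightnessRange = c(-0.1, 0.1),
                        contrastRange = c(0.75, 1.25),
                        gammaRange = c(0.7, 1.5),
                        noiseSdRange = c(0, 0.05)) {
  probs <- c(pMirror, pRotate, pScale, pElastic, pBrightness, pContrast,
             pGamma, pNoise)
  if (any(probs < 0) || any(probs > 1))
    voxsegError("configurationError", "probabilities must lie in [0, 1]")
  ordered <- function(r) length(r) == 2 && r[1] <= r[2]
  if (!ordered(rotationRange) || !ordered(scaleRange) ||
      !ordered(brightnessRange) || !ordered(contrastRange) ||
      !ordered(gammaRange) || !ordered(noiseSdRange))
    voxsegError("configurationError", "all ranges must be ordered (lo <= hi)")
  if (scaleRange[1] <= 0 || gammaRange[1] <= 0 || contrastRange[1] <= 0)
    voxsegError("configurationError",
                "scale, gamma and contrast ranges must be strictly positive")
  if (noiseSdRange[1] < 0 || elasticAmplitude < 0 || elasticSigma <= 0)
    voxsegError("configurationError", "invalid elastic/noise parameters")
  structure(list(pMirror = pMirror, pRotate = pRotate, pScale = pScale,
                 pElastic = pElastic, pBrightness = pBrightness,
                 pContrast = pContrast, pGamma = pGamma, pNoise = pNoise,
                 rotationRange = rotationRange, scaleRange = scaleRange,
                 elasticAmplitude = elasticAmplitude,
                 elasticSigma = elasticSigma,
                 brightnessRange = brightnessRange,
                 contrastRange = contrastRange, gammaRange = gammaRange,
                 noiseSdRange = noiseSdRange),
            class = "augmentSpec")
}

#' All-off augmentation spec (identity)
#' @return an `augmentSpec` with every probability 0.
#' @export
augmentSpecOff <- function() {
  augmentSpec(pMirror = 0, pRotate = 0, pScale = 0, pElastic = 0,
              pBrightness = 0, pContrast = 0, pGamma = 0, pNoise = 0)
}

## ---- geometric resampling machinery ---------------------------------------

## (nvox x nd) matrix of 1-based voxel-center coordinates in array order
coordGrid <- function(shape) {
  nd <- length(shape)
  out <- matrix(0, prod(shape), nd)
  rep1 <- 1L
  for (a in seq_len(nd)) {
    out[, a] <- rep(rep(seq_len(shape[a]), each = rep1),
                    length.out = prod(shape))
    rep1 <- rep1 * shape[a]
  }
  out
}

## sample a single-channel volume at fractional coordinates
## method "linear": multilinear with edge clamping; "nearest": rounded index
interpAt <- function(vol, coords, method = "linear") {
  shape <- dim(vol)
  nd <- length(shape)
  for (a in seq_len(nd))
    coords[, a] <- pmin(pmax(coords[, a], 1), shape[a])
  if (method == "nearest") {
    idx <- matrix(0L, nrow(coords), nd)
    for (a in seq_len(nd))
      idx[, a] <- pmin(pmax(as.integer(floor(coords[, a] + 0.5)), 1L),
                       shape[a])
    lin <- idx[, 1]
    mult <- 1
    for (a in seq_len(nd)[-1]) {
      mult <- mult * shape[a - 1]
      lin <- lin + (idx[, a] - 1L) * mult
    }
    return(vol[lin])
  }
  i0 <- matrix(0L, nrow(coords), nd)
  fr <- matrix(0, nrow(coords), nd)
  for (a in seq_len(nd)) {
    i0[, a] <- pmin(pmax(as.integer(floor(coords[, a])), 1L),
                    max(shape[a] - 1L, 1L))
    fr[, a] <- coords[, a] - i0[, a]
    if (shape[a] == 1L) fr[, a] <- 0
  }
  acc <- numeric(nrow(coords))
  corners <- as.matrix(do.call(expand.grid,
                               rep(list(0:1), nd)))
  for (k in seq_len(nrow(corners))) {
    w <- rep(1, nrow(coords))
    lin <- numeric(nrow(coords))
    mult <- 1
    for (a in seq_len(nd)) {
      da <- corners[k, a]
      ia <- pmin(i0[, a] + da, shape[a])
      w <- w * (if (da == 0) 1 - fr[, a] else fr[, a])
      lin <- lin + (ia - 1) * mult
      mult <- mult * shape[a]
    }
    acc <- acc + w * vol[lin + 1]
  }
  acc
}

## warp an image (channel axis) + label pair through an inverse coordinate
## map: srcCoords gives, for every output voxel, the source location
warpPair <- function(image, segmentation, srcCoords) {
  nd <- ncol(srcCoords)
  shape <- dim(image)[seq_len(nd)]
  nch <- dim(image)[nd + 1L]
  out <- image
  for (c in seq_len(nch)) {
    vol <- arraySubset(image, c(lapply(shape, seq_len), list(c)))
    dim(vol) <- shape
    out <- arrayAssign(out, c(lapply(shape, seq_len), list(c)),
                       interpAt(vol, srcCoords, "linear"))
  }
  segOut <- segmentation
  if (!is.null(segmentation)) {
    segOut <- array(as.integer(interpAt(segmentation, srcCoords, "nearest")),
                    shape)
  }
  list(image = out, segmentation = segOut)
}

## ---- spatial operators -----------------------------------------------------

#' Mirror (flip) image and labels along axes
#' @param image numeric array with trailing channel axis.
#' @param segmentation optional integer label array.
#' @param axes integer vector of spatial axes to reverse.
#' @return list with `image` and `segmentation`.
#' @export
opMirror <- function(image, segmentation = NULL, axes) {
  nd <- length(dim(image)) - 1L
  idx <- lapply(seq_len(nd), function(a)
    if (a %in% axes) rev(seq_len(dim(image)[a])) else seq_len(dim(image)[a]))
  img <- arraySubset(image, c(idx, list(seq_len(dim(image)[nd + 1L]))))
  seg <- if (is.null(segmentation)) NULL else arraySubset(segmentation, idx)
  list(image = img, segmentation = seg)
}

#' Rotate image and labels in a coordinate plane
#'
#' Resamples through the inverse rotation about the volume center; voxels
#' falling outside the source grid take the clamped edge value.
#'
#' @inheritParams opMirror
#' @param angle rotation angle in degrees (counter-clockwise in the plane).
#' @param plane integer pair of spatial axes spanning the rotation plane.
#' @export
opRotate <- function(image, segmentation = NULL, angle, plane = c(1, 2)) {
  nd <- length(dim(image)) - 1L
  shape <- dim(image)[seq_len(nd)]
  ctr <- (shape + 1) / 2
  th <- angle * pi / 180
  co <- coordGrid(shape)
  u <- co[, plane[1]] - ctr[plane[1]]
  v <- co[, plane[2]] - ctr[plane[2]]
  ## inverse map: rotate output coords by -angle
  co[, plane[1]] <- cos(th) * u + sin(th) * v + ctr[plane[1]]
  co[, plane[2]] <- -sin(th) * u + cos(th) * v + ctr[plane[2]]
  warpPair(image, segmentation, co)
}

#' Scale (zoom) image and labels about the volume center
#' @inheritParams opMirror
#' @param factor zoom factor `> 0`; factors `> 1` magnify.
#' @export
opScale <- function(image, segmentation = NULL, factor) {
  if (factor <= 0)
    voxsegError("validationError", "scale factor must be > 0")
  nd <- length(dim(image)) - 1L
  shape <- dim(image)[seq_len(nd)]
  ctr <- (shape + 1) / 2
  co <- coordGrid(shape)
  for (a in seq_len(nd))
    co[, a] <- (co[, a] - ctr[a]) / factor + ctr[a]
  warpPair(image, segmentation, co)
}

#' Elastic deformation of image and labels
#'
#' Displaces every output voxel by a smooth random field:
#' `source = voxel + displacement`.  The classic construction draws white
#' Gaussian noise per axis, smooths it with a Gaussian kernel and scales
#' the amplitude (see [makeDisplacementField()]).
#'
#' @inheritParams opMirror
#' @param displacementField numeric array `c(spatial shape, nd)` of
#'   per-axis displacements in voxels.
#' @export
opElastic <- function(image, segmentation = NULL, displacementField) {
  nd <- length(dim(image)) - 1L
  shape <- dim(image)[seq_len(nd)]
  if (!identical(as.integer(dim(displacementField)),
                 as.integer(c(shape, nd))))
    voxsegError("validationError", "displacement field shape mismatch")
  co <- coordGrid(shape)
  D <- matrix(displacementField, ncol = nd)
  warpPair(image, segmentation, co + D)
}

#' Smoothed random displacement field for elastic deformation
#' @param shape integer spatial shape.
#' @param amplitude maximum absolute displacement (voxels) after smoothing.
#' @param sigma Gaussian smoothing width (voxels).
#' @return array `c(shape, length(shape))`.
#' @export
makeDisplacementField <- function(shape, amplitude, sigma) {
  nd <- length(shape)
  out <- array(0, c(shape, nd))
  smoothers <- lapply(shape, function(n) {
    W <- outer(seq_len(n), seq_len(n),
               function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
    W / rowSums(W)
  })
  for (a in seq_len(nd)) {
    f <- array(stats::rnorm(prod(shape)), shape)
    for (ax in seq_len(nd))
      f <- applyAlongAxis(f, smoothers[[ax]], ax)
    m <- max(abs(f))
    if (m > 0) f <- f / m * amplitude
    out <- arrayAssign(out, c(lapply(shape, seq_len), list(a)), f)
  }
  out
}

## ---- intensity operators ---------------------------------------------------

#' Intensity operators: brightness, contrast, gamma, noise
#'
#' `opBrightness` adds a constant offset; `opContrast` scales intensities
#' about the image mean (the mean is preserved); `opGamma` maps min-max
#' normalized intensities through `x^exponent` and restores the original
#' range; `opNoise` adds independent zero-mean Gaussian perturbations.
#' None of these touch the segmentation.
#'
#' @param image numeric array.
#' @param offset additive brightness offset (intensity units).
#' @param factor contrast factor `> 0`.
#' @param exponent gamma exponent `> 0`.
#' @param sd Gaussian noise standard deviation `>= 0`.
#' @return transformed image array.
#' @name intensityOps
NULL

#' @rdname intensityOps
#' @export
opBrightness <- function(image, offset) image + offset

#' @rdname intensityOps
#' @export
opContrast <- function(image, factor) {
  if (factor <= 0)
    voxsegError("validationError", "contrast factor must be > 0")
  if (factor == 1) return(image)
  mu <- mean(image)
  mu + factor * (image - mu)
}

#' @rdname intensityOps
#' @export
opGamma <- function(image, exponent) {
  if (exponent <= 0)
    voxsegError("validationError", "gamma exponent must be > 0")
  if (exponent == 1) return(image)
  lo <- min(image); hi <- max(image)
  if (hi == lo) return(image)
  u <- (image - lo) / (hi - lo)
  u^exponent * (hi - lo) + lo
}

#' @rdname intensityOps
#' @param seed optional integer seeding a local RNG stream.
#' @export
opNoise <- function(image, sd, seed = NULL) {
  if (sd < 0) voxsegError("validationError", "noise sd must be >= 0")
  if (sd == 0) return(image)
  image + withSeed(seed, array(stats::rnorm(length(image), 0, sd),
                               dim(image)))
}

#' Apply the stochastic augmentation chain to an image/label pair
#'
#' Operators fire independently with their configured probabilities in the
#' fixed order mirror, rotation, scaling, elastic deformation, brightness,
#' contrast, gamma, noise.  Spatial operators move image and labels through
#' the same geometric map; intensity operators leave the labels untouched.
#' Output shapes equal input shapes.  With a fixed `seed` the output is
#' bit-reproducible.
#'
#' @param image numeric array with trailing channel axis.
#' @param segmentation optional integer label array over the spatial axes.
#' @param spec an [augmentSpec()].
#' @param seed optional integer seeding a local RNG stream.
#' @return list with `image` and `segmentation`.
#' @export
augmentPair <- function(image, segmentation = NULL, spec = augmentSpec(),
                        seed = NULL) {
  stopifnot(inherits(spec, "augmentSpec"))
  nd <- length(dim(image)) - 1L
  withSeed(seed, {
    if (spec$pMirror > 0 && stats::runif(1) < spec$pMirror) {
      axes <- which(stats::runif(nd) < 0.5)
      if (length(axes)) {
        r <- opMirror(image, segmentation, axes)
        image <- r$image; segmentation <- r$segmentation
      }
    }
    if (spec$pRotate > 0 && stats::runif(1) < spec$pRotate) {
      planes <- utils::combn(nd, 2)
      pl <- planes[, sample.int(ncol(planes), 1)]
      ang <- stats::runif(1, spec$rotationRange[1], spec$rotationRange[2])
      r <- opRotate(image, segmentation, ang, pl)
      image <- r$image; segmentation <- r$segmentation
    }
    if (spec$pScale > 0 && stats::runif(1) < spec$pScale) {
      fac <- stats::runif(1, spec$scaleRange[1], spec$scaleRange[2])
      r <- opScale(image, segmentation, fac)
      image <- r$image; segmentation <- r$segmentation
    }
    if (spec$pElastic > 0 && stats::runif(1) < spec$pElastic) {
      D <- makeDisplacementField(dim(image)[seq_len(nd)],
                                 spec$elasticAmplitude, spec$elasticSigma)
      r <- opElastic(image, segmentation, D)
      image <- r$image; segmentation <- r$segmentation
    }
    if (spec$pBrightness > 0 && stats::runif(1) < spec$pBrightness) {
      s <- stats::sd(as.vector(image))
      off <- stats::runif(1, spec$brightnessRange[1],
                          spec$brightnessRange[2]) * s
      image <- opBrightness(image, off)
    }
    if (spec$pContrast > 0 && stats::runif(1) < spec$pContrast)
      image <- opContrast(image, stats::runif(1, spec$contrastRange[1],
                                              spec$contrastRange[2]))
    if (spec$pGamma > 0 && stats::runif(1) < spec$pGamma)
      image <- opGamma(image, stats::runif(1, spec$gammaRange[1],
                                           spec$gammaRange[2]))
    if (spec$pNoise > 0 && stats::runif(1) < spec$pNoise)
      image <- opNoise(image, stats::runif(1, spec$noiseSdRange[1],
                                           spec$noiseSdRange[2]))
    list(image = image, segmentation = segmentation)
  })
}
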