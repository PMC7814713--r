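#' Batch management plan
#'
#' Prepared items (full images or patches) are bundled into batches that
#' the model processes in one gradient step.  Batches can be staged to disk
#' (`"disk-cache"`) for fast repeated access, or generated in memory
#' (`"on-the-fly"`); both modes feed identical voxel content.
#'
#' @param batchSize items per batch, `>= 1`.
#' @param mode `"on-the-fly"` or `"disk-cache"`.
#' @param cacheDir directory for cached batches (required for disk-cache).
#' @return a `batchPlan` list.
#' @export
batchPlan <- function(batchSize = 2L, mode = "on-the-fly",
                      cacheDir = NULL) {
  mode <- match.arg(mode, c("on-the-fly", "disk-cache"))
  if (batchSize < 1)
    voxsegError("validationError", "batchSize must be >= 1")
  if (mode == "disk-cache" && is.null(cacheDir))
    voxsegError("configurationError", "disk-cache mode requires cacheDir")
  structure(list(batchSize = as.integer(batchSize), mode = mode,
                 cacheDir = cacheDir),
            class = "batchPlan")
}

#' Training schedule
#'
#' @param epochs number of passes over the training set, `>= 1`.
#' @param learningRate starting learning rate of the adaptive-moment
#'   optimizer, `> 0` (constant; schedules are an extension point).
#' @param loss name of a registered metric with a gradient (e.g.
#'   `"tversky"`).
#' @param monitorMetrics names of registered metrics logged per epoch.
#' @param seed master seed; all per-epoch randomness derives from it.
#' @param logFile optional path; per-epoch metric history is written there
#'   as a tab-separated file (columns epoch, split, metric, value).
#' @return a `trainSpec` list.
#' @export
trainSpec <- function(epochs = 10L, learningRate = 1e-4, loss = "tversky",
                      monitorMetrics = c("dice_soft", "dice_classwise"),
                      seed = 1L, logFile = NULL) {
  if (epochs < 1) voxsegError("validationError", "epochs must be >= 1")
  if (learningRate <= 0)
    voxsegError("validationError", "learningRate must be > 0")
  structure(list(epochs = as.integer(epochs), learningRate = learningRate,
                 loss = loss, monitorMetrics = monitorMetrics,
                 seed = as.integer(seed), logFile = logFile),
            class = "trainSpec")
}

#' Bundle an ordered item list into batches
#'
#' Produces `ceiling(n / batchSize)` batches; all but possibly the last
#' have exactly `batchSize` items and their concatenation reproduces the
#' input order.
#'
#' @param items list of items.
#' @param batchSize items per batch.
#' @return list of batches (each a list of items).
#' @export
makeBatches <- function(items, batchSize) {
  if (batchSize < 1)
    voxsegError("validationError", "batchSize must be >= 1")
  n <- length(items)
  if (n == 0) voxsegError("validationError", "no items to batch")
  split(items, ceiling(seq_len(n) / batchSize))
}

#' Shuffle the batch processing order for an epoch
#'
#' Permutes the batch list deterministically given `(seed, epochIndex)`;
#' batch contents are untouched — only the processing sequence changes.
#'
#' @param batches list of batches.
#' @param epochIndex epoch number.
#' @param seed master seed.
#' @return permuted batch list.
#' @export
shuffleEpoch <- function(batches, epochIndex, seed = 1L) {
  if (length(batches) <= 1) return(batches)
  withSeed(deriveSeed(seed, 7L, epochIndex),
           batches[sample.int(length(batches))])
}

#' Stage batches to disk / load a cached batch
#'
#' `batchCache` writes each batch as one file under a stable naming scheme
#' (`batch_0001.rds`, ...) plus a tab-separated index manifest;
#' `loadCachedBatch` returns a batch voxel-identical to the original and
#' raises a cache error naming the index when its file is missing.
#'
#' @param batches list of batches.
#' @param cacheDir writable directory.
#' @return `batchCache`: manifest data.frame (index, file, size);
#'   `loadCachedBatch`: the batch.
#' @export
batchCache <- function(batches, cacheDir) {
  dir.create(cacheDir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(cacheDir, sprintf("batch_%04d.rds",
                                       seq_along(batches)))
  for (i in seq_along(batches)) saveRDS(batches[[i]], files[i])
  manifest <- data.frame(index = seq_along(batches), file = files,
                         size = vapply(batches, length, integer(1)))
  utils::write.table(manifest, file.path(cacheDir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest
}

#' @rdname batchCache
#' @param manifest manifest returned by `batchCache`.
#' @param index batch index to load.
#' @export
loadCachedBatch <- function(manifest, index) {
  row <- manifest[manifest$index == index, ]
  if (nrow(row) != 1 || !file.exists(row$file))
    voxsegError("cacheError", "cached batch %d is missing", index)
  readRDS(row$file)
}

## ---- training --------------------------------------------------------------

## one training item: preprocessed image patch + integer label patch
trainingItems <- function(prepped, patchcfg, epochSeed) {
  items <- list()
  for (s in prepped) {
    img <- s@image
    seg <- s@segmentation
    shape <- spatialShape(img)
    if (patchcfg$analysis == "fullimage") {
      items[[length(items) + 1L]] <- list(image = img, seg = seg)
    } else if (patchcfg$analysis == "patchwise-grid") {
      offs <- computePatchGrid(shape, patchcfg$patchShape, patchcfg$overlap)
      ip <- extractPatches(img, offs, patchcfg$patchShape)
      sp <- extractPatches(seg, offs, patchcfg$patchShape)
      if (patchcfg$skipBlanks) {
        fl <- filterBlankPatches(ip, sp)
        ip <- fl$image; sp <- fl$segmentation
      }
      for (i in seq_len(nPatches(ip)))
        items[[length(items) + 1L]] <- list(image = ip@patches[[i]],
                                            seg = sp@patches[[i]])
    } else {  # patchwise-crop: alternate uniform foreground-rejected crops
              # with crops centered on a voxel of a uniformly chosen
              # foreground class, so rare classes (lesions) appear in every
              # epoch's gradient signal
      for (ci in seq_len(patchcfg$cropsPerSample)) {
        balanced <- patchcfg$skipBlanks && ci %% 2L == 0L &&
          any(seg != 0L)
        if (balanced) {
          cr <- classCenteredCrop(img, seg, patchcfg$patchShape,
                                  seed = deriveSeed(epochSeed,
                                                    sampleOrd(s), ci))
        } else {
          cr <- NULL
          for (try in seq_len(10)) {
            cr <- randomCrop(img, seg, patchcfg$patchShape,
                             seed = deriveSeed(epochSeed, sampleOrd(s), ci,
                                               try))
            if (!patchcfg$skipBlanks || any(cr$segmentation != 0L)) break
          }
        }
        items[[length(items) + 1L]] <- list(image = cr$image,
                                            seg = cr$segmentation)
      }
    }
  }
  items
}

## stable per-sample ordinal used in seed derivation
sampleOrd <- function(s) {
  sum(utf8ToInt(s@id)) %% 10000L
}

## crop containing a voxel of a uniformly chosen foreground class: class
## first, then voxel, so rare classes are not drowned out by frequent ones
classCenteredCrop <- function(img, seg, P, seed = NULL) {
  nd <- length(P)
  shape <- dim(seg)
  withSeed(seed, {
    classes <- setdiff(sort(unique(as.vector(seg))), 0L)
    cls <- classes[sample.int(length(classes), 1L)]
    vox <- which(seg == cls)
    center <- arrayInd(vox[sample.int(length(vox), 1L)], shape)[1, ]
    off <- pmin(pmax(center - P %/% 2L, 1L), shape - P + 1L) - 1L
    idx <- lapply(seq_len(nd), function(a) seq.int(off[a] + 1L, off[a] + P[a]))
    list(image = arraySubset(img, c(idx, list(seq_len(dim(img)[nd + 1L])))),
         segmentation = arraySubset(seg, idx), offset = off)
  })
}

#' Train a segmentation model
#'
#' Runs `epochs` passes of batch assembly, augmentation and loss-gradient
#' updates over the training samples.  Per epoch the item source depends on
#' the analysis mode: full images, the deterministic blank-filtered patch
#' grid, or fresh random crops (one epoch = `cropsPerSample` crops per
#' sample).  Batches are shuffled per epoch and optionally staged to disk.
#' The per-epoch history of the loss and all monitored metrics is returned
#' and, when `spec$logFile` is set, written as a tab-separated file.  The
#' whole procedure is deterministic given `spec$seed`.
#'
#' @param model a `voxModel` (see [buildUNet()], [registerArchitecture()]).
#' @param samples list of [ImageSample-class] objects with segmentations.
#' @param preproc a [preprocSpec()].
#' @param patchcfg a [patchConfig()].
#' @param augspec an [augmentSpec()]; use [augmentSpecOff()] to disable.
#' @param plan a [batchPlan()].
#' @param spec a [trainSpec()].
#' @return list with the fitted `model` and the `history` data.frame
#'   (epoch, split, metric, value).
#' @export
trainModel <- function(model, samples, preproc, patchcfg,
                       augspec = augmentSpecOff(), plan = batchPlan(),
                       spec = trainSpec()) {
  loss <- resolveMetric(spec$loss)
  if (is.null(loss$grad))
    voxsegError("configurationError",
                "metric '%s' has no gradient and cannot be a training loss",
                spec$loss)
  if (any(vapply(samples, function(s) is.null(s@segmentation), logical(1))))
    voxsegError("validationError",
                "every training sample needs a segmentation")
  monitors <- lapply(spec$monitorMetrics, resolveMetric)
  names(monitors) <- spec$monitorMetrics
  arch <- resolveArchitecture(model$arch)
  C <- preproc$nClasses
  prepped <- lapply(samples, preprocessSample, spec = preproc)
  history <- list()
  for (e in seq_len(spec$epochs)) {
    epochSeed <- deriveSeed(spec$seed, e)
    items <- trainingItems(prepped, patchcfg, epochSeed)
    items <- lapply(seq_along(items), function(i) {
      a <- augmentPair(items[[i]]$image, items[[i]]$seg, augspec,
                       seed = deriveSeed(epochSeed, 1000L, i))
      list(image = a$image, seg = a$segmentation)
    })
    batches <- makeBatches(items, plan$batchSize)
    batches <- shuffleEpoch(batches, e, spec$seed)
    manifest <- NULL
    if (plan$mode == "disk-cache")
      manifest <- batchCache(batches, plan$cacheDir)
    epochStats <- stats::setNames(
      numeric(1 + length(monitors)), c(spec$loss, names(monitors)))
    nMembers <- 0L
    for (bi in seq_along(batches)) {
      batch <- if (is.null(manifest)) batches[[bi]] else
        loadCachedBatch(manifest, bi)
      shape <- spatialShape(batch[[1]]$image)
      B <- length(batch)
      nvox <- prod(shape)
      X <- do.call(rbind, lapply(batch,
                                 function(it) matrix(it$image, nvox)))
      Tm <- do.call(rbind, lapply(batch, function(it)
        matrix(oneHotEncode(it$seg, C), nvox)))
      withSeed(deriveSeed(epochSeed, 2000L, bi), {
        fw <- arch$forward(model, X, shape, B, train = TRUE)
        model <- fw$model
        dP <- matrix(0, nrow(fw$probs), C)
        for (b in seq_len(B)) {
          rows <- (b - 1L) * nvox + seq_len(nvox)
          tb <- Tm[rows, , drop = FALSE]
          pb <- fw$probs[rows, , drop = FALSE]
          epochStats[spec$loss] <- epochStats[spec$loss] + loss$fn(tb, pb)
          for (m in names(monitors))
            epochStats[m] <- epochStats[m] + monitors[[m]]$fn(tb, pb)
          dP[rows, ] <- loss$grad(tb, pb) / B
        }
        grads <- arch$backward(model, fw$cache, dP)
        if (is.null(model$opt)) model$opt <- adamInit(model$params)
        ad <- adamStep(model$params, grads, model$opt, spec$learningRate)
        model$params <- ad$params
        model$opt <- ad$state
      })
      nMembers <- nMembers + B
    }
    epochStats <- epochStats / nMembers
    history[[e]] <- data.frame(epoch = e, split = "train",
                               metric = names(epochStats),
                               value = as.numeric(epochStats))
    if (!is.null(spec$logFile))
      utils::write.table(do.call(rbind, history), spec$logFile, sep = "\t",
                         row.names = FALSE, quote = FALSE)
  }
  list(model = model, history = do.call(rbind, history))
}

#' Predict the segmentation of one sample
#'
#' Full prediction chain: preprocess, decompose into the overlapping
#' deterministic patch grid (or the full image), per-patch class
#' probabilities, mean-merge, per-voxel argmax, restore the original voxel
#' grid, and optionally save through a data interface.  The returned mask
#' has the sample's original shape with labels in `[0, C)`.
#'
#' @param model a `voxModel`.
#' @param sample an [ImageSample-class].
#' @param preproc a [preprocSpec()].
#' @param patchcfg a [patchConfig()]; prediction uses the overlapping grid
#'   whenever analysis is patch-wise (set `overlap = 0` for distinct
#'   patches).
#' @param batchSize inference batch size.
#' @param interface optional data interface used to save the prediction.
#' @param outDir output directory for the saved prediction.
#' @return integer mask array of shape `sample@originalShape`.
#' @export
predictSample <- function(model, sample, preproc, patchcfg,
                          batchSize = 2L, interface = NULL, outDir = NULL) {
  pp <- preprocessSample(sample, preproc)
  record <- pp@meta$gridRecord
  img <- pp@image
  shape <- spatialShape(img)
  C <- model$config$nClasses
  if (patchcfg$analysis == "fullimage") {
    offs <- matrix(0L, 1, length(shape))
    P <- as.integer(shape)
  } else {
    P <- patchcfg$patchShape
    offs <- computePatchGrid(shape, P, patchcfg$overlap)
  }
  ip <- extractPatches(img, offs, P)
  probs <- predictPatches(model, ip@patches, batchSize)
  probSet <- new("PatchSet", offsets = offs, patches = probs,
                 sourceShape = as.integer(shape))
  merged <- mergePatchPredictions(probSet, shape, C)
  labels <- oneHotDecode(merged)
  restored <- restoreToOriginalGrid(labels, record)
  if (!is.null(interface) && !is.null(outDir))
    interface$savePrediction(sample@id, restored, sample, outDir)
  restored
}
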