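#' Build a train/test split plan
#'
#' Supported evaluation modes: `"kfold"` (test sets partition the ids,
#' sizes differing by at most one — the first `n %% k` folds take the extra
#' sample), `"loo"` (leave-one-out: n singleton test sets), `"percentage"`
#' and `"holdout"` (the same single-fold mechanism: a random `fraction` of
#' the ids trains, the rest tests), and `"detailed"` (explicit user lists
#' copied verbatim).  All random modes sample deterministically from
#' `seed`.
#'
#' @param ids character vector of sample identifiers, `n >= 2`.
#' @param mode one of `"kfold"`, `"loo"`, `"percentage"`, `"holdout"`,
#'   `"detailed"`.
#' @param k number of folds (kfold), `k <= n`.
#' @param fraction training fraction in `(0, 1)` (percentage/holdout).
#' @param folds list of `list(train =, test =)` (detailed mode).
#' @param seed integer seed for the random sampling.
#' @return a `splitPlan` list with elements `mode`, `folds`, `seed`.
#' @export
makeSplit <- function(ids, mode = "kfold", k = 3L, fraction = 0.8,
                      folds = NULL, seed = 1L) {
  mode <- match.arg(mode,
                    c("kfold", "loo", "percentage", "holdout", "detailed"))
  n <- length(ids)
  if (n < 2) voxsegError("validationError", "need at least 2 sample ids")
  if (anyDuplicated(ids))
    voxsegError("validationError", "sample ids must be unique")
  out <- switch(mode,
    kfold = {
      if (k > n)
        voxsegError("validationError", "k = %d exceeds n = %d", k, n)
      perm <- withSeed(seed, sample(ids))
      sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
      stops <- cumsum(sizes)
      starts <- c(1L, stops[-k] + 1L)
      lapply(seq_len(k), function(f) {
        test <- perm[starts[f]:stops[f]]
        list(train = setdiff(ids, test), test = test)
      })
    },
    loo = lapply(ids, function(id)
      list(train = setdiff(ids, id), test = id)),
    percentage = ,
    holdout = {
      if (fraction <= 0 || fraction >= 1)
        voxsegError("validationError", "fraction must lie in (0, 1)")
      perm <- withSeed(seed, sample(ids))
      nTrain <- min(max(round(fraction * n), 1L), n - 1L)
      list(list(train = perm[seq_len(nTrain)], test = perm[-seq_len(nTrain)]))
    },
    detailed = {
      if (is.null(folds))
        voxsegError("validationError", "detailed mode requires explicit folds")
      for (f in folds) {
        if (length(intersect(f$train, f$test)))
          voxsegError("validationError",
                      "train and test lists overlap in a detailed fold")
        if (!all(c(f$train, f$test) %in% ids))
          voxsegError("validationError", "unknown id in a detailed fold")
      }
      lapply(folds, function(f) list(train = f$train, test = f$test))
    })
  structure(list(mode = mode, folds = out, seed = as.integer(seed)),
            class = "splitPlan")
}

#' Per-sample intensity range and class frequencies
#'
#' @param samples list of [ImageSample-class] objects.
#' @param nClasses class count; inferred from the labels present when
#'   `NULL`.
#' @return long data.frame with columns sample_id, quantity
#'   (`intensity_min`, `intensity_max`, `class_count`, `class_fraction`),
#'   class (`NA` for intensity rows) and value.  Class fractions sum to 1
#'   per sample.
#' @export
datasetStatistics <- function(samples, nClasses = NULL) {
  if (!length(samples)) voxsegError("validationError", "no samples")
  if (is.null(nClasses)) {
    nClasses <- max(vapply(samples, function(s)
      if (is.null(s@segmentation)) 1L else
        max(s@segmentation) + 1L, integer(1)))
  }
  rows <- lapply(samples, function(s) {
    out <- data.frame(sample_id = s@id,
                      quantity = c("intensity_min", "intensity_max"),
                      class = NA_integer_,
                      value = c(min(s@image), max(s@image)))
    if (!is.null(s@segmentation)) {
      counts <- tabulate(s@segmentation + 1L, nbins = nClasses)
      out <- rbind(out,
                   data.frame(sample_id = s@id, quantity = "class_count",
                              class = seq_len(nClasses) - 1L,
                              value = counts),
                   data.frame(sample_id = s@id, quantity = "class_fraction",
                              class = seq_len(nClasses) - 1L,
                              value = counts / sum(counts)))
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run an automatic cross-validation study
#'
#' For every fold of the plan: builds a fresh model from the architecture
#' registry, trains on the training ids only, predicts every test id
#' through the full pipeline, and scores predictions against ground truth
#' with the requested metrics — so the testing sets have no influence on
#' the fitting.  Per-fold rows and cross-fold means are returned and
#' written tab-separated when `outDir` is given.
#'
#' @param samples named list of [ImageSample-class] objects (names = ids).
#' @param plan a `splitPlan` from [makeSplit()].
#' @param architecture registered architecture name (e.g. `"unet"`).
#' @param modelConfig configuration consumed by the architecture builder
#'   (a [unetConfig()] for `"unet"`).
#' @param preproc,patchcfg,augspec,batchplan,trainspec pipeline
#'   configuration objects.
#' @param metrics names of registered metrics to score predictions with.
#' @param outDir optional directory for `cv_results.tsv` /
#'   `cv_summary.tsv`.
#' @param keepModels return the fitted per-fold models (can be large).
#' @return list with `results` (fold, sample_id, metric, value),
#'   `summary` (fold rows plus a `"mean"` row per metric) and optionally
#'   `models`.
#' @export
runCrossValidation <- function(samples, plan, architecture = "unet",
                               modelConfig = unetConfig(),
                               preproc = preprocSpec(),
                               patchcfg, augspec = augmentSpecOff(),
                               batchplan = batchPlan(),
                               trainspec = trainSpec(),
                               metrics = c("dice_soft", "dice_classwise",
                                           "tversky", "jaccard"),
                               outDir = NULL, keepModels = FALSE) {
  stopifnot(inherits(plan, "splitPlan"))
  ids <- names(samples)
  if (is.null(ids))
    ids <- vapply(samples, function(s) s@id, character(1))
  names(samples) <- ids
  arch <- resolveArchitecture(architecture)
  metricFns <- lapply(metrics, resolveMetric)
  names(metricFns) <- metrics
  C <- preproc$nClasses
  results <- list()
  models <- list()
  for (f in seq_along(plan$folds)) {
    fold <- plan$folds[[f]]
    missing <- setdiff(c(fold$train, fold$test), ids)
    if (length(missing))
      voxsegError("validationError", "fold %d: unresolvable id(s) %s", f,
                  paste(missing, collapse = ", "))
    noTruth <- Filter(function(id)
      is.null(samples[[id]]@segmentation), fold$test)
    if (length(noTruth))
      voxsegError("validationError",
                  "fold %d: missing ground truth for %s", f,
                  paste(noTruth, collapse = ", "))
    foldResult <- tryCatch({
      model <- arch$build(modelConfig,
                          seed = deriveSeed(trainspec$seed, 50L, f))
      tr <- trainModel(model, samples[fold$train], preproc, patchcfg,
                       augspec, batchplan, trainspec)
      rows <- list()
      for (id in fold$test) {
        s <- samples[[id]]
        pred <- predictSample(tr$model, s, preproc, patchcfg,
                              batchSize = batchplan$batchSize)
        truthOH <- oneHotEncode(s@segmentation, C)
        predOH <- oneHotEncode(pred, C)
        for (m in metrics)
          rows[[length(rows) + 1L]] <-
            data.frame(fold = f, sample_id = id, metric = m,
                       value = metricFns[[m]]$fn(truthOH, predOH))
      }
      list(rows = do.call(rbind, rows), model = tr$model)
    }, voxsegError = function(e)
      voxsegError("foldError", "cross-validation failed in fold %d: %s", f,
                  conditionMessage(e)))
    results[[f]] <- foldResult$rows
    if (keepModels) models[[f]] <- foldResult$model
  }
  results <- do.call(rbind, results)
  perFold <- stats::aggregate(value ~ fold + metric, results, mean)
  grand <- stats::aggregate(value ~ metric, results, mean)
  grand$fold <- "mean"
  summary <- rbind(data.frame(fold = as.character(perFold$fold),
                              metric = perFold$metric,
                              value = perFold$value),
                   grand[, c("fold", "metric", "value")])
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(results, file.path(outDir, "cv_results.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(summary, file.path(outDir, "cv_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out <- list(results = results, summary = summary)
  if (keepModels) out$models <- models
  out
}

## fixed class palette (class index 1..8), alpha-blended over grayscale
overlayPalette <- function() {
  grDevices::col2rgb(c("#E41A1C", "#377EB8", "#4DAF4A", "#FF7F00",
                       "#984EA3", "#FFFF33", "#A65628", "#F781BF")) / 255
}

## one grayscale slice + mask overlay as an h x w x 3 raster
overlayRaster <- function(slice, maskSlice, alpha = 0.4) {
  lo <- min(slice); hi <- max(slice)
  g <- if (hi > lo) (slice - lo) / (hi - lo) else slice * 0
  pal <- overlayPalette()
  out <- array(rep(g, 3), c(dim(g), 3))
  for (cls in sort(unique(as.vector(maskSlice)))) {
    if (cls == 0) next
    sel <- maskSlice == cls
    col <- pal[, ((cls - 1) %% ncol(pal)) + 1]
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[sel] <- (1 - alpha) * plane[sel] + alpha * col[ch]
      out[, , ch] <- plane
    }
  }
  ## raster rows run top-down, array rows run along axis 1
  aperm(out, c(2, 1, 3))[rev(seq_len(dim(out)[2])), , , drop = FALSE]
}

#' Render static slice overlays of a segmentation
#'
#' Writes, per requested slice along the last spatial axis, a PNG of the
#' grayscale image with the color-coded class overlay (alpha 0.4, fixed
#' palette by class index); when ground truth is given, prediction and
#' truth are placed side by side.  Output is deterministic given the
#' inputs.
#'
#' @param sample an [ImageSample-class].
#' @param mask integer mask aligned to the sample grid.
#' @param truth optional ground-truth mask for side-by-side display.
#' @param slices integer slice indices along the last spatial axis, or
#'   `"all"`; 2D samples have exactly one slice.
#' @param outDir output directory.
#' @return character vector of written file paths, invisibly.
#' @export
renderOverlay <- function(sample, mask, truth = NULL, slices = "all",
                          outDir) {
  shape <- sampleShape(sample)
  nd <- length(shape)
  if (!identical(as.integer(dim(mask)), as.integer(shape)))
    voxsegError("validationError", "mask is not aligned to the sample grid")
  nSlices <- if (nd == 2L) 1L else shape[nd]
  if (identical(slices, "all")) slices <- seq_len(nSlices)
  if (any(slices < 1 | slices > nSlices))
    voxsegError("validationError",
                "slice index out of range 1..%d", nSlices)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  img <- sample@image
  paths <- character(0)
  for (z in slices) {
    if (nd == 2L) {
      sl <- img[, , 1]
      mk <- mask
      tr <- truth
    } else {
      sl <- img[, , z, 1]
      mk <- mask[, , z]
      tr <- if (is.null(truth)) NULL else truth[, , z]
    }
    ras <- overlayRaster(sl, mk)
    if (!is.null(tr))
      ras <- abind2(ras, overlayRaster(sl, tr))
    p <- file.path(outDir, sprintf("%s_slice_%03d.png", sample@id, z))
    png::writePNG(ras, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

## bind two h x w x 3 rasters side by side with a 2-pixel divider
abind2 <- function(a, b) {
  h <- dim(a)[1]
  div <- array(1, c(h, 2, 3))
  out <- array(0, c(h, dim(a)[2] + 2 + dim(b)[2], 3))
  out[, seq_len(dim(a)[2]), ] <- a
  out[, dim(a)[2] + 1:2, ] <- div
  out[, dim(a)[2] + 2 + seq_len(dim(b)[2]), ] <- b
  out
}
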