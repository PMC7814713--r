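#' Tversky loss parameters
#'
#' The Tversky index generalizes Dice overlap with separate weights on
#' false positives (`alpha`) and false negatives (`beta`); with
#' `alpha = beta = 0.5` it reduces exactly to the Dice coefficient.
#' Weighting false negatives more (`beta > alpha`) trades precision for
#' recall, which counters the foreground under-segmentation typical of
#' class-unbalanced medical volumes.  Defaults follow the recall-weighted
#' setting `alpha = 0.3`, `beta = 0.7`.
#'
#' @param alpha false-positive weight, `>= 0`.
#' @param beta false-negative weight, `>= 0`; `alpha + beta > 0`.
#' @param epsilon smoothing constant `> 0` protecting empty classes.
#' @return a `tverskyParams` list.
#' @export
tverskyParams <- function(alpha = 0.3, beta = 0.7, epsilon = 1e-5) {
  if (alpha < 0 || beta < 0 || alpha + beta <= 0 || epsilon <= 0)
    voxsegError("validationError",
                "need alpha, beta >= 0, alpha + beta > 0, epsilon > 0")
  structure(list(alpha = alpha, beta = beta, epsilon = epsilon),
            class = "tverskyParams")
}

## coerce truth/prediction arrays (trailing class axis) to nvox x C matrices
asClassMatrix <- function(truth, pred) {
  dt <- dim(truth); dp <- dim(pred)
  if (!identical(as.integer(dt), as.integer(dp)))
    voxsegError("validationError",
                "truth and prediction shapes differ (%s vs %s)",
                paste(dt, collapse = "x"), paste(dp, collapse = "x"))
  C <- dt[length(dt)]
  list(t = matrix(truth, ncol = C), p = matrix(pred, ncol = C), C = C)
}

#' Simple (soft) Dice coefficient
#'
#' Accumulates overlap over all voxels and classes at once:
#' `(2 * sum(t * p) + eps) / (sum(t) + sum(p) + eps)`.  On hard one-hot
#' masks this is the classical Dice similarity coefficient pooled over
#' classes; on probabilities it is the soft variant.
#'
#' @param truth one-hot truth array, trailing class axis.
#' @param pred predicted probabilities, same shape.
#' @param epsilon smoothing constant.
#' @return scalar in `[0, 1]`.
#' @export
softDice <- function(truth, pred, epsilon = 1e-5) {
  m <- asClassMatrix(truth, pred)
  (2 * sum(m$t * m$p) + epsilon) / (sum(m$t) + sum(m$p) + epsilon)
}

#' Class-wise Dice coefficient
#'
#' Scores each segmentation class separately, which is the recommended view
#' for unbalanced problems where a pooled score is dominated by the
#' background.  A class absent from both truth and prediction scores
#' `eps / eps = 1` by the smoothed formula; this inflates class-wise means
#' when classes are missing and is documented deliberately.
#'
#' @inheritParams softDice
#' @return list with `perClass` (length-C vector) and `mean`.
#' @export
classwiseDice <- function(truth, pred, epsilon = 1e-5) {
  m <- asClassMatrix(truth, pred)
  num <- 2 * colSums(m$t * m$p) + epsilon
  den <- colSums(m$t) + colSums(m$p) + epsilon
  perClass <- num / den
  list(perClass = as.numeric(perClass), mean = mean(perClass))
}

#' Jaccard index (intersection over union)
#'
#' `(sum(t*p) + eps) / (sum(t) + sum(p) - sum(t*p) + eps)`, pooled and
#' class-wise.  Related to Dice by `J = D / (2 - D)` on hard masks.
#'
#' @inheritParams softDice
#' @return list with `pooled`, `perClass` and `mean`.
#' @export
jaccardIndex <- function(truth, pred, epsilon = 1e-5) {
  m <- asClassMatrix(truth, pred)
  iAll <- sum(m$t * m$p)
  pooled <- (iAll + epsilon) / (sum(m$t) + sum(m$p) - iAll + epsilon)
  iC <- colSums(m$t * m$p)
  perClass <- (iC + epsilon) /
    (colSums(m$t) + colSums(m$p) - iC + epsilon)
  list(pooled = pooled, perClass = as.numeric(perClass),
       mean = mean(perClass))
}

#' Tversky loss
#'
#' Per class `c`, the soft Tversky index is
#' `TI_c = (TP_c + eps) / (TP_c + alpha * FP_c + beta * FN_c + eps)` with
#' soft counts `TP = sum(t * p)`, `FP = sum((1 - t) * p)`,
#' `FN = sum(t * (1 - p))`; the loss is `1 - mean_c TI_c`.  With
#' `alpha = beta = 0.5` this equals the class-wise soft-Dice loss exactly.
#'
#' @inheritParams softDice
#' @param params a [tverskyParams()].
#' @return scalar loss `>= 0`.
#' @export
tverskyLoss <- function(truth, pred, params = tverskyParams()) {
  m <- asClassMatrix(truth, pred)
  tp <- colSums(m$t * m$p)
  fp <- colSums((1 - m$t) * m$p)
  fn <- colSums(m$t * (1 - m$p))
  ti <- (tp + params$epsilon) /
    (tp + params$alpha * fp + params$beta * fn + params$epsilon)
  1 - mean(ti)
}

## analytic gradient of tverskyLoss w.r.t. pred, same shape as pred
tverskyLossGrad <- function(truth, pred, params = tverskyParams()) {
  m <- asClassMatrix(truth, pred)
  eps <- params$epsilon
  tp <- colSums(m$t * m$p)
  fp <- colSums((1 - m$t) * m$p)
  fn <- colSums(m$t * (1 - m$p))
  num <- tp + eps
  den <- tp + params$alpha * fp + params$beta * fn + eps
  ## d num / d p = t ; d den / d p = t + alpha (1 - t) - beta t
  dP <- matrix(0, nrow(m$p), m$C)
  for (c in seq_len(m$C)) {
    t_c <- m$t[, c]
    dden <- t_c + params$alpha * (1 - t_c) - params$beta * t_c
    dTI <- (t_c * den[c] - num[c] * dden) / den[c]^2
    dP[, c] <- -dTI / m$C
  }
  array(dP, dim(pred))
}

#' Categorical cross-entropy minus soft Dice
#'
#' The combined training/evaluation score
#' `CE - softDice` with `CE = -(1/N) * sum(t * log(p))` (probabilities
#' clipped internally to `[1e-7, 1 - 1e-7]`).  A perfect prediction
#' approaches `-1`; the score may be negative.
#'
#' @inheritParams softDice
#' @return scalar score.
#' @export
crossentropyDice <- function(truth, pred, epsilon = 1e-5) {
  m <- asClassMatrix(truth, pred)
  p <- pmin(pmax(m$p, 1e-7), 1 - 1e-7)
  ce <- -sum(m$t * log(p)) / nrow(m$p)
  ce - softDice(truth, pred, epsilon)
}

## categorical cross-entropy and its gradient (training loss)
categoricalCrossentropy <- function(truth, pred) {
  m <- asClassMatrix(truth, pred)
  p <- pmin(pmax(m$p, 1e-7), 1 - 1e-7)
  -sum(m$t * log(p)) / nrow(m$p)
}

categoricalCrossentropyGrad <- function(truth, pred) {
  m <- asClassMatrix(truth, pred)
  p <- pmin(pmax(m$p, 1e-7), 1 - 1e-7)
  array(-(m$t / p) / nrow(m$p), dim(pred))
}

## per-class confusion counts on hard masks (reference representation)
#' Per-class confusion counts of two hard label masks
#'
#' Counts TP/FP/FN/TN voxels per class between integer label masks.  This is
#' the closed-form representation every overlap metric can be written in and
#' serves as the evaluation bookkeeping for hard predictions.
#'
#' @param truthLabels,predLabels integer label arrays, same shape.
#' @param nClasses class count `C`.
#' @return data.frame with columns class, tp, fp, fn, tn.
#' @export
confusionCounts <- function(truthLabels, predLabels, nClasses) {
  if (!identical(dim(truthLabels), dim(predLabels)))
    voxsegError("validationError", "mask shapes differ")
  n <- length(truthLabels)
  out <- data.frame(class = seq_len(nClasses) - 1L, tp = 0, fp = 0,
                    fn = 0, tn = 0)
  for (c in seq_len(nClasses) - 1L) {
    t_c <- truthLabels == c
    p_c <- predLabels == c
    tp <- sum(t_c & p_c)
    fp <- sum(!t_c & p_c)
    fn <- sum(t_c & !p_c)
    out[out$class == c, 2:5] <- c(tp, fp, fn, n - tp - fp - fn)
  }
  out
}

## ---- metric registry -------------------------------------------------------

#' Register a metric or training loss
#'
#' Metrics are resolved by name from the pipeline configuration, both as
#' monitored quantities and (when a gradient is supplied) as training
#' losses.  A metric function has signature `fn(truth, pred)` on arrays with
#' a trailing class axis and returns a scalar; a loss gradient has the same
#' signature and returns an array shaped like `pred`.
#'
#' @param name metric name (unused so far).
#' @param fn scalar metric function `fn(truth, pred)`.
#' @param grad optional gradient function for use as a training loss.
#' @param overwrite replace an existing entry instead of erroring.
#' @return the registered name, invisibly.
#' @export
registerMetric <- function(name, fn, grad = NULL, overwrite = FALSE) {
  if (!overwrite && exists(name, envir = .voxseg$metrics, inherits = FALSE))
    voxsegError("configurationError", "metric '%s' is already registered",
                name)
  if (!is.function(fn) || length(formals(fn)) < 2)
    voxsegError("validationError",
                "metric must be a function of (truth, prediction)")
  assign(name, list(fn = fn, grad = grad), envir = .voxseg$metrics)
  invisible(name)
}

#' Resolve a registered metric by name
#' @param name metric name.
#' @return list with elements `fn` and (possibly `NULL`) `grad`.
#' @export
resolveMetric <- function(name) {
  if (!exists(name, envir = .voxseg$metrics, inherits = FALSE))
    voxsegError("configurationError", "no metric registered under '%s'", name)
  get(name, envir = .voxseg$metrics)
}

#' Names of all registered metrics
#' @return character vector.
#' @export
listMetrics <- function() sort(ls(.voxseg$metrics))

registerBuiltinMetrics <- function() {
  reg <- function(name, fn, grad = NULL)
    registerMetric(name, fn, grad, overwrite = TRUE)
  reg("dice_soft", function(truth, pred) softDice(truth, pred))
  reg("dice_classwise", function(truth, pred) classwiseDice(truth, pred)$mean)
  reg("jaccard", function(truth, pred) jaccardIndex(truth, pred)$mean)
  reg("tversky",
      function(truth, pred) tverskyLoss(truth, pred),
      function(truth, pred) tverskyLossGrad(truth, pred))
  reg("dice_classwise_loss",
      function(truth, pred)
        tverskyLoss(truth, pred, tverskyParams(0.5, 0.5)),
      function(truth, pred)
        tverskyLossGrad(truth, pred, tverskyParams(0.5, 0.5)))
  reg("crossentropy",
      categoricalCrossentropy, categoricalCrossentropyGrad)
  reg("crossentropy_dice",
      function(truth, pred) crossentropyDice(truth, pred))
  invisible()
}
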