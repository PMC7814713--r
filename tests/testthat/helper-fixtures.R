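## Shared fixtures, generated in code at test time.

## small fast phantom (24^3) used wherever exact scale does not matter
smallPhantomConfig <- function(nClasses = 3L, noiseSd = 0.05) {
  phantomConfig(shape = c(24L, 24L, 24L), nClasses = nClasses,
                noiseSd = noiseSd, organSemiAxes = c(5, 8),
                lesionSemiAxes = c(2, 3))
}

## intensity-threshold oracle architecture: classifies each voxel by its
## proximity to the phantom class means.  Trains as a no-op (no params) and
## predicts the ground truth exactly on noiseless, unnormalized phantoms.
thresholdArchitecture <- function(means = c(0, 0.5, 1.0)) {
  force(means)
  list(
    build = function(config, seed = 1L) {
      structure(list(arch = "threshold", config = config,
                     params = list(), bnState = list(), opt = NULL),
                class = "voxModel")
    },
    forward = function(model, X, shape, B, train = FALSE) {
      C <- model$config$nClasses
      d2 <- vapply(means[seq_len(C)], function(m) (X[, 1] - m)^2,
                   numeric(nrow(X)))
      ## hard assignment: winner takes (numerically) all
      hard <- max.col(-d2, ties.method = "first")
      P <- matrix(1e-7, nrow(X), C)
      P[cbind(seq_len(nrow(X)), hard)] <- 1 - 1e-7 * (C - 1)
      list(probs = P, cache = NULL, model = model)
    },
    backward = function(model, cache, dP) list())
}

withThresholdArch <- function(code, means = c(0, 0.5, 1.0)) {
  registerArchitecture("threshold", thresholdArchitecture(means),
                       overwrite = TRUE)
  code
}

## deterministic phantom pair used by several files
fixturePhantoms <- function(n, config = smallPhantomConfig(), seed = 123L) {
  lapply(seq_len(n), function(i)
    generatePhantom(config, seed = 1000L + i,
                    id = sprintf("fix_%02d", i)))
}
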