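#' U-Net configuration
#'
#' Describes a standard 2D/3D U-Net: `depth` pooling steps, two 3-per-axis
#' convolutions per level with filters doubling from `baseFilters`, max-pool
#' downsampling, transposed-convolution upsampling with skip concatenation
#' from the same-level encoder block, and a final 1-per-axis convolution to
#' `nClasses` channels with a per-voxel softmax (class probabilities sum to
#' 1).  Every input spatial dimension must be divisible by `2^depth`.
#'
#' @param nDims spatial rank, 2 or 3.
#' @param inChannels input channels `>= 1`.
#' @param nClasses segmentation classes `C >= 2`.
#' @param baseFilters filters at the first level `f0 >= 1`.
#' @param depth number of pooling steps `d >= 1`.
#' @param batchNorm add batch normalization after every convolution.
#' @param dropout dropout rate in `[0, 1)` applied after each block during
#'   training (0 disables).
#' @return a `unetConfig` list.
#' @export
unetConfig <- function(nDims = 3L, inChannels = 1L, nClasses = 2L,
                       baseFilters = 32L, depth = 4L, batchNorm = FALSE,
                       dropout = 0) {
  if (!nDims %in% c(2L, 3L))
    voxsegError("configurationError", "nDims must be 2 or 3")
  if (inChannels < 1 || nClasses < 2 || baseFilters < 1 || depth < 1)
    voxsegError("configurationError",
                "need inChannels >= 1, nClasses >= 2, baseFilters >= 1, depth >= 1")
  if (dropout < 0 || dropout >= 1)
    voxsegError("configurationError", "dropout must lie in [0, 1)")
  structure(list(nDims = as.integer(nDims),
                 inChannels = as.integer(inChannels),
                 nClasses = as.integer(nClasses),
                 baseFilters = as.integer(baseFilters),
                 depth = as.integer(depth), batchNorm = isTRUE(batchNorm),
                 dropout = dropout),
            class = "unetConfig")
}

checkDivisibility <- function(shape, depth) {
  bad <- which(shape %% (2L^depth) != 0L)
  if (length(bad))
    voxsegError("configurationError",
                "input axis %s (size %s) not divisible by 2^depth = %d",
                paste(bad, collapse = ","),
                paste(shape[bad], collapse = ","), 2L^depth)
  invisible(TRUE)
}

## filters at encoder level l
unetFilters <- function(config, l) config$baseFilters * 2L^(l - 1L)

## conv-unit parameter prefixes in network order
unetPrefixes <- function(config) {
  d <- config$depth
  c(paste0("enc", rep(seq_len(d), each = 2), "_", 1:2),
    "bot_1", "bot_2",
    as.vector(rbind(paste0("dec", d:1, "_up"),
                    paste0("dec", d:1, "_1"), paste0("dec", d:1, "_2"))),
    "final")
}

unetInit <- function(config, seed = 1L) {
  d <- config$depth
  K <- 3L^config$nDims
  P2 <- 2L^config$nDims
  params <- list()
  bnState <- list()
  addConv <- function(prefix, ci, co) {
    params[[paste0(prefix, "_W")]] <<- heInit(K * ci, c(K * ci, co))
    params[[paste0(prefix, "_b")]] <<- numeric(co)
    if (config$batchNorm) {
      params[[paste0(prefix, "_gamma")]] <<- rep(1, co)
      params[[paste0(prefix, "_beta")]] <<- numeric(co)
      bnState[[prefix]] <<- list(mean = numeric(co), var = rep(1, co))
    }
  }
  withSeed(seed, {
    cin <- config$inChannels
    for (l in seq_len(d)) {
      f <- unetFilters(config, l)
      addConv(paste0("enc", l, "_1"), cin, f)
      addConv(paste0("enc", l, "_2"), f, f)
      cin <- f
    }
    fb <- unetFilters(config, d + 1L)
    addConv("bot_1", cin, fb)
    addConv("bot_2", fb, fb)
    up <- fb
    for (l in rev(seq_len(d))) {
      f <- unetFilters(config, l)
      params[[paste0("dec", l, "_up_W")]] <- heInit(up, c(up, f, P2))
      params[[paste0("dec", l, "_up_b")]] <- numeric(f)
      addConv(paste0("dec", l, "_1"), 2L * f, f)
      addConv(paste0("dec", l, "_2"), f, f)
      up <- f
    }
    params[["final_W"]] <- heInit(config$baseFilters,
                                  c(config$baseFilters, config$nClasses))
    params[["final_b"]] <- numeric(config$nClasses)
  })
  list(params = params, bnState = bnState)
}

## conv -> (batch norm) -> relu, with caches for backprop
convUnitForward <- function(model, X, prefix, NI, K, train) {
  p <- model$params
  Z <- convForward(X, p[[paste0(prefix, "_W")]],
                   p[[paste0(prefix, "_b")]], NI, K)
  cache <- list(X = X, Z = Z)
  if (model$config$batchNorm) {
    bn <- bnForward(Z, p[[paste0(prefix, "_gamma")]],
                    p[[paste0(prefix, "_beta")]],
                    model$bnState[[prefix]], train)
    model$bnState[[prefix]] <- bn$run
    cache$bn <- list(xhat = bn$xhat, inv = bn$inv)
    cache$Zn <- bn$Y
  } else cache$Zn <- Z
  list(A = reluForward(cache$Zn), cache = cache, model = model)
}

convUnitBackward <- function(model, dA, prefix, cache, NI, K, grads) {
  dZn <- reluBackward(dA, cache$Zn)
  p <- model$params
  if (model$config$batchNorm) {
    bb <- bnBackward(dZn, cache$bn, p[[paste0(prefix, "_gamma")]])
    grads[[paste0(prefix, "_gamma")]] <- bb$dgamma
    grads[[paste0(prefix, "_beta")]] <- bb$dbeta
    dZ <- bb$dX
  } else dZ <- dZn
  cb <- convBackward(dZ, cache$X, p[[paste0(prefix, "_W")]], NI, K)
  grads[[paste0(prefix, "_W")]] <- cb$dW
  grads[[paste0(prefix, "_b")]] <- cb$db
  list(dX = cb$dX, grads = grads)
}

unetForward <- function(model, X, shape, B, train = FALSE) {
  config <- model$config
  d <- config$depth
  checkDivisibility(shape, d)
  plans <- getNetPlans(shape, B, d)
  K <- plans$K; P2 <- plans$P2
  cache <- list(shape = shape, B = B, enc = vector("list", d),
                dec = vector("list", d), drop = list())
  x <- X
  for (l in seq_len(d)) {
    lev <- plans$levels[[l]]
    u1 <- convUnitForward(model, x, paste0("enc", l, "_1"), lev$conv, K,
                          train)
    model <- u1$model
    u2 <- convUnitForward(model, u1$A, paste0("enc", l, "_2"), lev$conv, K,
                          train)
    model <- u2$model
    a <- u2$A
    if (train && config$dropout > 0) {
      dr <- dropoutForward(a, config$dropout)
      a <- dr$Y
      cache$drop[[paste0("enc", l)]] <- dr$mask
    }
    pool <- poolForward(a, lev$pool, P2)
    cache$enc[[l]] <- list(u1 = u1$cache, u2 = u2$cache, skip = a,
                           amax = pool$amax)
    x <- pool$Y
  }
  levB <- plans$levels[[d + 1]]
  b1 <- convUnitForward(model, x, "bot_1", levB$conv, K, train)
  model <- b1$model
  b2 <- convUnitForward(model, b1$A, "bot_2", levB$conv, K, train)
  model <- b2$model
  x <- b2$A
  if (train && config$dropout > 0) {
    dr <- dropoutForward(x, config$dropout)
    x <- dr$Y
    cache$drop[["bot"]] <- dr$mask
  }
  cache$bot <- list(u1 = b1$cache, u2 = b2$cache)
  for (l in rev(seq_len(d))) {
    lev <- plans$levels[[l]]
    up <- upconvForward(x, model$params[[paste0("dec", l, "_up_W")]],
                        model$params[[paste0("dec", l, "_up_b")]],
                        lev$pool, P2, nrow(lev$conv))
    xc <- cbind(cache$enc[[l]]$skip, up)
    u1 <- convUnitForward(model, xc, paste0("dec", l, "_1"), lev$conv, K,
                          train)
    model <- u1$model
    u2 <- convUnitForward(model, u1$A, paste0("dec", l, "_2"), lev$conv, K,
                          train)
    model <- u2$model
    cache$dec[[l]] <- list(Xup = x, u1 = u1$cache, u2 = u2$cache)
    x <- u2$A
  }
  Z <- conv1Forward(x, model$params$final_W, model$params$final_b)
  P <- softmaxForward(Z)
  cache$final <- list(X = x)
  cache$P <- P
  list(probs = P, cache = cache, model = model)
}

unetBackward <- function(model, cache, dP) {
  config <- model$config
  d <- config$depth
  plans <- getNetPlans(cache$shape, cache$B, d)
  K <- plans$K; P2 <- plans$P2
  grads <- list()
  dZ <- softmaxBackward(dP, cache$P)
  fb <- conv1Backward(dZ, cache$final$X, model$params$final_W)
  grads$final_W <- fb$dW
  grads$final_b <- fb$db
  dx <- fb$dX
  for (l in seq_len(d)) {
    lev <- plans$levels[[l]]
    cc <- cache$dec[[l]]
    r2 <- convUnitBackward(model, dx, paste0("dec", l, "_2"), cc$u2,
                           lev$conv, K, grads)
    grads <- r2$grads
    r1 <- convUnitBackward(model, r2$dX, paste0("dec", l, "_1"), cc$u1,
                           lev$conv, K, grads)
    grads <- r1$grads
    f <- unetFilters(config, l)
    dskip <- r1$dX[, seq_len(f), drop = FALSE]
    dup <- r1$dX[, f + seq_len(f), drop = FALSE]
    ub <- upconvBackward(dup, cc$Xup,
                         model$params[[paste0("dec", l, "_up_W")]],
                         lev$pool, P2)
    grads[[paste0("dec", l, "_up_W")]] <- ub$dW
    grads[[paste0("dec", l, "_up_b")]] <- ub$db
    cache$enc[[l]]$dskip <- dskip
    dx <- ub$dX
  }
  if (config$dropout > 0 && !is.null(cache$drop[["bot"]]))
    dx <- dx * cache$drop[["bot"]]
  levB <- plans$levels[[d + 1]]
  r2 <- convUnitBackward(model, dx, "bot_2", cache$bot$u2, levB$conv, K,
                         grads)
  grads <- r2$grads
  r1 <- convUnitBackward(model, r2$dX, "bot_1", cache$bot$u1, levB$conv, K,
                         grads)
  grads <- r1$grads
  dx <- r1$dX
  for (l in rev(seq_len(d))) {
    lev <- plans$levels[[l]]
    cc <- cache$enc[[l]]
    da <- poolBackward(dx, cc$amax, lev$pool, nrow(lev$conv)) + cc$dskip
    if (config$dropout > 0 && !is.null(cache$drop[[paste0("enc", l)]]))
      da <- da * cache$drop[[paste0("enc", l)]]
    r2 <- convUnitBackward(model, da, paste0("enc", l, "_2"), cc$u2,
                           lev$conv, K, grads)
    grads <- r2$grads
    r1 <- convUnitBackward(model, r2$dX, paste0("enc", l, "_1"), cc$u1,
                           lev$conv, K, grads)
    grads <- r1$grads
    dx <- r1$dX
  }
  grads
}

## ---- architecture registry -------------------------------------------------

#' Register a model architecture
#'
#' An architecture is a list of three functions forming the backend-neutral
#' model contract: `build(config, seed)` returning a list with at least
#' `params` (named list of numeric arrays) and optionally `bnState`;
#' `forward(model, X, shape, B, train)` returning
#' `list(probs, cache, model)` where `probs` is an
#' `(B * prod(shape)) x nClasses` matrix of per-voxel class probabilities;
#' and `backward(model, cache, dProbs)` returning gradients named like
#' `model$params`.  Registered architectures are selectable by name from
#' the pipeline configuration; the bundled `"unet"` ships at load time.
#'
#' @param name architecture name.
#' @param architecture list with `build`, `forward`, `backward`.
#' @param overwrite replace an existing entry instead of erroring.
#' @return the name, invisibly.
#' @export
registerArchitecture <- function(name, architecture, overwrite = FALSE) {
  if (!overwrite &&
      exists(name, envir = .voxseg$architectures, inherits = FALSE))
    voxsegError("configurationError",
                "architecture '%s' is already registered", name)
  need <- c("build", "forward", "backward")
  if (!all(need %in% names(architecture)) ||
      !all(vapply(architecture[need], is.function, logical(1))))
    voxsegError("validationError",
                "architecture must provide build, forward and backward functions")
  assign(name, architecture, envir = .voxseg$architectures)
  invisible(name)
}

#' Resolve a registered architecture by name
#' @param name architecture name.
#' @return the architecture list.
#' @export
resolveArchitecture <- function(name) {
  if (!exists(name, envir = .voxseg$architectures, inherits = FALSE))
    voxsegError("configurationError",
                "no architecture registered under '%s'", name)
  get(name, envir = .voxseg$architectures)
}

registerBuiltinArchitectures <- function() {
  registerArchitecture("unet", list(
    build = function(config, seed = 1L) {
      ini <- unetInit(config, seed)
      structure(list(arch = "unet", config = config, params = ini$params,
                     bnState = ini$bnState, opt = NULL),
                class = "voxModel")
    },
    forward = unetForward,
    backward = unetBackward), overwrite = TRUE)
  invisible()
}

#' Build the bundled configurable U-Net
#'
#' @param config a [unetConfig()].
#' @param inputShape optional spatial shape used to check the `2^depth`
#'   divisibility invariant up front (it is re-checked at every forward
#'   pass).
#' @param seed integer seeding the weight initialization.
#' @return a `voxModel` list (architecture `"unet"`).
#' @export
buildUNet <- function(config, inputShape = NULL, seed = 1L) {
  stopifnot(inherits(config, "unetConfig"))
  if (!is.null(inputShape)) {
    if (length(inputShape) != config$nDims)
      voxsegError("configurationError",
                  "inputShape rank differs from nDims")
    checkDivisibility(as.integer(inputShape), config$depth)
  }
  resolveArchitecture("unet")$build(config, seed)
}

#' Total number of trainable parameters of a model
#' @param model a `voxModel`.
#' @return integer count.
#' @export
countParams <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Run a model over a list of equally shaped patches
#'
#' Stacks patches into inference batches, runs the architecture forward in
#' evaluation mode and returns per-patch probability arrays with a trailing
#' class axis.
#'
#' @param model a `voxModel`.
#' @param patches list of arrays `c(spatial shape, inChannels)`.
#' @param batchSize inference batch size.
#' @return list of arrays `c(spatial shape, nClasses)`.
#' @export
predictPatches <- function(model, patches, batchSize = 2L) {
  arch <- resolveArchitecture(model$arch)
  shape <- spatialShape(patches[[1]])
  nvox <- prod(shape)
  C <- model$config$nClasses
  out <- vector("list", length(patches))
  i <- 1L
  while (i <= length(patches)) {
    j <- min(i + batchSize - 1L, length(patches))
    B <- j - i + 1L
    X <- do.call(rbind, lapply(patches[i:j],
                               function(p) matrix(p, nvox)))
    fw <- arch$forward(model, X, shape, B, train = FALSE)
    P <- fw$probs
    if (ncol(P) != C || nrow(P) != B * nvox ||
        any(abs(rowSums(P) - 1) > 1e-5) || any(P < -1e-8))
      voxsegError("validationError",
                  "architecture '%s' violates the probability shape contract",
                  model$arch)
    for (b in seq_len(B))
      out[[i + b - 1L]] <- array(P[(b - 1L) * nvox + seq_len(nvox), ],
                                 c(shape, C))
    i <- j + 1L
  }
  out
}

#' Save / load a fitted model
#'
#' Serializes the model object (architecture name, configuration, weights,
#' normalization state, optimizer state) to an `.rds` file.  Custom
#' architectures must be re-registered before a loaded model can predict;
#' the bundled `"unet"` always resolves.
#'
#' @param model a `voxModel`.
#' @param path file path.
#' @return `saveModel`: the path, invisibly; `loadModel`: the model.
#' @export
saveModel <- function(model, path) {
  stopifnot(inherits(model, "voxModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e)
    voxsegError("loadError", "cannot read model file '%s': %s", path,
                conditionMessage(e)))
  if (!inherits(model, "voxModel"))
    voxsegError("loadError", "'%s' does not contain a voxseg model", path)
  model
}
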