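## Native CPU engine for small encoder-decoder segmentation networks.
##
## Tensors are stored as dense matrices with one row per voxel (batch
## members stacked along the row axis, R column-major voxel order) and one
## column per channel.  Convolutions are evaluated as gather (im2col) +
## matrix product, which keeps every layer inside BLAS; gradients are
## hand-derived.  This is sized for desk-scale patches (tens of thousands
## of voxels), not for GPU-scale workloads.

## (nvox x K) gather table: row v, column k holds the linear index of the
## voxel at coords(v) + offsets[k, ], or 0 when that falls outside `shape`
neighborIndex <- function(shape, offsets) {
  nd <- length(shape)
  co <- coordGrid(shape)
  nvox <- nrow(co)
  K <- nrow(offsets)
  NI <- matrix(0L, nvox, K)
  strides <- cumprod(c(1, shape[-nd]))
  for (k in seq_len(K)) {
    lin <- rep(1, nvox)
    valid <- rep(TRUE, nvox)
    for (a in seq_len(nd)) {
      ca <- co[, a] + offsets[k, a]
      valid <- valid & ca >= 1 & ca <= shape[a]
      lin <- lin + (ca - 1) * strides[a]
    }
    lin[!valid] <- 0
    NI[, k] <- as.integer(lin)
  }
  NI
}

## stack a per-volume index table across B batch members (0 stays 0)
stackIndex <- function(NI, nvox, B) {
  if (B == 1) return(NI)
  out <- vector("list", B)
  for (b in seq_len(B)) {
    M <- NI + (b - 1L) * as.integer(nvox)
    M[NI == 0L] <- 0L
    out[[b]] <- M
  }
  do.call(rbind, out)
}

## per-(shape, batch) index plans for all resolution levels of a network
## with `depth` pooling steps; memoized in the package environment
getNetPlans <- function(shape, B, depth) {
  key <- paste(c(shape, "b", B, "d", depth), collapse = "_")
  if (is.null(.voxseg$planCache))
    .voxseg$planCache <- new.env(parent = emptyenv())
  if (!is.null(.voxseg$planCache[[key]])) return(.voxseg$planCache[[key]])
  nd <- length(shape)
  kernOff <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  poolOff <- as.matrix(do.call(expand.grid, rep(list(0:1), nd)))
  levels <- vector("list", depth + 1)
  s <- as.integer(shape)
  for (l in seq_len(depth + 1)) {
    nvox <- prod(s)
    lev <- list(shape = s, nvox = nvox,
                conv = stackIndex(neighborIndex(s, kernOff), nvox, B))
    if (l <= depth) {
      if (any(s %% 2L != 0L))
        voxsegError("configurationError",
                    "spatial shape %s not divisible by 2 at level %d (axis %s)",
                    paste(s, collapse = "x"), l,
                    paste(which(s %% 2L != 0L), collapse = ","))
      sOut <- s %/% 2L
      ## input linear indices of each 2^nd pooling window, one row per
      ## output voxel; also the inverse map used by transposed convolution
      coOut <- coordGrid(sOut)
      strides <- cumprod(c(1, s[-nd]))
      PI <- matrix(0L, prod(sOut), nrow(poolOff))
      for (k in seq_len(nrow(poolOff))) {
        lin <- rep(1, prod(sOut))
        for (a in seq_len(nd))
          lin <- lin + (2 * coOut[, a] - 2 + poolOff[k, a]) * strides[a]
        PI[, k] <- as.integer(lin)
      }
      lev$pool <- stackIndex(PI, nvox, B)        # values index level-l rows
      lev$poolOutRows <- prod(sOut)
      s <- sOut
    }
    levels[[l]] <- lev
  }
  plans <- list(levels = levels, B = B, nd = nd,
                K = nrow(kernOff), P2 = nrow(poolOff))
  .voxseg$planCache[[key]] <- plans
  plans
}

## ---- primitive layers ------------------------------------------------------

im2col <- function(X, NI, K) {
  ci <- ncol(X)
  Xz <- rbind(0, X)
  G <- Xz[as.vector(NI) + 1L, , drop = FALSE]   # (nrow*K, ci)
  dim(G) <- c(nrow(NI), K * ci)
  G
}

convForward <- function(X, W, b, NI, K) {
  Xcol <- im2col(X, NI, K)
  Y <- Xcol %*% W
  Y + rep(b, each = nrow(Y))
}

convBackward <- function(dY, X, W, NI, K) {
  Xcol <- im2col(X, NI, K)
  dW <- crossprod(Xcol, dY)
  db <- colSums(dY)
  dXcol <- tcrossprod(dY, W)                     # (nrow, K*ci)
  ci <- ncol(X)
  dim(dXcol) <- c(nrow(X), K, ci)
  dX <- matrix(0, nrow(X), ci)
  for (k in seq_len(K)) {
    tgt <- NI[, k]
    ok <- tgt > 0L
    if (any(ok))
      dX[tgt[ok], ] <- dX[tgt[ok], ] + dXcol[ok, k, ]
  }
  list(dX = dX, dW = dW, db = db)
}

conv1Forward <- function(X, W, b) X %*% W + rep(b, each = nrow(X))

conv1Backward <- function(dY, X, W)
  list(dX = tcrossprod(dY, W), dW = crossprod(X, dY), db = colSums(dY))

reluForward <- function(X) pmax(X, 0)
reluBackward <- function(dY, X) dY * (X > 0)

poolForward <- function(X, PI, P2) {
  nout <- nrow(PI)
  ci <- ncol(X)
  Y <- X[PI[, 1], , drop = FALSE]
  amax <- matrix(1L, nout, ci)
  for (k in 2:P2) {
    cand <- X[PI[, k], , drop = FALSE]
    upd <- cand > Y
    Y[upd] <- cand[upd]
    amax[upd] <- k
  }
  list(Y = Y, amax = amax)
}

poolBackward <- function(dY, amax, PI, nin) {
  nout <- nrow(PI)
  ci <- ncol(dY)
  rowsel <- PI[cbind(rep(seq_len(nout), times = ci), as.vector(amax))]
  dX <- matrix(0, nin, ci)
  dX[rowsel + (rep(seq_len(ci), each = nout) - 1L) * nin] <- as.vector(dY)
  dX
}

## transposed convolution, kernel 2 stride 2: every (input voxel, offset)
## pair owns exactly one output voxel, given by the pooling gather table
upconvForward <- function(X, W, b, PI, P2, nout) {
  cout <- dim(W)[2]
  Y <- matrix(0, nout, cout)
  for (k in seq_len(P2))
    Y[PI[, k], ] <- X %*% W[, , k]
  Y + rep(b, each = nout)
}

upconvBackward <- function(dY, X, W, PI, P2) {
  ci <- dim(W)[1]; cout <- dim(W)[2]
  dX <- matrix(0, nrow(X), ci)
  dW <- array(0, dim(W))
  for (k in seq_len(P2)) {
    dYk <- dY[PI[, k], , drop = FALSE]
    dX <- dX + tcrossprod(dYk, W[, , k])
    dW[, , k] <- crossprod(X, dYk)
  }
  list(dX = dX, dW = dW, db = colSums(dY))
}

bnForward <- function(X, gamma, beta, run, train, momentum = 0.9,
                      eps = 1e-5) {
  if (train) {
    mu <- colMeans(X)
    xc <- X - rep(mu, each = nrow(X))
    v <- colMeans(xc^2)
    run$mean <- momentum * run$mean + (1 - momentum) * mu
    run$var <- momentum * run$var + (1 - momentum) * v
  } else {
    mu <- run$mean; v <- run$var
    xc <- X - rep(mu, each = nrow(X))
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv, each = nrow(X))
  Y <- xhat * rep(gamma, each = nrow(X)) + rep(beta, each = nrow(X))
  list(Y = Y, xhat = xhat, inv = inv, run = run)
}

bnBackward <- function(dY, cache, gamma) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  g <- rep(gamma * cache$inv, each = n)
  dX <- g * (dY - rep(dbeta / n, each = n) -
               cache$xhat * rep(dgamma / n, each = n))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

dropoutForward <- function(X, rate) {
  keep <- 1 - rate
  mask <- (matrix(stats::runif(length(X)), nrow(X)) < keep) / keep
  list(Y = X * mask, mask = mask)
}

softmaxForward <- function(Z) {
  mx <- Z[, 1]
  for (c in seq_len(ncol(Z))[-1]) mx <- pmax(mx, Z[, c])
  E <- exp(Z - mx)
  E / rowSums(E)
}

softmaxBackward <- function(dP, P) P * (dP - rowSums(dP * P))

## He-normal weight initialization
heInit <- function(fanIn, dims) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fanIn)), dims)
}

## ---- Adam optimizer --------------------------------------------------------

adamInit <- function(params) {
  list(t = 0,
       m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
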