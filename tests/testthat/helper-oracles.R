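## Independent brute-force oracles used across the suite.  These deliberately
## re-derive results by enumeration / integer counting, not by calling the
## package's own vectorized implementations.

## window start offsets along one axis, accumulated step by step
oracleAxisOffsets <- function(n, p, o) {
  s <- p - o
  off <- integer(0)
  x <- 0L
  while (x + p <= n) {
    off <- c(off, x)
    x <- x + s
  }
  if (off[length(off)] + p < n) off <- c(off, n - p)
  unique(off)
}

## full grid by explicit nested looping (lexicographic, first axis slowest)
oracleGrid <- function(shape, P, O) {
  axes <- lapply(seq_along(shape),
                 function(a) oracleAxisOffsets(shape[a], P[a], O[a]))
  out <- matrix(0L, 0, length(shape))
  rec <- function(prefix, a) {
    if (a > length(shape)) {
      out <<- rbind(out, prefix)
      return(invisible())
    }
    for (x in axes[[a]]) rec(c(prefix, x), a + 1L)
  }
  rec(integer(0), 1L)
  dimnames(out) <- NULL
  out
}

## voxel coverage count of a set of windows
oracleCoverage <- function(shape, offsets, P) {
  cnt <- array(0L, shape)
  for (i in seq_len(nrow(offsets))) {
    idx <- lapply(seq_along(shape), function(a)
      seq.int(offsets[i, a] + 1L, offsets[i, a] + P[a]))
    cnt <- do.call(`[<-`, c(list(cnt), idx,
                            list(value = do.call(`[`, c(list(cnt), idx)) + 1L)))
  }
  cnt
}

## number of windows containing at least one foreground voxel
oracleForegroundWindows <- function(seg, offsets, P, background = 0L) {
  hits <- 0L
  for (i in seq_len(nrow(offsets))) {
    idx <- lapply(seq_along(dim(seg)), function(a)
      seq.int(offsets[i, a] + 1L, offsets[i, a] + P[a]))
    w <- do.call(`[`, c(list(seg), idx))
    if (any(w != background)) hits <- hits + 1L
  }
  hits
}

## integer TP/FP/FN confusion counting on hard label masks
oracleConfusion <- function(truth, pred, cls) {
  t <- truth == cls
  p <- pred == cls
  c(tp = sum(t & p), fp = sum(!t & p), fn = sum(t & !p))
}

## smoothed overlap scores from integer counts
oracleDiceFromCounts <- function(cc, eps) {
  (2 * cc["tp"] + eps) / (2 * cc["tp"] + cc["fp"] + cc["fn"] + eps)
}
oracleJaccardFromCounts <- function(cc, eps) {
  (cc["tp"] + eps) / (cc["tp"] + cc["fp"] + cc["fn"] + eps)
}
oracleTverskyIndexFromCounts <- function(cc, alpha, beta, eps) {
  (cc["tp"] + eps) /
    (cc["tp"] + alpha * cc["fp"] + beta * cc["fn"] + eps)
}

## random hard one-hot mask pair of a given shape / class count
randomMaskPair <- function(shape, C) {
  t <- array(sample(0:(C - 1), prod(shape), replace = TRUE), shape)
  p <- array(sample(0:(C - 1), prod(shape), replace = TRUE), shape)
  list(truth = t, pred = p,
       truthOH = oneHotEncode(t, C), predOH = oneHotEncode(p, C))
}
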