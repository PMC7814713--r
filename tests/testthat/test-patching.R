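test_that("patch grid matches brute-force enumeration and covers all voxels", {
  set.seed(41)
  for (i in 1:40) {
    nd <- sample(2:3, 1)
    shape <- sample(6:40, nd, replace = TRUE)
    P <- pmin(shape, sample(2:16, nd, replace = TRUE))
    O <- vapply(P, function(p) sample(0:(p - 1), 1), integer(1))
    g <- computePatchGrid(shape, P, O)
    expect_equal(g, oracleGrid(shape, P, O))
    cov <- oracleCoverage(shape, g, P)
    expect_true(all(cov >= 1L))
    expect_true(all(g >= 0) &&
                  all(sweep(g, 2, shape - P, `<=`)))
  }
})

test_that("patch grid handles the large-CT reference geometry and edges", {
  g <- computePatchGrid(c(400, 512, 512), c(128, 128, 128), c(0, 0, 0))
  expect_equal(nrow(g), 64L)
  expect_equal(sort(unique(g[, 1])), c(0L, 128L, 256L, 272L))
  expect_equal(sort(unique(g[, 2])), c(0L, 128L, 256L, 384L))
  ## degenerate: patch fills the volume exactly
  expect_equal(computePatchGrid(c(8, 8), c(8, 8), c(3, 3)),
               matrix(0L, 1, 2))
  ## stride-2 enumeration
  g2 <- computePatchGrid(c(8, 8), c(4, 4), c(2, 2))
  expect_equal(nrow(g2), 9L)
  expect_equal(sort(unique(g2[, 1])), c(0L, 2L, 4L))
  expect_error(computePatchGrid(c(8, 8), c(9, 4), c(0, 0)),
               class = "patchTooLargeError")
})

test_that("extracted patches are voxel-exact windows", {
  ## constant volume: every patch constant
  v <- array(7, c(10, 12, 1))
  g <- computePatchGrid(c(10, 12), c(4, 4), c(1, 1))
  ps <- extractPatches(v, g, c(4, 4))
  expect_true(all(vapply(patchArrays(ps),
                         function(p) all(p == 7), logical(1))))
  ## flattened-index volume: each patch corner equals its offset's index
  shape <- c(6, 5, 4)
  v <- array(seq_len(prod(shape)), c(shape, 1))
  g <- computePatchGrid(shape, c(2, 2, 2), c(0, 0, 0))
  ps <- extractPatches(v, g, c(2, 2, 2))
  for (i in seq_len(nPatches(ps))) {
    off <- patchOffsets(ps)[i, ]
    expect_equal(patchArrays(ps)[[i]][1, 1, 1, 1],
                 1 + off[1] + off[2] * shape[1] +
                   off[3] * shape[1] * shape[2])
  }
  ## non-overlapping reassembly is the identity
  shape <- c(8, 6)
  v <- array(rnorm(prod(shape)), c(shape, 1))
  g <- computePatchGrid(shape, c(4, 3), c(0, 0))
  ps <- extractPatches(v, g, c(4, 3))
  rec <- array(0, c(shape, 1))
  for (i in seq_len(nPatches(ps))) {
    off <- patchOffsets(ps)[i, ]
    rec[off[1] + 1:4, off[2] + 1:3, 1] <- patchArrays(ps)[[i]][, , 1]
  }
  expect_identical(rec, v)
})

test_that("blank-patch filtering equals the exhaustive window scan", {
  set.seed(42)
  for (i in 1:30) {
    nd <- sample(2:3, 1)
    shape <- sample(6:20, nd, replace = TRUE)
    P <- pmin(shape, sample(2:6, nd, replace = TRUE))
    O <- vapply(P, function(p) sample(0:(p - 1), 1), integer(1))
    seg <- array(0L, shape)
    nfg <- sample(0:5, 1)
    seg[sample(prod(shape), nfg)] <- 1L
    img <- array(rnorm(prod(shape)), c(shape, 1))
    g <- computePatchGrid(shape, P, O)
    ips <- extractPatches(img, g, P)
    sps <- extractPatches(seg, g, P)
    fl <- filterBlankPatches(ips, sps)
    expect_equal(nPatches(fl$segmentation),
                 oracleForegroundWindows(seg, g, P))
    expect_identical(patchOffsets(fl$image), patchOffsets(fl$segmentation))
  }
  ## all background -> nothing retained; single labeled voxel at the origin
  seg <- array(0L, c(8, 8))
  img <- array(0, c(8, 8, 1))
  g <- computePatchGrid(c(8, 8), c(4, 4), c(0, 0))
  fl <- filterBlankPatches(extractPatches(img, g, c(4, 4)),
                           extractPatches(seg, g, c(4, 4)))
  expect_equal(nPatches(fl$image), 0L)
  seg[1, 1] <- 2L
  fl <- filterBlankPatches(extractPatches(img, g, c(4, 4)),
                           extractPatches(seg, g, c(4, 4)))
  expect_equal(nPatches(fl$image), 1L)
  expect_equal(patchOffsets(fl$image)[1, ], c(0L, 0L))
})

test_that("random crops are deterministic, valid and uniform", {
  img <- array(rnorm(2 * 5 * 1), c(2, 5, 1))
  seg <- array(0L, c(2, 5))
  c1 <- randomCrop(img, seg, c(1, 5), seed = 77)
  c2 <- randomCrop(img, seg, c(1, 5), seed = 77)
  expect_identical(c1, c2)
  ## volume shape == patch shape: the only crop
  cfull <- randomCrop(img, seg, c(2, 5), seed = 1)
  expect_identical(cfull$image, img)
  expect_equal(cfull$offset, c(0L, 0L))
  ## 2-wide axis, patch covers 1 voxel: both offsets ~ 0.5 each
  offs <- vapply(1:10000, function(i)
    randomCrop(img, seg, c(1, 5), seed = i)$offset[1], integer(1))
  expect_equal(mean(offs == 0), 0.5, tolerance = 0.04)
  expect_error(randomCrop(img, seg, c(3, 5)),
               class = "patchTooLargeError")
})

test_that("mean merging averages overlaps and round-trips one-hot truth", {
  ## two windows with constant probabilities 0.2 / 0.6 -> 0.4 in the overlap
  offs <- matrix(c(0L, 4L), 2, 1)
  p1 <- array(0.2, c(8, 1)); p2 <- array(0.6, c(8, 1))
  ps <- new("PatchSet", offsets = offs, patches = list(p1, p2),
            sourceShape = 12L)
  m <- mergePatchPredictions(ps, 12L, 1L)
  expect_equal(as.vector(m), c(rep(0.2, 4), rep(0.4, 4), rep(0.6, 4)))
  ## lossless round-trip on one-hot ground truth, overlapping and not
  set.seed(43)
  for (i in 1:50) {
    nd <- sample(2:3, 1)
    shape <- sample(6:24, nd, replace = TRUE)
    P <- pmin(shape, sample(3:8, nd, replace = TRUE))
    O <- vapply(P, function(p) sample(0:(p - 1), 1), integer(1))
    C <- sample(2:4, 1)
    seg <- array(sample(0:(C - 1), prod(shape), TRUE), shape)
    oh <- oneHotEncode(seg, C)
    g <- computePatchGrid(shape, P, O)
    ps <- extractPatches(oh, g, P)
    merged <- mergePatchPredictions(ps, shape, C)
    expect_identical(oneHotDecode(merged), seg)
  }
})

test_that("mean merging is permutation-invariant in patch order", {
  set.seed(44)
  shape <- c(10, 9)
  g <- computePatchGrid(shape, c(4, 4), c(2, 2))
  probs <- lapply(seq_len(nrow(g)),
                  function(i) array(runif(4 * 4 * 2), c(4, 4, 2)))
  ps <- new("PatchSet", offsets = g, patches = probs,
            sourceShape = as.integer(shape))
  perm <- sample(nrow(g))
  ps2 <- new("PatchSet", offsets = g[perm, , drop = FALSE],
             patches = probs[perm], sourceShape = as.integer(shape))
  m1 <- mergePatchPredictions(ps, shape, 2L)
  m2 <- mergePatchPredictions(ps2, shape, 2L)
  expect_lt(max(abs(m1 - m2)), 1e-12)
})

test_that("uncovered voxels are reported as a coverage error", {
  ps <- new("PatchSet", offsets = matrix(0L, 1, 1),
            patches = list(array(0.5, c(4, 1))), sourceShape = 8L)
  expect_error(mergePatchPredictions(ps, 8L, 1L), class = "coverageError")
})
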