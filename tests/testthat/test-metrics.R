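test_that("overlap metrics agree with integer confusion counting", {
  set.seed(51)
  eps <- 1e-5
  for (i in 1:120) {
    C <- sample(2:4, 1)
    shape <- sample(3:8, sample(2:3, 1), replace = TRUE)
    mp <- randomMaskPair(shape, C)
    cw <- classwiseDice(mp$truthOH, mp$predOH, eps)
    jc <- jaccardIndex(mp$truthOH, mp$predOH, eps)
    tv <- tverskyLoss(mp$truthOH, mp$predOH, tverskyParams(0.3, 0.7, eps))
    tiSum <- 0
    for (cls in 0:(C - 1)) {
      cc <- oracleConfusion(mp$truth, mp$pred, cls)
      expect_equal(cw$perClass[cls + 1],
                   unname(oracleDiceFromCounts(cc, eps)), tolerance = 1e-6)
      expect_equal(jc$perClass[cls + 1],
                   unname(oracleJaccardFromCounts(cc, eps)),
                   tolerance = 1e-6)
      tiSum <- tiSum + oracleTverskyIndexFromCounts(cc, 0.3, 0.7, eps)
    }
    expect_equal(tv, unname(1 - tiSum / C), tolerance = 1e-6)
    ## pooled soft Dice from total counts
    tpAll <- sum(mp$truth == mp$pred)
    expect_equal(softDice(mp$truthOH, mp$predOH, eps),
                 (2 * tpAll + eps) / (2 * prod(shape) + eps),
                 tolerance = 1e-6)
  }
})

test_that("hand-computed worked examples hold", {
  ## binary 4x4: |truth| = 6, |pred| = 6, overlap 4 -> Dice 8/12
  truth <- array(0L, c(4, 4)); truth[1:6] <- 1L
  pred <- array(0L, c(4, 4)); pred[3:8] <- 1L
  tOH <- oneHotEncode(truth, 2); pOH <- oneHotEncode(pred, 2)
  expect_equal(classwiseDice(tOH, pOH, 1e-12)$perClass[2], 2 / 3,
               tolerance = 1e-9)
  ## Tversky index with tp=4, fp=1, fn=3, alpha=0.3, beta=0.7 -> 0.625
  t1 <- array(c(rep(1, 7), 0), c(8, 1))
  p1 <- array(c(rep(1, 4), 0, 0, 0, 1), c(8, 1))
  ti <- 1 - tverskyLoss(t1, p1, tverskyParams(0.3, 0.7, 1e-12))
  expect_equal(ti, 0.625, tolerance = 1e-9)
  ## Jaccard with tp=4, fp=2, fn=2 -> 0.5
  t2 <- array(c(rep(1, 6), 0, 0, 0, 0), c(10, 1))
  p2 <- array(c(rep(1, 4), 0, 0, 1, 1, 0, 0), c(10, 1))
  expect_equal(jaccardIndex(t2, p2, 1e-12)$perClass[1], 0.5,
               tolerance = 1e-9)
  ## perfect and disjoint predictions
  expect_equal(softDice(tOH, tOH), 1, tolerance = 1e-6)
  tA <- array(c(rep(1, 100), rep(0, 100)), c(200, 1))
  tB <- array(c(rep(0, 100), rep(1, 100)), c(200, 1))
  expect_lt(softDice(tA, tB), 1e-6)
  expect_lt(tverskyLoss(tOH, tOH), 1e-5)
})

test_that("algebraic identities: Tversky(.5,.5) = Dice loss, J = D/(2-D)", {
  set.seed(52)
  for (i in 1:25) {
    C <- sample(2:4, 1)
    mp <- randomMaskPair(sample(4:8, 3, replace = TRUE), C)
    tv <- tverskyLoss(mp$truthOH, mp$predOH, tverskyParams(0.5, 0.5, 1e-12))
    dl <- 1 - classwiseDice(mp$truthOH, mp$predOH, 1e-12)$mean
    expect_equal(tv, dl, tolerance = 1e-9)
    D <- classwiseDice(mp$truthOH, mp$predOH, 1e-12)$perClass
    J <- jaccardIndex(mp$truthOH, mp$predOH, 1e-12)$perClass
    expect_equal(J, D / (2 - D), tolerance = 1e-9)
  }
})

test_that("absent classes score 1 under the smoothed formula", {
  truth <- array(c(0L, 1L, 1L, 0L), c(2, 2))
  cw <- classwiseDice(oneHotEncode(truth, 3), oneHotEncode(truth, 3))
  expect_equal(cw$perClass[3], 1)   # class 2 absent from both masks
})

test_that("combined cross-entropy minus Dice behaves at its anchors", {
  truth <- oneHotEncode(array(sample(0:1, 64, TRUE), c(8, 8)), 2)
  ## perfect (clipped) prediction -> about 0 - 1 = -1
  expect_equal(crossentropyDice(truth, truth), -1, tolerance = 1e-3)
  ## uniform prediction: CE = log 2; Dice computable from counts
  unif <- array(0.5, dim(truth))
  n1 <- sum(truth[, , 2]); n <- 64
  dice <- (2 * 0.5 * n + 1e-5) / (n + n + 1e-5)
  expect_equal(crossentropyDice(truth, unif), log(2) - dice,
               tolerance = 1e-6)
  ## compositional: equals CE and Dice computed independently
  set.seed(53)
  p <- array(runif(length(truth), 0.05, 0.95), dim(truth))
  ce <- -mean(rowSums(matrix(truth, ncol = 2) *
                        log(matrix(p, ncol = 2))))
  expect_equal(crossentropyDice(truth, p), ce - softDice(truth, p),
               tolerance = 1e-9)
})

test_that("scores are permutation-invariant, bounded, and monotone", {
  set.seed(54)
  mp <- randomMaskPair(c(6, 6, 2), 3)
  perm <- sample(72)
  tP <- array(matrix(mp$truthOH, ncol = 3)[perm, ], c(72, 3))
  pP <- array(matrix(mp$predOH, ncol = 3)[perm, ], c(72, 3))
  expect_equal(softDice(mp$truthOH, mp$predOH), softDice(tP, pP))
  expect_equal(classwiseDice(mp$truthOH, mp$predOH)$perClass,
               classwiseDice(tP, pP)$perClass)
  expect_equal(tverskyLoss(mp$truthOH, mp$predOH), tverskyLoss(tP, pP))
  for (i in 1:10) {
    mp <- randomMaskPair(c(5, 5), 2)
    d <- classwiseDice(mp$truthOH, mp$predOH)$perClass
    j <- jaccardIndex(mp$truthOH, mp$predOH)$perClass
    tv <- tverskyLoss(mp$truthOH, mp$predOH,
                      tverskyParams(runif(1), runif(1)))
    expect_true(all(d >= 0 & d <= 1) && all(j >= 0 & j <= 1))
    expect_true(tv >= 0 && tv <= 1)
  }
  ## flipping one correct foreground voxel never increases Dice
  truth <- array(c(rep(1L, 10), rep(0L, 15)), c(25))
  pred <- truth
  d0 <- classwiseDice(oneHotEncode(truth, 2), oneHotEncode(pred, 2))$perClass[2]
  pred[1] <- 0L
  d1 <- classwiseDice(oneHotEncode(truth, 2), oneHotEncode(pred, 2))$perClass[2]
  expect_lt(d1, d0)
})

test_that("the Tversky gradient matches finite differences", {
  set.seed(55)
  truth <- oneHotEncode(array(sample(0:2, 27, TRUE), c(3, 3, 3)), 3)
  p <- matrix(runif(27 * 3, 0.1, 0.9), 27)
  p <- p / rowSums(p)
  p <- array(p, c(3, 3, 3, 3))
  g <- tverskyLossGrad(truth, p)
  eps <- 1e-6
  for (i in sample(length(p), 8)) {
    pp <- p; pp[i] <- pp[i] + eps
    pm <- p; pm[i] <- pm[i] - eps
    num <- (tverskyLoss(truth, pp) - tverskyLoss(truth, pm)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("the metric registry resolves, rejects duplicates and integrates", {
  nm <- paste0("acc_", as.integer(stats::runif(1, 1, 1e6)))
  registerMetric(nm, function(truth, pred)
    mean(oneHotDecode(truth) == oneHotDecode(pred)))
  m <- resolveMetric(nm)
  mp <- randomMaskPair(c(4, 4), 2)
  expect_equal(m$fn(mp$truthOH, mp$predOH), mean(mp$truth == mp$pred))
  expect_error(registerMetric(nm, function(t, p) 0),
               class = "configurationError")
  expect_error(resolveMetric("no_such_metric"),
               class = "configurationError")
  expect_true(all(c("dice_soft", "dice_classwise", "jaccard", "tversky",
                    "crossentropy_dice") %in% listMetrics()))
})

test_that("confusionCounts partitions every voxel for every class", {
  set.seed(56)
  mp <- randomMaskPair(c(7, 5), 3)
  cc <- confusionCounts(mp$truth, mp$pred, 3)
  expect_true(all(rowSums(cc[, c("tp", "fp", "fn", "tn")]) == 35))
  for (cls in 0:2) {
    o <- oracleConfusion(mp$truth, mp$pred, cls)
    expect_equal(unlist(cc[cc$class == cls, c("tp", "fp", "fn")]),
                 o, ignore_attr = TRUE)
  }
})
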