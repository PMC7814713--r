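test_that("network outputs are valid probability fields across a config grid", {
  set.seed(81)
  for (nd in 2:3) {
    for (d in 1:2) {
      for (f0 in c(2, 4)) {
        cfg <- unetConfig(nDims = nd, inChannels = 1, nClasses = 3,
                          baseFilters = f0, depth = d)
        m <- buildUNet(cfg, seed = d * 10 + f0)
        shape <- rep(ifelse(nd == 3, 8L, 16L), nd)
        X <- matrix(rnorm(prod(shape)), ncol = 1)
        fw <- unetForward(m, X, shape, B = 1)
        expect_equal(dim(fw$probs), c(prod(shape), 3L))
        expect_lt(max(abs(rowSums(fw$probs) - 1)), 1e-5)
        expect_gte(min(fw$probs), 0)
      }
    }
  }
  ## deeper 3D case at batch 2
  cfg <- unetConfig(3, 1, 2, baseFilters = 2, depth = 3)
  m <- buildUNet(cfg, seed = 2)
  X <- matrix(rnorm(2 * 8^3), ncol = 1)
  fw <- unetForward(m, X, c(8, 8, 8), B = 2)
  expect_equal(dim(fw$probs), c(2 * 512L, 2L))
  expect_lt(max(abs(rowSums(fw$probs) - 1)), 1e-5)
})

test_that("divisibility violations raise configuration errors naming the axis", {
  cfg <- unetConfig(3, 1, 3, baseFilters = 8, depth = 4)
  expect_silent(buildUNet(cfg, inputShape = c(80, 160, 160)))
  err <- tryCatch(buildUNet(cfg, inputShape = c(20, 160, 160)),
                  configurationError = function(e) e)
  expect_s3_class(err, "configurationError")
  expect_match(conditionMessage(err), "axis 1")
  m <- buildUNet(unetConfig(2, 1, 2, 2, depth = 2), seed = 1)
  expect_error(unetForward(m, matrix(0, 60, 1), c(10, 6), 1),
               class = "configurationError")
})

test_that("parameter counts match the analytic layer-by-layer derivation", {
  ## 2D, depth 1, f0 = 2, C = 2, 1 input channel, no batch norm
  cfg <- unetConfig(2, 1, 2, baseFilters = 2, depth = 1)
  m <- buildUNet(cfg, seed = 1)
  K <- 9
  count <- (K * 1 * 2 + 2) + (K * 2 * 2 + 2) +      # encoder level 1
    (K * 2 * 4 + 4) + (K * 4 * 4 + 4) +             # bottleneck
    (4 * 2 * 4 + 2) +                               # transposed conv 2x2
    (K * 4 * 2 + 2) + (K * 2 * 2 + 2) +             # decoder level 1
    (2 * 2 + 2)                                     # 1x1 classifier
  expect_equal(countParams(m), count)
  ## doubling base filters strictly increases capacity
  m2 <- buildUNet(unetConfig(2, 1, 2, baseFilters = 4, depth = 1))
  expect_gt(countParams(m2), countParams(m))
  ## batch norm adds 2 parameters per convolution channel
  mbn <- buildUNet(unetConfig(2, 1, 2, baseFilters = 2, depth = 1,
                              batchNorm = TRUE))
  expect_equal(countParams(mbn), count + 2 * (2 + 2 + 4 + 4 + 2 + 2))
})

test_that("the analytic gradient agrees with finite differences", {
  set.seed(82)
  cfg <- unetConfig(2, 1, 2, baseFilters = 2, depth = 1, batchNorm = TRUE)
  m <- buildUNet(cfg, seed = 3)
  shape <- c(6, 6); nvox <- 36L; B <- 2L
  X <- matrix(rnorm(B * nvox), ncol = 1)
  Tm <- matrix(0, B * nvox, 2)
  Tm[cbind(seq_len(B * nvox), sample(1:2, B * nvox, TRUE))] <- 1
  lossOf <- function(model) {
    fw <- unetForward(model, X, shape, B, train = TRUE)
    tverskyLoss(array(Tm, dim(Tm)), array(fw$probs, dim(fw$probs)))
  }
  fw <- unetForward(m, X, shape, B, train = TRUE)
  dP <- tverskyLossGrad(array(Tm, dim(Tm)), array(fw$probs, dim(fw$probs)))
  grads <- unetBackward(fw$model, fw$cache, matrix(dP, ncol = 2))
  eps <- 1e-5
  for (nm in c("enc1_1_W", "enc1_2_gamma", "bot_2_b", "dec1_up_W",
               "final_W")) {
    i <- sample(length(m$params[[nm]]), 1)
    mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
    mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
    num <- (lossOf(mp) - lossOf(mm)) / (2 * eps)
    expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("models survive a save/load round trip bit-for-bit", {
  tmp <- withr::local_tempdir()
  cfg <- unetConfig(3, 1, 3, baseFilters = 2, depth = 1)
  m <- buildUNet(cfg, seed = 7)
  X <- matrix(rnorm(4^3), ncol = 1)
  p1 <- unetForward(m, X, c(4, 4, 4), 1)$probs
  f <- file.path(tmp, "model.rds")
  saveModel(m, f)
  m2 <- loadModel(f)
  p2 <- unetForward(m2, X, c(4, 4, 4), 1)$probs
  expect_lt(max(abs(p1 - p2)), 1e-6)
  ## a truncated file yields a load error, not a partial model
  raw <- readBin(f, "raw", file.info(f)$size)
  writeBin(raw[1:20], file.path(tmp, "trunc.rds"))
  expect_error(loadModel(file.path(tmp, "trunc.rds")), class = "loadError")
  writeLines("{}", file.path(tmp, "x.rds"))
  expect_error(loadModel(file.path(tmp, "x.rds")), class = "loadError")
})

test_that("the architecture registry accepts custom builders and rejects abuse", {
  expect_identical(resolveArchitecture("unet")$forward, unetForward)
  expect_error(resolveArchitecture("resnet_of_theseus"),
               class = "configurationError")
  expect_error(registerArchitecture("unet", list()),
               class = "configurationError")
  expect_error(registerArchitecture("lobotomized", list(build = 1)),
               class = "validationError")
  ## a custom architecture violating the probability contract is caught
  nm <- paste0("bad_", as.integer(stats::runif(1, 1, 1e6)))
  registerArchitecture(nm, list(
    build = function(config, seed = 1)
      structure(list(arch = nm, config = config, params = list()),
                class = "voxModel"),
    forward = function(model, X, shape, B, train = FALSE)
      list(probs = matrix(2, nrow(X), model$config$nClasses),
           cache = NULL, model = model),
    backward = function(model, cache, dP) list()))
  bad <- resolveArchitecture(nm)$build(unetConfig(2, 1, 2, 2, 1))
  expect_error(predictPatches(bad, list(array(0, c(4, 4, 1)))),
               class = "validationError")
})

test_that("weight initialization is reproducible from the seed", {
  cfg <- unetConfig(2, 1, 2, baseFilters = 2, depth = 1)
  expect_identical(buildUNet(cfg, seed = 5)$params,
                   buildUNet(cfg, seed = 5)$params)
  expect_false(identical(buildUNet(cfg, seed = 5)$params,
                         buildUNet(cfg, seed = 6)$params))
})
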