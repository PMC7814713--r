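test_that("split plans satisfy partition and disjointness invariants", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(c(5, 10, 24, 120), 1)
    ids <- sprintf("s%03d", seq_len(n))
    mode <- sample(c("kfold", "loo", "percentage", "holdout"), 1)
    k <- sample(2:min(10, n), 1)
    fr <- runif(1, 0.2, 0.8)
    plan <- makeSplit(ids, mode, k = k, fraction = fr, seed = i)
    for (f in plan$folds) {
      expect_length(intersect(f$train, f$test), 0)
      expect_setequal(c(f$train, f$test), ids)
    }
    if (plan$mode == "kfold") {
      tests <- lapply(plan$folds, `[[`, "test")
      expect_setequal(unlist(tests), ids)
      expect_equal(sum(lengths(tests)), n)   # partition, no double use
      expect_lte(diff(range(lengths(tests))), 1)
    }
    if (plan$mode == "loo") {
      expect_length(plan$folds, n)
      expect_true(all(lengths(lapply(plan$folds, `[[`, "test")) == 1))
    }
  }
})

test_that("the canonical fold geometries come out exactly", {
  ids120 <- sprintf("ct%03d", 1:120)
  plan <- makeSplit(ids120, "kfold", k = 3, seed = 2)
  for (f in plan$folds) {
    expect_length(f$train, 80)
    expect_length(f$test, 40)
  }
  plan10 <- makeSplit(sprintf("x%02d", 1:10), "kfold", k = 3, seed = 3)
  expect_setequal(lengths(lapply(plan10$folds, `[[`, "test")), c(4, 3, 3))
  plan5 <- makeSplit(letters[1:5], "loo")
  expect_length(plan5$folds, 5)
  expect_error(makeSplit(letters[1:3], "kfold", k = 5),
               class = "validationError")
})

test_that("splits are seed-reproducible yet seed-sensitive", {
  ids <- sprintf("s%02d", 1:20)
  a <- makeSplit(ids, "kfold", k = 4, seed = 9)
  b <- makeSplit(ids, "kfold", k = 4, seed = 9)
  expect_identical(a, b)
  differs <- vapply(1:50, function(s)
    !identical(makeSplit(ids, "kfold", k = 4, seed = s)$folds,
               makeSplit(ids, "kfold", k = 4, seed = s + 1000)$folds),
    logical(1))
  expect_gt(mean(differs), 0.9)
})

test_that("detailed splits are copied verbatim and validated", {
  ids <- letters[1:6]
  plan <- makeSplit(ids, "detailed",
                    folds = list(list(train = c("a", "b", "c"),
                                      test = c("d", "e"))))
  expect_identical(plan$folds[[1]]$train, c("a", "b", "c"))
  expect_identical(plan$folds[[1]]$test, c("d", "e"))
  expect_error(
    makeSplit(ids, "detailed",
              folds = list(list(train = c("a", "b"), test = c("b", "c")))),
    class = "validationError")
  expect_error(
    makeSplit(ids, "detailed",
              folds = list(list(train = "a", test = "zz"))),
    class = "validationError")
})

test_that("dataset statistics report ranges and exact class frequencies", {
  tmp <- withr::local_tempdir()
  cfg <- smallPhantomConfig()
  manifest <- generatePhantomDataset(tmp, 3, cfg, seed = 7)
  iface <- niftiInterface(tmp)
  samples <- lapply(iface$listSamples(), iface$load)
  st <- datasetStatistics(samples, nClasses = 3)
  for (id in unique(manifest$sample_id)) {
    got <- st[st$sample_id == id & st$quantity == "class_count", ]
    expect_equal(got$value[order(got$class)],
                 manifest$count[manifest$sample_id == id])
    fr <- st[st$sample_id == id & st$quantity == "class_fraction", "value"]
    expect_equal(sum(fr), 1, tolerance = 1e-9)
  }
  ## all-background sample -> class-0 fraction 1
  bg <- imageSample("bg", array(0, c(4, 4, 4)),
                    segmentation = array(0L, c(4, 4, 4)))
  st2 <- datasetStatistics(list(bg), nClasses = 2)
  expect_equal(st2[st2$quantity == "class_fraction" & st2$class == 0,
                   "value"], 1)
  ## intensity range of a clipped dataset lies inside the clip window
  clipped <- lapply(samples, preprocessSample,
                    spec = preprocSpec(clipRange = c(0.2, 0.8),
                                       normalization = "none",
                                       nClasses = 3))
  st3 <- datasetStatistics(clipped, nClasses = 3)
  expect_gte(min(st3[st3$quantity == "intensity_min", "value"]), 0.2)
  expect_lte(max(st3[st3$quantity == "intensity_max", "value"]), 0.8)
})

test_that("cross-validation with a ground-truth oracle scores 1 everywhere", {
  withThresholdArch({
    tmp <- withr::local_tempdir()
    samples <- lapply(1:6, function(i)
      generatePhantom(smallPhantomConfig(noiseSd = 0), seed = 600 + i,
                      id = sprintf("ph%02d", i)))
    names(samples) <- vapply(samples, sampleId, character(1))
    plan <- makeSplit(names(samples), "kfold", k = 3, seed = 1)
    pre <- preprocSpec(normalization = "none", nClasses = 3)
    pc <- patchConfig(c(8, 8, 8), c(4, 4, 4))
    cv <- runCrossValidation(samples, plan, architecture = "threshold",
                             modelConfig = unetConfig(3, 1, 3, 2, 1),
                             preproc = pre, patchcfg = pc,
                             trainspec = trainSpec(epochs = 1,
                                                   learningRate = 1e-3),
                             metrics = c("dice_soft", "dice_classwise"),
                             outDir = tmp)
    expect_true(all(abs(cv$results$value - 1) < 1e-4))
    ## bookkeeping: fold rows + mean row per metric; files written
    expect_equal(nrow(cv$results), 6 * 2)
    expect_equal(nrow(cv$summary), (3 + 1) * 2)
    expect_setequal(unique(cv$summary$fold), c("1", "2", "3", "mean"))
    expect_true(file.exists(file.path(tmp, "cv_results.tsv")))
    expect_true(file.exists(file.path(tmp, "cv_summary.tsv")))
    ## orchestration drift check: recomputing the metric directly agrees
    s <- samples[[plan$folds[[1]]$test[1]]]
    stub <- resolveArchitecture("threshold")$build(unetConfig(3, 1, 3, 2, 1))
    pred <- predictSample(stub, s, pre, pc)
    direct <- softDice(oneHotEncode(s@segmentation, 3),
                       oneHotEncode(pred, 3))
    got <- cv$results[cv$results$sample_id == sampleId(s) &
                        cv$results$metric == "dice_soft", "value"]
    expect_equal(got, direct)
  })
})

test_that("cross-validation validates ids and ground truth", {
  samples <- list(a = generatePhantom(smallPhantomConfig(), seed = 1,
                                      id = "a"),
                  b = generatePhantom(smallPhantomConfig(), seed = 2,
                                      id = "b"))
  plan <- makeSplit(c("a", "b"), "detailed",
                    folds = list(list(train = "a", test = "b")))
  planBad <- structure(list(mode = "detailed", seed = 1L,
                            folds = list(list(train = "a", test = "zz"))),
                       class = "splitPlan")
  expect_error(
    runCrossValidation(samples, planBad, patchcfg = patchConfig(c(8, 8, 8))),
    class = "validationError")
  samples$b@segmentation <- NULL
  expect_error(
    runCrossValidation(samples, plan, patchcfg = patchConfig(c(8, 8, 8))),
    class = "validationError")
})

test_that("slice overlays render deterministically with correct geometry", {
  tmp <- withr::local_tempdir()
  s <- generatePhantom(smallPhantomConfig(), seed = 51)
  mask <- s@segmentation
  ## all-background overlay equals the plain grayscale render
  zero <- array(0L, dim(mask))
  p1 <- renderOverlay(s, zero, slices = 12, outDir = file.path(tmp, "a"))
  ras <- png::readPNG(p1)
  expect_equal(dim(ras), c(24, 24, 3))
  expect_equal(ras[, , 1], ras[, , 2])   # gray: channels identical
  ## a single labeled voxel colors exactly one pixel region
  one <- zero; one[5, 7, 12] <- 1L
  p2 <- renderOverlay(s, one, slices = 12, outDir = file.path(tmp, "b"))
  ras2 <- png::readPNG(p2)
  differs <- which(abs(ras2[, , 1] - ras[, , 1]) > 1e-6, arr.ind = TRUE)
  expect_equal(nrow(differs), 1L)
  ## raster row = shape[2] - col + 1, raster col = row (axes transposed)
  expect_equal(unname(differs[1, ]), c(24 - 7 + 1, 5))
  ## determinism and truth side-by-side
  p3 <- renderOverlay(s, mask, truth = mask, slices = 12,
                      outDir = file.path(tmp, "c"))
  p4 <- renderOverlay(s, mask, truth = mask, slices = 12,
                      outDir = file.path(tmp, "d"))
  expect_identical(png::readPNG(p3), png::readPNG(p4))
  expect_equal(dim(png::readPNG(p3))[2], 24 + 2 + 24)
  expect_error(renderOverlay(s, mask, slices = 99, outDir = tmp),
               class = "validationError")
  expect_error(renderOverlay(s, array(0L, c(4, 4, 4)), outDir = tmp),
               class = "validationError")
})
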