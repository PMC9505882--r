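test_that("split arithmetic reproduces the cohort counts", {
  s986 <- splitDataset(986, c(0.5, 0.3, 0.2), seed = 1)
  expect_length(s986$train, 493L)
  expect_length(s986$validation, 295L)
  expect_length(s986$test, 986L - 493L - 295L)
  s920 <- splitDataset(920, c(0.5, 0.3, 0.2), seed = 1)
  expect_length(s920$train, 460L)
  s10 <- splitDataset(10, c(0.5, 0.3, 0.2), seed = 4)
  expect_identical(lengths(s10), c(train = 5L, validation = 3L, test = 2L))
  ## disjoint and exhaustive
  all10 <- c(s10$train, s10$validation, s10$test)
  expect_identical(sort(all10), 1:10)
  expect_identical(anyDuplicated(all10), 0L)
  ## seeded: same seed reproduces, different seed permutes
  expect_identical(splitDataset(10, seed = 4), splitDataset(10, seed = 4))
  expect_false(identical(splitDataset(100, seed = 1)$train,
                         splitDataset(100, seed = 2)$train))
  expect_error(splitDataset(2), "at least 3")
  expect_error(splitDataset(10, c(0.5, 0.4, 0.2)), "summing to 1")
})

test_that("the staircase learning-rate schedule reproduces its endpoints", {
  cfg <- trainConfig()   # full-scale protocol
  expect_equal(lrAtEpoch(cfg, 1), 1e-4)
  expect_equal(lrAtEpoch(cfg, 10), 1e-4)       # first plateau is 10 epochs
  expect_equal(lrAtEpoch(cfg, 11), 0.8e-4)     # first reduction at epoch 11
  ## printed endpoint: 1.5e-7 to two significant figures after 29 cuts
  expect_equal(signif(lrAtEpoch(cfg, 300), 2), 1.5e-7)
  ## non-increasing with exact plateau ratios
  lrs <- vapply(1:300, function(e) lrAtEpoch(cfg, e), 0)
  expect_true(all(diff(lrs) <= 0))
  plateaus <- lrs[seq(1, 300, by = 10)]
  expect_equal(plateaus[-1] / plateaus[-length(plateaus)],
               rep(0.8, 29), tolerance = 1e-12)
  expect_error(lrAtEpoch(cfg, 0), "range")
  expect_error(lrAtEpoch(cfg, 301), "range")
})

test_that("training reduces the loss and checkpoints the best validation epoch", {
  fit <- deskTrained()
  h <- lossHistory(fit)
  expect_lt(h$train_rmse[nrow(h)], h$train_rmse[1])
  expect_identical(h$val_rmse[bestEpoch(fit)], min(h$val_rmse))
  expect_equal(h$lr[1], 1e-3)
})

test_that("the trained model beats the identity on held-out pairs", {
  fit <- deskTrained()
  ds <- deskData()
  sp <- deskSplit()
  imp <- vapply(sp$test, function(i) {
    den <- predictNetwork(bestModel(fit), noisyImages(ds)[[i]])
    psnr(cleanImages(ds)[[i]], den) -
      psnr(cleanImages(ds)[[i]], noisyImages(ds)[[i]])
  }, 0)
  expect_gt(mean(imp), 0)
})

test_that("training is seeded and reproducible end-to-end", {
  ds <- generatePairedDataset(phantomSpec(size = 32, nStructures = 3), 5,
                              acquisitionModel(doseFraction = 0.1,
                                               nAngles = 32), seed = 7)
  cfg <- networkConfig("modified_unet", inputSize = 32, filters = 4,
                       encoderDepth = 2, seed = 5)
  tc <- deskTrainConfig(epochs = 3, seed = 9)
  h1 <- lossHistory(trainNetwork(buildNetwork(cfg), ds, tc))
  h2 <- lossHistory(trainNetwork(buildNetwork(cfg), ds, tc))
  expect_equal(h1, h2, tolerance = 1e-12)
  ## a different initialisation changes the trajectory
  cfgB <- networkConfig("modified_unet", inputSize = 32, filters = 4,
                        encoderDepth = 2, seed = 6)
  h3 <- lossHistory(trainNetwork(buildNetwork(cfgB), ds, tc))
  expect_false(isTRUE(all.equal(h1$train_rmse, h3$train_rmse,
                                tolerance = 1e-12)))
})

test_that("degenerate training configurations are rejected", {
  expect_error(trainConfig(lrFactor = 1.2), "lrFactor")
  expect_error(trainConfig(splitFractions = c(0.6, 0.3, 0.2)), "sum to 1")
  ds <- generatePairedDataset(phantomSpec(size = 32), 3,
                              acquisitionModel(nAngles = 32), seed = 1)
  net <- buildNetwork(networkConfig("modified_unet", inputSize = 32,
                                    filters = 4, encoderDepth = 2))
  expect_error(trainNetwork(net, ds, deskTrainConfig(epochs = 1),
                            split = list(train = integer(0),
                                         validation = 1L)),
               "empty")
})
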