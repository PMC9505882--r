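test_that("noise masks threshold, rescale and localise differences", {
  ref <- generatePhantom(phantomSpec(size = 48, seed = 2))
  expect_true(all(noiseMask(ref, ref) == 0))
  ## a single differing pixel at or above the clip point saturates to 1
  tst <- ref
  tst[10, 10] <- tst[10, 10] + 0.2 * max(ref)
  m <- noiseMask(ref, tst, 0.1)
  expect_equal(m[10, 10], 1)
  expect_identical(sum(m > 0), 1L)
  expect_error(noiseMask(matrix(0, 8, 8), matrix(0, 8, 8)), "zero")
  expect_error(noiseMask(ref, ref, 0), "contrastFraction")
  ## for a simulated low-dose pair the mask energy concentrates in the body
  ld <- simulateLowDose(ref, acquisitionModel(doseFraction = 0.1, seed = 4,
                                              nAngles = 48))
  mask <- noiseMask(ref, ld, 0.1)
  body <- ldctlab:::.ellipseMask(48, 0.8 * 24, 0.6 * 24)
  expect_gt(mean(mask[body]^2), mean(mask[!body]^2))
})

test_that("evaluateMethods scores every pair with every method", {
  ds <- generatePairedDataset(phantomSpec(size = 96, nStructures = 5), 3,
                              acquisitionModel(doseFraction = 0.1,
                                               nAngles = 96), seed = 200)
  model <- fixtureNIQE()
  ## oracle method: returns the matching clean image (nearest by MSE)
  cleanLookup <- cleanImages(ds)
  methods <- list(
    identity = function(x) x,
    oracle = function(x)
      cleanLookup[[which.min(vapply(cleanLookup,
                                    function(c2) mean((c2 - x)^2), 0))]],
    gaussian = function(x) gaussianSmooth(x, 0.45))
  rep <- evaluateMethods(ds, methods, model)
  rec <- reportRecords(rep)
  expect_identical(nrow(rec), 3L * 3L)
  expect_false(anyNA(rec[c("ssim_low", "ssim_denoised", "niqe_low",
                           "niqe_denoised")]))
  ## identity: all improvements zero
  idr <- rec[rec$method == "identity", ]
  expect_true(all(idr$psnr_improvement == 0))
  expect_true(all(idr$ssim_improvement == 0))
  expect_true(all(idr$niqe_improvement == 0))
  ## the oracle attains the maximal PSNR improvement of all methods
  agg <- reportAggregates(rep)
  expect_identical(agg$method[which.max(agg$psnr_improvement)], "oracle")
  ## gaussian smoothing helps on the 10%-dose corpus
  expect_gt(agg$psnr_improvement[agg$method == "gaussian"], 0)
  ## a shape-breaking method is named in its error
  bad <- list(cropper = function(x) x[1:10, 1:10])
  expect_error(evaluateMethods(ds, bad, model), "cropper")
})

test_that("binned improvement tables partition images and respect totals", {
  ds <- generatePairedDataset(phantomSpec(size = 96, nStructures = 5), 4,
                              acquisitionModel(doseFraction = 0.1,
                                               nAngles = 96), seed = 300)
  model <- fixtureNIQE()
  rep <- evaluateMethods(ds, list(identity = function(x) x,
                                  gaussian = function(x)
                                    gaussianSmooth(x, 0.45)), model)
  tab1 <- binImprovements(rep, "psnr", nBins = 1)
  agg <- reportAggregates(rep)
  for (m in rownames(tab1@cells))
    expect_equal(unname(tab1@cells[m, 1]),
                 agg$psnr_improvement[agg$method == m])
  tab <- binImprovements(rep, "psnr", nBins = 3)
  expect_identical(sum(tab@counts), 4L)
  ## overall equals the count-weighted mean of bin means
  for (m in rownames(tab@cells)) {
    cells <- tab@cells[m, ]
    ok <- !is.na(cells)
    expect_equal(sum(cells[ok] * tab@counts[ok]) / sum(tab@counts[ok]),
                 unname(tab@overall[m]))
  }
})

test_that("a trained model removes more noise where there is more noise", {
  fit <- deskTrained()
  ## mixed-dose corpus: very noisy (5%) and mildly noisy (20%) pairs
  mk <- function(df, seed) generatePairedDataset(
    phantomSpec(size = 64, nStructures = 5), 4,
    acquisitionModel(doseFraction = df), seed = seed)
  d05 <- mk(0.05, 400); d20 <- mk(0.2, 410)
  pairs <- methods::new("PairedDataset",
                        clean = c(cleanImages(d05), cleanImages(d20)),
                        noisy = c(noisyImages(d05), noisyImages(d20)),
                        acquisition = acquisition(d05),
                        seeds = c(d05@seeds, d20@seeds))
  model <- fitNIQEModel(lapply(1:3, function(s)
    generatePhantom(phantomSpec(size = 64, nStructures = 5,
                                seed = 600 + s))), patchSize = 16)
  rep <- evaluateMethods(pairs, list(sdual3 = networkDenoiser(fit)), model)
  tab <- binImprovements(rep, "psnr", nBins = 2)
  ## noisiest bin = lowest low-dose PSNR = first bin
  expect_gte(tab@cells["sdual3", 1], tab@cells["sdual3", 2])
})

test_that("metric reports survive the CSV round trip with identities intact", {
  ds <- generatePairedDataset(phantomSpec(size = 96, nStructures = 5), 2,
                              acquisitionModel(doseFraction = 0.1,
                                               nAngles = 96), seed = 500)
  rep <- evaluateMethods(ds, list(gaussian = function(x)
    gaussianSmooth(x, 0.45)), fixtureNIQE())
  path <- withr::local_tempfile(fileext = ".csv")
  writeMetricReport(rep, path)
  back <- readMetricReport(path)
  expect_equal(reportAggregates(back), reportAggregates(rep),
               tolerance = 1e-9)
  ## a corrupted improvement column is rejected on load
  bad <- read.csv(path)
  bad$psnr_improvement <- bad$psnr_improvement + 1
  write.csv(bad, path, row.names = FALSE)
  expect_error(readMetricReport(path), "identities")
})
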