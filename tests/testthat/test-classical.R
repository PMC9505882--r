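test_that("gaussian smoothing preserves constants, reproduces its kernel, and contracts variance", {
  cst <- matrix(0.7, 16, 16)
  expect_equal(gaussianSmooth(cst, 1), cst, tolerance = 1e-12)
  ## unit impulse in the interior returns the kernel itself
  imp <- matrix(0, 15, 15); imp[8, 8] <- 1
  out <- gaussianSmooth(imp, 1)
  k <- ldctlab:::.gaussKernel1d(1)
  expect_equal(out[8 + (-3:3), 8 + (-3:3)], outer(k, k), tolerance = 1e-12)
  expect_equal(sum(out), 1, tolerance = 1e-12)
  ## white noise loses variance
  wn <- matrix(ldctlab:::.withSeed(1, rnorm(64^2)), 64)
  expect_lt(var(as.vector(gaussianSmooth(wn, 1))), var(as.vector(wn)))
})

test_that("NLM equals a brute-force double-loop oracle on an 8x8 fixture", {
  img <- matrix(ldctlab:::.withSeed(2, runif(64)), 8)
  params <- classicalParams(nlmH = 0.25, nlmPatch = 3L, nlmSearch = 5L)
  fast <- nlmDenoise(img, params)
  ## oracle: per-pixel loops; patch distances are box means over the
  ## replicate-padded squared-difference field, as documented
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    num <- 0; den <- 0
    for (dy in -2:2) for (dx in -2:2) {
      d2 <- 0
      for (py in -1:1) for (px in -1:1) {
        r <- clamp(i + py, 8L); c <- clamp(j + px, 8L)
        a <- img[r, c]
        b <- img[clamp(r + dy, 8L), clamp(c + dx, 8L)]
        d2 <- d2 + (a - b)^2
      }
      d2 <- d2 / 9
      w <- exp(-d2 / 0.25^2)
      num <- num + w * img[clamp(i + dy, 8L), clamp(j + dx, 8L)]
      den <- den + w
    }
    oracle[i, j] <- num / den
  }
  expect_equal(fast, oracle, tolerance = 1e-12)
})

test_that("NLM limits: constants pass through and h -> Inf gives the window mean", {
  cst <- matrix(0.3, 12, 12)
  expect_equal(nlmDenoise(cst, classicalParams(nlmH = 0.1)), cst,
               tolerance = 1e-12)
  img <- matrix(ldctlab:::.withSeed(3, runif(144)), 12)
  big <- nlmDenoise(img, classicalParams(nlmH = 1e6, nlmPatch = 3L,
                                         nlmSearch = 5L))
  ## equal weights: the output is the replicate-padded 5x5 box mean
  box <- rep(1 / 5, 5)
  expect_equal(big, ldctlab:::.sepFilter(img, box), tolerance = 1e-8)
})

test_that("collaborative filtering denoises and its Wiener stage helps", {
  phs <- lapply(1:8, function(s)
    generatePhantom(phantomSpec(size = 64, nStructures = 4, seed = s)))
  ## noise-free piecewise-constant input passes through essentially intact
  ## (hard thresholding at 2.7 sigma may round the sharpest edges slightly,
  ## so the tolerance is well below any noise scale of interest)
  clean0 <- bm3dDenoise(phs[[1]], classicalParams(bm3dSigma = 0.05))
  expect_lte(mean((clean0 - phs[[1]])^2), 1e-3)
  gain <- numeric(8); wienerWin <- logical(8)
  for (s in 1:8) {
    ref <- phs[[s]]
    noisy <- ref + matrix(ldctlab:::.withSeed(40 + s, rnorm(64^2, 0, 0.1)),
                          64)
    p <- classicalParams(bm3dSigma = 0.1)
    den <- bm3dDenoise(noisy, p)
    gain[s] <- psnr(ref, den) - psnr(ref, noisy)
    basic <- ldctlab:::.bm3dStage(noisy, noisy, 0.1, p, wiener = FALSE)
    wienerWin[s] <- psnr(ref, den) >= psnr(ref, basic) - 0.05
  }
  expect_true(all(gain > 0))
  ## the Wiener refinement improves or preserves stage 1 on most fixtures
  expect_gte(sum(wienerWin), 6L)
})

test_that("baselines rank as expected on stationary Gaussian noise", {
  impG <- numeric(8); impN <- numeric(8); impB <- numeric(8)
  for (s in 1:8) {
    ref <- generatePhantom(phantomSpec(size = 64, nStructures = 4,
                                       seed = 20 + s))
    noisy <- ref + matrix(ldctlab:::.withSeed(60 + s, rnorm(64^2, 0, 0.1)),
                          64)
    impG[s] <- psnr(ref, denoise(noisy, "gaussian")) - psnr(ref, noisy)
    impN[s] <- psnr(ref, denoise(noisy, "nlm")) - psnr(ref, noisy)
    impB[s] <- psnr(ref, denoise(noisy, "bm3d")) - psnr(ref, noisy)
  }
  expect_gt(mean(impG), 0)
  expect_gt(mean(impN), 0)
  expect_gt(mean(impB), 0)
  ## mean ordering: collaborative filtering beats non-local means
  expect_gte(mean(impB), mean(impN))
})

test_that("all baselines preserve shape and produce finite output", {
  img <- generatePhantom(phantomSpec(size = 48, seed = 1)) +
    matrix(ldctlab:::.withSeed(5, rnorm(48^2, 0, 0.05)), 48)
  for (m in c("gaussian", "nlm", "bm3d")) {
    out <- denoise(img, m)
    expect_identical(dim(out), dim(img))
    expect_true(all(is.finite(out)))
  }
  expect_error(bm3dDenoise(matrix(0.1, 4, 4)), "block")
  expect_error(classicalParams(nlmPatch = 7L, nlmSearch = 5L), "smaller")
})
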