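## Forward projection, FBP, and the photon-noise chain.

test_that("forward projection conserves mass and matches the disk chord form", {
  n <- 64L
  ctr <- (n + 1) / 2
  x <- matrix(seq_len(n), n, n, byrow = TRUE) - ctr
  y <- matrix(seq_len(n), n, n) - ctr
  ## all-zero image -> all-zero sinogram
  z <- forwardProject(matrix(0, n, n), 16)
  expect_true(all(sinogramValues(z) == 0))
  ## single centred unit pixel: every angle carries the same total mass
  imp <- matrix(0, n, n); imp[32, 32] <- 1
  sgI <- forwardProject(imp, 24)
  expect_lt(diff(range(colSums(sinogramValues(sgI)))), 0.02)
  ## uniform disk: chord-length profile 2 v sqrt(r^2 - d^2)
  r <- 14; v <- 0.7
  disk <- (x^2 + y^2 <= r^2) * v
  sg <- forwardProject(disk, 32)
  D <- nrow(sinogramValues(sg))
  d <- seq_len(D) - (D + 1) / 2
  chord <- ifelse(abs(d) <= r, 2 * v * sqrt(pmax(r^2 - d^2, 0)), 0)
  for (k in c(1L, 9L, 20L)) {
    p <- sinogramValues(sg)[, k]
    ## away from the tangent bins the discretised profile tracks the
    ## closed form; RMS over the full detector stays small as well
    interior <- abs(d) <= r - 2
    expect_lt(max(abs(p[interior] - chord[interior])), 0.06 * max(chord))
    expect_lt(sqrt(mean((p - chord)^2)), 0.05 * max(chord))
  }
  ## mass conservation across angles within 1%
  cs <- colSums(sinogramValues(sg))
  expect_lt((max(cs) - min(cs)) / mean(cs), 0.01)
  expect_error(forwardProject(matrix(0, 4, 6), 8), "square")
})

test_that("FBP reconstructs amplitude and degrades with fewer angles", {
  expect_true(all(reconstructFBP(sinogram(matrix(0, 45, 8),
                                          (0:7) * 22.5), side = 31) == 0))
  ph <- generatePhantom(phantomSpec(size = 128, nStructures = 5, seed = 7))
  rec <- reconstructFBP(forwardProject(ph, 180), side = 128)
  body <- ldctlab:::.ellipseMask(128, 0.8 * 64 - 3, 0.6 * 64 - 3)
  psnrIn <- function(r) {
    e <- r - ph
    20 * log10(1 / sqrt(mean(e[body]^2)))
  }
  expect_gte(psnrIn(rec), 30)
  rec30 <- reconstructFBP(forwardProject(ph, 30), side = 128)
  expect_lt(psnrIn(rec30), psnrIn(rec))
  ## disk amplitude is reconstructed, not just shape
  n <- 64L; ctr <- (n + 1) / 2
  x <- matrix(seq_len(n), n, n, byrow = TRUE) - ctr
  y <- matrix(seq_len(n), n, n) - ctr
  disk <- (x^2 + y^2 <= 14^2) * 0.7
  rd <- reconstructFBP(forwardProject(disk, 64), side = n)
  expect_lt(abs(mean(rd[x^2 + y^2 <= 11^2]) - 0.7), 0.01)
})

test_that("incident flux and dose reduction follow the product laws", {
  expect_identical(incidentFlux(acquisitionModel(K = 1, c = 1, mA = 100,
                                                 s = 1)), 100)
  expect_identical(incidentFlux(acquisitionModel(K = 2, c = 0.5, mA = 700,
                                                 s = 1)), 700)
  base <- acquisitionModel(K = 3, c = 0.7, mA = 650, s = 1)
  dbl <- acquisitionModel(K = 3, c = 0.7, mA = 650, s = 2)
  expect_equal(incidentFlux(dbl), 2 * incidentFlux(base))
  expect_error(acquisitionModel(mA = -5), "positive")
  expect_equal(reduceDose(1000, 0.1), 100)
  expect_identical(reduceDose(650, 0.5), 325)
  expect_identical(reduceDose(42, 1), 42)
  expect_error(reduceDose(100, 0), "doseFraction")
  expect_error(reduceDose(100, 1.2), "doseFraction")
})

test_that("attenuation obeys Beer-Lambert with the bowtie profile", {
  ang <- (0:7) * 22.5
  zero <- sinogram(matrix(0, 33, 8), ang)
  lam <- attenuate(zero, 100, bowtieProfile("flat"))
  expect_equal(max(abs(lam - 100)), 0)
  ln2 <- sinogram(matrix(log(2), 33, 8), ang)
  expect_equal(max(abs(attenuate(ln2, 100, bowtieProfile("flat")) - 50)), 0,
               tolerance = 1e-12)
  ## gaussian-edge bowtie: edge counts below centre counts for rho == 0
  lamB <- attenuate(zero, 100, bowtieProfile("gaussian_edge"))
  expect_lt(lamB[1, 1], lamB[17, 1])
  expect_equal(lamB[17, 1], 100)   # normalised to 1 at the centre
  w <- bowtieWeights(bowtieProfile("gaussian_edge"), 33)
  expect_equal(max(w), 1)
  expect_equal(w[1], 0.3, tolerance = 1e-6)
})

test_that("Poisson sampling matches its first two moments and edge cases", {
  expect_true(all(sampleCounts(matrix(0, 5, 5), seed = 1) == 0))
  ex <- matrix(123.4, 3, 3)
  expect_identical(sampleCounts(ex, seed = 1, poissonEnabled = FALSE), ex)
  expect_error(sampleCounts(matrix(-1, 2, 2)), "non-negative")
  lam <- matrix(100, 500, 200)   # 1e5 elements
  s <- sampleCounts(lam, seed = 4)
  expect_lt(abs(mean(s) - 100), 4 * sqrt(100 / 1e5))
  expect_gt(var(as.vector(s)) / mean(s), 0.95)
  expect_lt(var(as.vector(s)) / mean(s), 1.05)
  ## seeded determinism without touching the global RNG stream
  set.seed(77); before <- runif(1)
  s2 <- sampleCounts(lam, seed = 4)
  set.seed(77); after <- runif(1)
  expect_identical(s, s2)
  expect_identical(before, after)
})

test_that("log conversion inverts the deterministic attenuation", {
  ang <- (0:15) * 11.25
  rho <- sinogram(matrix(runif(33 * 16, 0, 3), 33, 16), ang)
  I0L <- 5000
  lam <- attenuate(rho, I0L, bowtieProfile("flat"))
  back <- countsToSinogram(lam, I0L, ang)
  expect_equal(sinogramValues(back), sinogramValues(rho), tolerance = 1e-12)
  ## zero counts clip to a 1-count floor
  IL <- matrix(c(0, 100), 2, 1)
  out <- countsToSinogram(IL, 100, 0)
  expect_equal(sinogramValues(out)[1, 1], -log(1 / 100))
  expect_equal(sinogramValues(out)[2, 1], 0)
})

test_that("the end-to-end simulator is deterministic and dose-monotone", {
  ph <- generatePhantom(phantomSpec(size = 64, seed = 7))
  m <- acquisitionModel(doseFraction = 0.1, seed = 3)
  a <- simulateLowDose(ph, m)
  expect_identical(a, simulateLowDose(ph, m))
  expect_true(all(a >= 0 & a <= 1.5))
  ## noise variance of (noisy - clean) rises monotonically as dose falls
  noiseVar <- vapply(c(1, 0.5, 0.1, 0.05), function(df) {
    mean(vapply(1:8, function(s) {
      nz <- simulateLowDose(ph, acquisitionModel(doseFraction = df,
                                                 seed = 20 + s))
      det <- simulateLowDose(ph, acquisitionModel(doseFraction = df,
                                                  poissonEnabled = FALSE))
      var(as.vector(nz - det))
    }, 0))
  }, 0)
  expect_true(all(diff(noiseVar) > 0))
})

test_that("photon noise concentrates inside the body region", {
  ph <- generatePhantom(phantomSpec(size = 64, nStructures = 5, seed = 7))
  body <- ldctlab:::.ellipseMask(64, 0.8 * 32, 0.6 * 32)
  for (kind in c("gaussian_edge", "flat")) {
    m1 <- acquisitionModel(doseFraction = 0.1, seed = 11,
                           bowtie = bowtieProfile(kind))
    m0 <- acquisitionModel(doseFraction = 0.1, poissonEnabled = FALSE,
                           bowtie = bowtieProfile(kind))
    noise <- simulateLowDose(ph, m1) - simulateLowDose(ph, m0)
    expect_gt(var(noise[body]) / var(noise[!body]), 1)
  }
})

test_that("sinograms persist with their acquisition sidecar", {
  path <- withr::local_tempfile(fileext = ".csv")
  sg <- forwardProject(generatePhantom(phantomSpec(size = 32, seed = 2)), 16)
  writeSinogram(sg, path, model = acquisitionModel())
  back <- readSinogram(path)
  expect_equal(sinogramValues(back), sinogramValues(sg), tolerance = 1e-12)
  expect_equal(sinogramAngles(back), sinogramAngles(sg))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$acquisition$dose_fraction, 0.1)
})
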