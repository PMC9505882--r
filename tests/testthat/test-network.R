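test_that("every family preserves the image shape at any valid input size", {
  fams <- c("stacked_modified_unet", "modified_unet", "unet", "segnet_like",
            "deconvnet_like", "rednet")
  for (fam in fams) {
    cfg <- networkConfig(fam, inputSize = 16, filters = 4,
                         encoderDepth = if (fam == "rednet") 6L else 2L,
                         seed = 1)
    net <- buildNetwork(cfg)
    for (side in c(16L, 32L)) {
      out <- predictNetwork(net, matrix(runif(side^2), side))
      expect_identical(dim(out), c(side, side))
    }
  }
  expect_error(buildNetwork(networkConfig("modified_unet", inputSize = 30,
                                          filters = 4, encoderDepth = 2)),
               "divisible")
})

test_that("the proposed graph has two encoder-decoder stacks and rednet none", {
  cfg <- networkConfig("stacked_modified_unet", inputSize = 32, filters = 8,
                       encoderDepth = 3)
  expect_identical(cfg@stackCount, 2L)
  net <- buildNetwork(cfg)
  opNames <- vapply(net@ops, `[[`, "", "out")
  expect_true(any(grepl("^s1_enc", opNames)))
  expect_true(any(grepl("^s2_enc", opNames)))
  expect_false(any(grepl("^s3_", opNames)))
  ## inter-stack concatenation feeds stack 2
  expect_true("stack2_in" %in% opNames)
  ## rednet: no contraction or expansion ops anywhere
  red <- buildNetwork(networkConfig("rednet", inputSize = 16, filters = 4,
                                    encoderDepth = 6))
  types <- vapply(red@ops, `[[`, "", "type")
  strides <- vapply(red@ops, function(o)
    if (!is.null(o$stride)) o$stride else 1L, 0L)
  expect_false(any(types == "pool"))
  expect_true(all(strides == 1L))
})

test_that("classical U-Net doubles filters to 1024 at depth 4", {
  cfg <- networkConfig("unet", inputSize = 16, encoderDepth = 4)
  expect_identical(cfg@filters, 64L)
  net <- buildNetwork(cfg)
  couts <- vapply(net@ops, function(o)
    if (!is.null(o$Cout)) o$Cout else 0L, 0L)
  expect_identical(max(couts), 1024L)
  expect_identical(cfg@contraction, "maxpool")
})

test_that("receptive fields follow k + (n-1)(k-1) and the perturbation probe agrees", {
  expect_identical(receptiveField(2, 3), 5L)
  expect_identical(receptiveField(3, 3), 7L)
  expect_identical(receptiveField(1, 3), 3L)
  expect_identical(receptiveField(1, 5), 5L)
  expect_identical(receptiveField(2, 5), 9L)
  for (n in 1:3)
    expect_identical(empiricalReceptiveField(n, 3), receptiveField(n, 3))
  expect_identical(empiricalReceptiveField(1, 5), 5L)
})

test_that("parameter counts match an independent closed-form sum", {
  ## single conv layer, 1 -> 128 channels, k = 3: 128 * 9 + 128
  g <- ldctlab:::.graphBuilder()
  g$setChannels("input", 1L)
  g$conv("input", "c1", 1L, 128L, 3L)
  net1 <- methods::new("LDCTNetwork",
                       config = networkConfig("modified_unet"),
                       ops = g$ops(),
                       params = list(c1 = ldctlab:::.initConv(3L, 1L, 128L)))
  expect_identical(parameterCount(net1), 1280)
  ## dual 3x3 at constant channels beats a single 5x5 on parameters
  C <- 128
  expect_lt(2 * (9 * C^2 + C), 25 * C^2 + C)
  ## closed-form oracle over the compiled graph for three configurations
  closedForm <- function(net) {
    tot <- 0
    for (op in net@ops) {
      if (op$type == "conv")
        tot <- tot + op$k^2 * op$Cin * op$Cout + op$Cout
      else if (op$type == "tconv")
        tot <- tot + op$k^2 * op$Cout * op$Cin + op$Cout
    }
    tot
  }
  cfgs <- list(
    networkConfig("stacked_modified_unet", inputSize = 32, filters = 8,
                  encoderDepth = 2),
    networkConfig("unet", inputSize = 16, filters = 8, encoderDepth = 2),
    networkConfig("rednet", inputSize = 16, filters = 6, encoderDepth = 5))
  for (cfg in cfgs) {
    net <- buildNetwork(cfg)
    expect_identical(parameterCount(net), closedForm(net))
  }
})

test_that("gradients reach every trainable tensor and match finite differences", {
  cfg <- networkConfig("stacked_modified_unet", inputSize = 8, filters = 3,
                       encoderDepth = 2, seed = 3)
  net <- buildNetwork(cfg)
  x <- array(ldctlab:::.withSeed(5, runif(64)), c(8, 8, 1))
  tgt <- array(ldctlab:::.withSeed(6, runif(64)), c(8, 8, 1))
  fw <- ldctlab:::.netForward(net, x, keepCache = TRUE)
  resid <- fw$out - tgt
  L <- sqrt(mean(resid^2))
  gr <- ldctlab:::.netBackward(net, fw, resid / (length(resid) * L))
  ## connectivity: no dead branches from mis-wired skips
  expect_setequal(names(gr), names(net@params))
  for (nm in names(gr))
    expect_true(any(gr[[nm]]$W != 0) || any(gr[[nm]]$b != 0))
  ## finite-difference agreement on sampled coordinates
  lossAt <- function(n2) {
    o <- ldctlab:::.netForward(n2, x)$out
    sqrt(mean((o - tgt)^2))
  }
  eps <- 1e-6
  picks <- ldctlab:::.withSeed(7, sample(names(gr), 4))
  for (nm in picks) {
    idx <- ldctlab:::.withSeed(8, sample(length(net@params[[nm]]$W), 1))
    up <- net; up@params[[nm]]$W[idx] <- up@params[[nm]]$W[idx] + eps
    dn <- net; dn@params[[nm]]$W[idx] <- dn@params[[nm]]$W[idx] - eps
    fd <- (lossAt(up) - lossAt(dn)) / (2 * eps)
    expect_equal(gr[[nm]]$W[idx], fd, tolerance = 1e-4)
  }
  ## maxpool and dropout paths backpropagate too (unet family)
  un <- buildNetwork(networkConfig("unet", inputSize = 8, filters = 3,
                                   encoderDepth = 2, seed = 2))
  fw2 <- ldctlab:::.netForward(un, x, training = FALSE, keepCache = TRUE)
  gr2 <- ldctlab:::.netBackward(un, fw2, array(1, dim(fw2$out)))
  for (nm in names(gr2))
    expect_true(any(gr2[[nm]]$W != 0) || any(gr2[[nm]]$b != 0))
})

test_that("network builds are seeded and reproducible", {
  cfg <- networkConfig("modified_unet", inputSize = 16, filters = 4,
                       encoderDepth = 2, seed = 11)
  a <- buildNetwork(cfg)
  b <- buildNetwork(cfg)
  expect_identical(a@params, b@params)
  cfg2 <- networkConfig("modified_unet", inputSize = 16, filters = 4,
                        encoderDepth = 2, seed = 12)
  expect_false(identical(buildNetwork(cfg2)@params, a@params))
})
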