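## Natural Image Quality Evaluator (NIQE).
##
## Features are natural-scene statistics of the mean-subtracted
## contrast-normalised (MSCN) coefficients: a generalized Gaussian (GGD)
## fit of the MSCN field (2 features) plus asymmetric GGD (AGGD) fits of
## the four orientation pairwise products (4 features each), per dyadic
## scale: 18 features per scale, 36 for the default two scales. The score
## is the Mahalanobis-type distance between the multivariate Gaussian fit
## of a test image's features and a pristine-corpus model. Computation
## follows the construction cited for the method (MSCN window 7x7 Gaussian
## sigma 7/6, moment-matching GGD/AGGD estimation, two scales with
## factor-2 downsampling); images are rescaled internally to the
## conventional 0..255 working range.

.mscn <- function(img, C = 1) {
  k <- .gaussKernel1d(7 / 6, 3L)          # 7-tap window
  mu <- .sepFilter(img, k)
  sigma <- sqrt(pmax(.sepFilter(img * img, k) - mu^2, 0))
  list(mscn = (img - mu) / (sigma + C), sigma = sigma)
}

## Moment-matching GGD fit; returns c(alpha, sigma^2).
.ggdFit <- function(x, grid) {
  m2 <- mean(x^2)
  m1 <- mean(abs(x))
  if (m2 < 1e-12 || m1 < 1e-12) return(c(grid$g[1], 0))
  rho <- m2 / m1^2
  alpha <- grid$g[which.min(abs(grid$rGGD - rho))]
  c(alpha, m2)
}

## Moment-matching AGGD fit; returns c(alpha, mean, sigma_l^2, sigma_r^2).
.aggdFit <- function(x, grid) {
  l <- x[x < 0]; r <- x[x >= 0]
  sl <- if (length(l)) sqrt(mean(l^2)) else 0
  sr <- if (length(r)) sqrt(mean(r^2)) else 0
  if (sl + sr < 1e-12) return(c(grid$g[1], 0, 0, 0))
  gam <- if (sr > 0) sl / max(sr, 1e-12) else Inf
  m1 <- mean(abs(x)); m2 <- mean(x^2)
  if (m2 < 1e-12) return(c(grid$g[1], 0, sl^2, sr^2))
  rhat <- m1^2 / m2
  Rhat <- rhat * (gam^3 + 1) * (gam + 1) / (gam^2 + 1)^2
  alpha <- grid$g[which.min(abs(grid$rAGGD - Rhat))]
  cst <- sqrt(gamma(1 / alpha) / gamma(3 / alpha))
  eta <- (sr - sl) * gamma(2 / alpha) / gamma(1 / alpha) * cst
  c(alpha, eta, sl^2, sr^2)
}

.niqeGrid <- function() {
  g <- seq(0.2, 10, by = 0.001)
  list(g = g,
       rGGD = gamma(1 / g) * gamma(3 / g) / gamma(2 / g)^2,
       rAGGD = gamma(2 / g)^2 / (gamma(1 / g) * gamma(3 / g)))
}

## 18 NSS features of one MSCN patch: GGD of the coefficients plus AGGD of
## the four orientation products (horizontal, vertical, both diagonals).
.patchFeatures <- function(p, grid) {
  n <- nrow(p); m <- ncol(p)
  shifts <- list(h  = p[, -1] * p[, -m],
                 v  = p[-1, ] * p[-n, ],
                 d1 = p[-1, -1] * p[-n, -m],
                 d2 = p[-1, -m] * p[-n, -1])
  c(.ggdFit(as.vector(p), grid),
    unlist(lapply(shifts, function(s) .aggdFit(as.vector(s), grid)),
           use.names = FALSE))
}

## Feature matrix (patches x 18*nScales) of one image, using the
## sharpness-based patch selection at full scale.
.niqeFeatures <- function(img, patchSize, threshold, nScales, grid) {
  H <- nrow(img); W <- ncol(img)
  nr <- H %/% patchSize; nc <- W %/% patchSize
  if (nr < 1L || nc < 1L)
    stop("image too small for even one NIQE patch", call. = FALSE)
  m1 <- .mscn(img)
  ## per-patch sharpness: mean local sigma, peak-normalised per image
  sharp <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    sharp[i, j] <- mean(m1$sigma[((i - 1) * patchSize + 1):(i * patchSize),
                                 ((j - 1) * patchSize + 1):(j * patchSize)])
  sel <- which(sharp > threshold * max(sharp), arr.ind = TRUE)
  if (nrow(sel) == 0L)
    stop("no patch passed the sharpness threshold; lower T", call. = FALSE)
  levels <- list(m1$mscn)
  cur <- img
  for (s in seq_len(nScales - 1L)) {
    cur <- (cur[seq(1, nrow(cur) - 1, 2), seq(1, ncol(cur) - 1, 2)] +
            cur[seq(2, nrow(cur), 2),     seq(1, ncol(cur) - 1, 2)] +
            cur[seq(1, nrow(cur) - 1, 2), seq(2, ncol(cur), 2)] +
            cur[seq(2, nrow(cur), 2),     seq(2, ncol(cur), 2)]) / 4
    levels[[s + 1L]] <- .mscn(cur)$mscn
  }
  feats <- matrix(0, nrow(sel), 18L * nScales)
  for (r in seq_len(nrow(sel))) {
    i <- sel[r, 1]; j <- sel[r, 2]
    f <- numeric(0)
    for (s in seq_len(nScales)) {
      ps <- patchSize %/% 2L^(s - 1L)
      p <- levels[[s]][((i - 1) * ps + 1):(i * ps),
                       ((j - 1) * ps + 1):(j * ps)]
      f <- c(f, .patchFeatures(p, grid))
    }
    feats[r, ] <- f
  }
  feats
}

#' Fit a NIQE natural-scene-statistics model on pristine images
#'
#' Extracts NSS features from sharp patches of a corpus of pristine
#' (distortion-free) images and fits their multivariate Gaussian model
#' (feature mean \eqn{\nu_1} and covariance \eqn{\Sigma_1}). Patches are
#' `patchSize` x `patchSize` tiles whose mean local contrast exceeds
#' `sharpnessThreshold` times the per-image maximum.
#'
#' @param images list of numeric matrices, each at least `2 * patchSize`
#'   per side; at least 2 images.
#' @param patchSize patch side length (default 48).
#' @param sharpnessThreshold patch-selection threshold T in \[0, 1\]
#'   (default 0.5).
#' @param nScales number of dyadic scales (default 2; 18 features each).
#' @param dataRange intensity range of the inputs (default 1); images are
#'   rescaled internally to the conventional 0..255 working range.
#' @return A [NIQEModel-class].
#' @examples
#' imgs <- lapply(1:3, function(s)
#'   generatePhantom(phantomSpec(size = 96, seed = s)))
#' m <- fitNIQEModel(imgs, patchSize = 24)
#' @seealso [niqeScore()]
#' @export
fitNIQEModel <- function(images, patchSize = 48L, sharpnessThreshold = 0.5,
                         nScales = 2L, dataRange = 1) {
  if (!is.list(images) || length(images) < 2L)
    stop("need at least 2 pristine images", call. = FALSE)
  patchSize <- as.integer(patchSize)
  for (img in images) {
    .assertImage(img)
    if (min(dim(img)) < 2L * patchSize)
      stop("every image must be at least 2 * patchSize per side",
           call. = FALSE)
  }
  grid <- .niqeGrid()
  feats <- do.call(rbind, lapply(images, function(img)
    .niqeFeatures(img * 255 / dataRange, patchSize, sharpnessThreshold,
                  nScales, grid)))
  if (nrow(feats) < 2L)
    stop("too few selected patches to fit a covariance; lower T",
         call. = FALSE)
  new("NIQEModel", mu = colMeans(feats), sigma = cov(feats),
      patchSize = patchSize,
      sharpnessThreshold = as.numeric(sharpnessThreshold),
      nScales = as.integer(nScales))
}

#' NIQE score of an image
#'
#' Fits the test image's feature statistics (\eqn{\nu_2}, \eqn{\Sigma_2})
#' on its selected patches and returns the distance
#' \deqn{NIQE = \sqrt{(\nu_1-\nu_2)^\top \left(\frac{\Sigma_1+\Sigma_2}{2}\right)^{-1} (\nu_1-\nu_2)}.}
#' Lower scores indicate better (more natural) image quality. The pooled
#' covariance is ridge-regularised with \eqn{\epsilon I}
#' (\eqn{\epsilon = 10^{-6} \cdot tr/dim}) so near-singular fits from small
#' patch counts never crash.
#'
#' @param image numeric matrix, large enough for at least one patch.
#' @param model a fitted [NIQEModel-class].
#' @param dataRange intensity range of `image` (default 1).
#' @return Non-negative scalar score.
#' @export
niqeScore <- function(image, model, dataRange = 1) {
  .assertImage(image)
  stopifnot(is(model, "NIQEModel"))
  grid <- .niqeGrid()
  feats <- .niqeFeatures(image * 255 / dataRange, model@patchSize,
                         model@sharpnessThreshold, model@nScales, grid)
  mu2 <- colMeans(feats)
  sigma2 <- if (nrow(feats) >= 2L) cov(feats) else
    matrix(0, length(mu2), length(mu2))
  pooled <- (model@sigma + sigma2) / 2
  d <- length(mu2)
  eps <- 1e-6 * sum(diag(pooled)) / d
  if (eps <= 0) eps <- 1e-12
  pooled <- pooled + diag(eps, d)
  delta <- model@mu - mu2
  sqrt(max(0, sum(delta * solve(pooled, delta))))
}
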