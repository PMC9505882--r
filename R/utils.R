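## Internal helpers shared across modules.

.assertImage <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", arg), call. = FALSE)
  invisible(x)
}

.assertSameShape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("images must have identical dimensions", call. = FALSE)
  invisible(NULL)
}

## Evaluate a deterministic expression under a local RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## 1-D Gaussian kernel, normalised to sum 1.
.gaussKernel1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## Separable same-size convolution with replicate padding.
## `kr`, `kc` are 1-D kernels applied along rows and columns.
.sepFilter <- function(img, kr, kc = kr) {
  n <- nrow(img); m <- ncol(img)
  rr <- (length(kr) - 1L) %/% 2L
  rc <- (length(kc) - 1L) %/% 2L
  ridx <- pmin(pmax(seq_len(n + 2L * rr) - rr, 1L), n)
  cidx <- pmin(pmax(seq_len(m + 2L * rc) - rc, 1L), m)
  xp <- img[ridx, cidx, drop = FALSE]
  ## filter along rows (first dimension)
  acc <- matrix(0, n, m + 2L * rc)
  for (i in seq_along(kr))
    acc <- acc + kr[i] * xp[(i):(i + n - 1L), , drop = FALSE]
  out <- matrix(0, n, m)
  for (j in seq_along(kc))
    out <- out + kc[j] * acc[, (j):(j + m - 1L), drop = FALSE]
  out
}

## Vectorised bilinear sampling of matrix `img` at fractional (row, col)
## coordinates; points outside the support return 0.
.bilinear <- function(img, r, c) {
  n <- nrow(img); m <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  val <- numeric(length(r))
  get <- function(ri, ci) {
    ok <- ri >= 1 & ri <= n & ci >= 1 & ci <= m
    v <- numeric(length(ri))
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v
  }
  val <- (1 - fr) * (1 - fc) * get(r0, c0) +
         (1 - fr) * fc       * get(r0, c0 + 1) +
         fr       * (1 - fc) * get(r0 + 1, c0) +
         fr       * fc       * get(r0 + 1, c0 + 1)
  val
}

## Immerkaer fast noise-variance estimate (used to auto-set classical
## denoiser strengths): convolve with a Laplacian-difference mask whose
## response to smooth content vanishes, then rescale the mean absolute
## response assuming Gaussian noise.
.estimateNoiseSigma <- function(img) {
  n <- nrow(img); m <- ncol(img)
  if (n < 3L || m < 3L) return(0)
  M <- matrix(c(1, -2, 1, -2, 4, -2, 1, -2, 1), 3, 3)
  acc <- matrix(0, n - 2L, m - 2L)
  for (i in 1:3) for (j in 1:3)
    acc <- acc + M[i, j] * img[(i):(i + n - 3L), (j):(j + m - 3L)]
  sqrt(pi / 2) / 6 * mean(abs(acc))
}

## Body-ellipse mask helper (shared by phantoms and evaluation).
.ellipseMask <- function(size, a, b, cx = (size + 1) / 2, cy = (size + 1) / 2) {
  x <- matrix(seq_len(size), size, size, byrow = TRUE)
  y <- matrix(seq_len(size), size, size)
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
}
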