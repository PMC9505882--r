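## Full-reference quality metrics: RMSE, PSNR, SSIM, and improvement scores.

#' Root mean squared error between two images
#'
#' \deqn{RMSE = \sqrt{\sum_i (t_i - o_i)^2 / P_x}} where \eqn{P_x} is the
#' pixel count. This is also the training loss of the network engine.
#'
#' @param target,output numeric matrices of identical shape.
#' @return Non-negative scalar.
#' @examples
#' rmse(matrix(0, 2, 2), matrix(1, 2, 2))  # 1
#' @export
rmse <- function(target, output) {
  .assertImage(target); .assertImage(output)
  .assertSameShape(target, output)
  sqrt(mean((target - output)^2))
}

#' Peak signal-to-noise ratio (dB)
#'
#' \deqn{PSNR = 20 \log_{10}(f_{max} / \sqrt{mse})} between a reference and
#' a test image. `fmax` is the configured data range (1 for normalised
#' phantoms), not the per-image maximum, so scores are comparable across
#' methods. Identical images return `Inf` (documented sentinel).
#'
#' @param reference,test numeric matrices of identical shape.
#' @param fmax positive peak signal value (default 1).
#' @return PSNR in decibels; `Inf` for identical images.
#' @examples
#' psnr(matrix(0, 4, 4), matrix(0.1, 4, 4))  # 20 dB
#' @export
psnr <- function(reference, test, fmax = 1) {
  .assertImage(reference); .assertImage(test)
  .assertSameShape(reference, test)
  if (!is.finite(fmax) || fmax <= 0)
    stop("fmax must be positive", call. = FALSE)
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  20 * log10(fmax / sqrt(mse))
}

#' Structural similarity index
#'
#' Mean local SSIM over a sliding Gaussian window (11 x 11, sigma 1.5),
#' combining luminance, contrast and structure terms in the standard
#' product form with exponents \eqn{\alpha = \beta = \gamma = 1} and
#' stabilisers \eqn{C_1 = (0.01 f_{max})^2}, \eqn{C_2 = (0.03 f_{max})^2},
#' \eqn{C_3 = C_2 / 2} (the three-term product then simplifies to the
#' familiar two-factor formula). Higher values indicate closer resemblance;
#' `ssim(x, x)` is 1 and the score is symmetric in its arguments.
#'
#' @param reference,test numeric matrices of identical shape, at least as
#'   large as the window.
#' @param fmax data range used in the stabilisers (default 1).
#' @param windowSize odd Gaussian window side (default 11).
#' @param windowSigma Gaussian window sigma (default 1.5).
#' @return Scalar in \[-1, 1\].
#' @examples
#' a <- matrix(runif(64^2), 64)
#' ssim(a, a)  # 1
#' @export
ssim <- function(reference, test, fmax = 1, windowSize = 11L,
                 windowSigma = 1.5) {
  .assertImage(reference); .assertImage(test)
  .assertSameShape(reference, test)
  if (nrow(reference) < windowSize || ncol(reference) < windowSize)
    stop("image smaller than the SSIM window", call. = FALSE)
  C1 <- (0.01 * fmax)^2
  C2 <- (0.03 * fmax)^2
  r <- (windowSize - 1L) %/% 2L
  k <- .gaussKernel1d(windowSigma, r)
  mu1 <- .sepFilter(reference, k)
  mu2 <- .sepFilter(test, k)
  s11 <- .sepFilter(reference * reference, k) - mu1^2
  s22 <- .sepFilter(test * test, k) - mu2^2
  s12 <- .sepFilter(reference * test, k) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Per-image improvement scores of a denoising result
#'
#' Computes PSNR, SSIM and NIQE of the low-dose input and of the denoised
#' output against the full-dose reference, plus the improvement scores:
#' PSNR and SSIM improvements are denoised minus low-dose, while the NIQE
#' improvement is low-dose minus denoised (a lower NIQE means a better
#' image, so positive improvements always mean "better").
#'
#' @param low low-dose (noisy) image.
#' @param denoised denoised image.
#' @param reference full-dose reference image.
#' @param model a fitted [NIQEModel-class].
#' @param fmax data range for PSNR/SSIM (default 1).
#' @return A one-row data.frame with columns `psnr_low`, `psnr_denoised`,
#'   `psnr_improvement`, `ssim_low`, `ssim_denoised`, `ssim_improvement`,
#'   `niqe_low`, `niqe_denoised`, `niqe_improvement`.
#' @seealso [evaluateMethods()]
#' @export
improvementScores <- function(low, denoised, reference, model, fmax = 1) {
  .assertSameShape(low, denoised)
  .assertSameShape(low, reference)
  pL <- psnr(reference, low, fmax)
  pD <- psnr(reference, denoised, fmax)
  sL <- ssim(reference, low, fmax)
  sD <- ssim(reference, denoised, fmax)
  nL <- niqeScore(low, model)
  nD <- niqeScore(denoised, model)
  data.frame(psnr_low = pL, psnr_denoised = pD, psnr_improvement = pD - pL,
             ssim_low = sL, ssim_denoised = sD, ssim_improvement = sD - sL,
             niqe_low = nL, niqe_denoised = nD, niqe_improvement = nL - nD)
}
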