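## Sinogram-domain low-dose noise simulation.
##
## The simulated acquisition chain is the classical photon-counting model:
## incident flux I0 = K*c*mA*s, dose-reduced flux I0L = doseFraction * I0,
## expected detected counts lambda = I0L * Pb(omega) * exp(-rho(omega,theta))
## (Beer-Lambert with a bowtie profile Pb along the detector axis), Poisson
## sampling of the counts, and log conversion back to line integrals
## rhoL = -log(IL / I0L), followed by filtered back-projection.

#' Bowtie profile weights along the detector axis
#'
#' Evaluates the beam-shaping profile \eqn{P_b} over `nDet` detector bins.
#' The profile is normalised to 1 at the detector centre; the
#' `"gaussian_edge"` kind decays as \eqn{\exp(-\lambda (d/d_{max})^2)}
#' towards the edges, emulating a bowtie filter that concentrates photon
#' flux (and hence relative noise) in the patient's body region.
#'
#' @param bowtie a [BowtieProfile-class].
#' @param nDet number of detector bins.
#' @return Numeric vector of weights in (0, 1], maximum 1 at the centre.
#' @export
bowtieWeights <- function(bowtie, nDet) {
  stopifnot(is(bowtie, "BowtieProfile"))
  nDet <- as.integer(nDet)
  if (bowtie@kind == "flat") return(rep(1, nDet))
  ctr <- (nDet + 1) / 2
  d <- (seq_len(nDet) - ctr) / (nDet - ctr)
  exp(-bowtie@strength * d^2)
}

#' Incident photon flux of the acquisition
#'
#' Returns \eqn{I_0 = K \cdot c \cdot mA \cdot s}, the photon count (cps)
#' incident on the detector at full dose: the product of the scanner
#' constant, collimation factor, tube current and exposure time.
#'
#' @param model an [AcquisitionModel-class].
#' @return A positive scalar (counts per second).
#' @examples
#' incidentFlux(acquisitionModel(K = 1, c = 1, mA = 100, s = 1))  # 100
#' @export
incidentFlux <- function(model) {
  stopifnot(is(model, "AcquisitionModel"))
  validObject(model)
  model@K * model@c * model@mA * model@s
}

#' Dose-reduced incident flux
#'
#' Scales the incident flux by the dose fraction,
#' \eqn{I_{0L} = \mathrm{doseFraction} \cdot I_0}; a fraction of 0.1
#' emulates a 10% dose acquisition.
#'
#' @param I0 positive incident flux.
#' @param doseFraction dose fraction in (0, 1].
#' @return The reduced flux \eqn{I_{0L}}.
#' @examples
#' reduceDose(1000, 0.1)  # 100
#' @export
reduceDose <- function(I0, doseFraction) {
  if (!is.finite(I0) || I0 <= 0)
    stop("I0 must be positive", call. = FALSE)
  if (!is.finite(doseFraction) || doseFraction <= 0 || doseFraction > 1)
    stop("doseFraction must be in (0, 1]", call. = FALSE)
  doseFraction * I0
}

#' Expected detector counts under Beer-Lambert attenuation
#'
#' Computes the expected photon counts
#' \eqn{\lambda(\omega,\theta) = I_{0L} P_b(\omega) e^{-\rho(\omega,\theta)}},
#' broadcasting the bowtie weights along the detector axis.
#'
#' @param sino a [Sinogram-class] of line integrals.
#' @param I0L positive (dose-reduced) incident flux.
#' @param bowtie a [BowtieProfile-class].
#' @return Numeric matrix of expected counts, same shape as the sinogram.
#' @seealso [sampleCounts()], [countsToSinogram()]
#' @export
attenuate <- function(sino, I0L, bowtie = bowtieProfile("flat")) {
  stopifnot(is(sino, "Sinogram"))
  if (!is.finite(I0L) || I0L <= 0) stop("I0L must be positive", call. = FALSE)
  Pb <- bowtieWeights(bowtie, nrow(sino@values))
  I0L * Pb * exp(-sino@values)
}

#' Poisson photon-count sampling
#'
#' Draws independent Poisson counts with the given expected values,
#' emulating quantum (photon-counting) noise. When disabled, returns the
#' expectation unchanged, giving the deterministic pipeline.
#'
#' @param expected non-negative matrix of expected counts.
#' @param seed integer seed (draws are reproducible and leave the global
#'   RNG state untouched).
#' @param poissonEnabled logical switch.
#' @return Matrix of sampled (or expected) counts, same shape.
#' @export
sampleCounts <- function(expected, seed = 1L, poissonEnabled = TRUE) {
  if (any(expected < 0) || any(!is.finite(expected)))
    stop("expected counts must be finite and non-negative", call. = FALSE)
  if (!poissonEnabled) return(expected)
  out <- .withSeed(seed, rpois(length(expected), as.vector(expected)))
  ## rpois returns NA above .Machine$integer.max; such fluxes are far
  ## outside the simulated regime but guard with a normal approximation
  big <- is.na(out)
  if (any(big)) {
    ev <- as.vector(expected)[big]
    out[big] <- round(ev + sqrt(ev) * .withSeed(seed + 1L, rnorm(sum(big))))
  }
  matrix(as.numeric(out), nrow(expected), ncol(expected))
}

#' Log conversion of counts back to line integrals
#'
#' Inverts the attenuation step:
#' \eqn{\rho_L(\omega,\theta) = -\ln(I_L / I_{0L})}. Zero counts are
#' clipped to a floor of 1 count before the logarithm (the conventional
#' handling, since the log is undefined at 0).
#'
#' @param IL matrix of detected counts.
#' @param I0L positive incident flux used in the attenuation.
#' @param angles angles (degrees) for the resulting sinogram.
#' @return A [Sinogram-class] of noisy line integrals.
#' @export
countsToSinogram <- function(IL, I0L, angles = NULL) {
  if (!is.finite(I0L) || I0L <= 0) stop("I0L must be positive", call. = FALSE)
  if (is.null(angles))
    angles <- (seq_len(ncol(IL)) - 1L) * 180 / ncol(IL)
  vals <- -log(pmax(IL, 1) / I0L)
  sinogram(vals, angles)
}

## Resolve NA fields of an AcquisitionModel against a concrete image side:
## nAngles defaults to the side length; muScale is calibrated so that a
## body-width path (0.7 * side pixels) at intensity 1 attenuates by e^-4.
.resolveModel <- function(model, side) {
  nAngles <- if (is.na(model@nAngles)) side else as.integer(model@nAngles)
  muScale <- if (is.na(model@muScale)) 4 / (0.7 * side) else model@muScale
  list(nAngles = nAngles, muScale = muScale)
}

#' End-to-end synthetic low-dose image
#'
#' Chains the full simulation: intensity-to-attenuation scaling, forward
#' projection, Beer-Lambert attenuation at the dose-reduced flux with the
#' bowtie profile, Poisson count sampling, log conversion, and filtered
#' back-projection, then undoes the attenuation scaling. The output is
#' clipped to \[0, `clipMax`\] to absorb reconstruction overshoot.
#'
#' With `doseFraction = 1` and Poisson sampling disabled the result is the
#' plain forward-project + FBP round trip of the input.
#'
#' @param image square numeric matrix with values in \[0, 1\].
#' @param model an [AcquisitionModel-class].
#' @param clipMax upper clip bound of the reconstruction (default 1.5).
#' @param filter FBP filter, `"ramp"` or `"hann"`.
#' @return Numeric matrix of the same size: the synthetic low-dose image.
#' @examples
#' ph <- generatePhantom(phantomSpec(size = 32, seed = 1))
#' ld <- simulateLowDose(ph, acquisitionModel(doseFraction = 0.1, seed = 7))
#' @export
simulateLowDose <- function(image, model = acquisitionModel(),
                            clipMax = 1.5, filter = c("ramp", "hann")) {
  .assertImage(image)
  stopifnot(is(model, "AcquisitionModel"))
  validObject(model)
  if (min(image) < 0 || max(image) > 1)
    stop("image values must lie in [0, 1]", call. = FALSE)
  filter <- match.arg(filter)
  side <- nrow(image)
  rs <- .resolveModel(model, side)
  sino <- forwardProject(image * rs$muScale, rs$nAngles)
  I0L <- reduceDose(incidentFlux(model), model@doseFraction)
  lambda <- attenuate(sino, I0L, model@bowtie)
  IL <- sampleCounts(lambda, model@seed, model@poissonEnabled)
  noisy <- countsToSinogram(IL, I0L, sino@angles)
  ## undo the bowtie weighting in the log domain before reconstruction
  ## (the scanner's calibration knows its own bowtie): rhoL includes
  ## -log(Pb), which would otherwise reconstruct as a bias
  Pb <- bowtieWeights(model@bowtie, nrow(noisy@values))
  vals <- noisy@values + log(Pb)
  rec <- reconstructFBP(sinogram(vals, noisy@angles), side = side,
                        filter = filter)
  pmin(pmax(rec / rs$muScale, 0), clipMax)
}
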