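#' @import methods
#' @importFrom stats rpois rnorm runif median cov sd quantile fft mvfft
#' @importFrom utils write.csv read.csv modifyList
#' @importFrom graphics barplot
#' @importFrom grDevices png dev.off
NULL

## ---------------------------------------------------------------------------
## Bowtie profile
## ---------------------------------------------------------------------------

#' Bowtie beam-shaping profile
#'
#' Describes the detector-axis weighting \eqn{P_b} applied to the incident
#' photon flux. A CT bowtie filter attenuates the beam more strongly towards
#' the field edge, so photon flux (and hence relative noise) concentrates in
#' the patient's body region. Two parametric profiles are available:
#' `"flat"` (\eqn{P_b \equiv 1}, i.e. no bowtie) and `"gaussian_edge"`,
#' \deqn{P_b(d) = \exp(-\lambda (d/d_{max})^2),}
#' normalised to 1 at the detector centre, where `strength` is
#' \eqn{\lambda}. The default strength gives an edge weight of about 0.3.
#'
#' @slot kind character, `"flat"` or `"gaussian_edge"`.
#' @slot strength non-negative numeric decay constant (ignored for `"flat"`).
#' @seealso [bowtieWeights()], [attenuate()]
#' @exportClass BowtieProfile
setClass("BowtieProfile",
  representation(kind = "character", strength = "numeric"),
  prototype(kind = "flat", strength = 0))

setValidity("BowtieProfile", function(object) {
  if (length(object@kind) != 1L ||
      !object@kind %in% c("flat", "gaussian_edge"))
    return("kind must be 'flat' or 'gaussian_edge'")
  if (length(object@strength) != 1L || !is.finite(object@strength) ||
      object@strength < 0)
    return("strength must be a single non-negative number")
  TRUE
})

#' @param kind `"flat"` or `"gaussian_edge"`.
#' @param strength non-negative decay constant; the default
#'   `-log(0.3)` makes the edge weight approximately 0.3.
#' @return `bowtieProfile()` returns a [BowtieProfile-class] object.
#' @rdname BowtieProfile-class
#' @export
bowtieProfile <- function(kind = c("flat", "gaussian_edge"),
                          strength = -log(0.3)) {
  kind <- match.arg(kind)
  if (kind == "flat") strength <- 0
  new("BowtieProfile", kind = kind, strength = as.numeric(strength))
}

## ---------------------------------------------------------------------------
## Acquisition model
## ---------------------------------------------------------------------------

#' Photon-flux and geometry parameters of the simulated acquisition
#'
#' Bundles everything the low-dose simulator needs: the incident-flux
#' factors (scanner constant `K`, collimation factor `c`, tube current
#' `mA`, exposure time `s`, so that \eqn{I_0 = K c \cdot mA \cdot s}), the
#' dose fraction \eqn{I_{0L}/I_0}, the bowtie profile, the number of
#' projection angles, the scale mapping pixel intensity to attenuation line
#' integrals, and the Poisson sampling switch and seed.
#'
#' `muScale` may be `NA`, in which case it is resolved per image so that a
#' body-width path (0.7 of the image side) at intensity 1 attenuates by
#' about \eqn{e^{-4}}; `nAngles` may be `NA`, in which case it defaults to
#' the image side length.
#'
#' @slot K,c,mA,s positive incident-flux factors.
#' @slot doseFraction dose fraction in (0, 1].
#' @slot bowtie a [BowtieProfile-class].
#' @slot nAngles number of equispaced projection angles in \[0, 180), or NA.
#' @slot muScale pixel-intensity to attenuation-coefficient scale, or NA.
#' @slot poissonEnabled logical; disable to get the noise-free pipeline.
#' @slot seed integer seed for the Poisson draws.
#' @seealso [simulateLowDose()], [incidentFlux()]
#' @exportClass AcquisitionModel
setClass("AcquisitionModel",
  representation(K = "numeric", c = "numeric", mA = "numeric", s = "numeric",
                 doseFraction = "numeric", bowtie = "BowtieProfile",
                 nAngles = "numeric", muScale = "numeric",
                 poissonEnabled = "logical", seed = "integer"))

setValidity("AcquisitionModel", function(object) {
  for (nm in c("K", "c", "mA", "s")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      return(sprintf("'%s' must be a single positive number", nm))
  }
  if (length(object@doseFraction) != 1L || !is.finite(object@doseFraction) ||
      object@doseFraction <= 0 || object@doseFraction > 1)
    return("doseFraction must be in (0, 1]")
  if (length(object@nAngles) != 1L ||
      (!is.na(object@nAngles) && object@nAngles < 1))
    return("nAngles must be NA or >= 1")
  if (length(object@muScale) != 1L ||
      (!is.na(object@muScale) && object@muScale <= 0))
    return("muScale must be NA or positive")
  TRUE
})

#' @param K,c,mA,s positive incident-flux factors (defaults emulate a chest
#'   protocol at 700 mA with an overall flux of 7e4 counts).
#' @param doseFraction dose fraction in (0, 1]; 0.1 emulates a 10% dose scan.
#' @param bowtie a [BowtieProfile-class]; default `"gaussian_edge"`.
#' @param nAngles number of projection angles, or `NA` for the image side.
#' @param muScale intensity-to-attenuation scale, or `NA` for the automatic
#'   body-width calibration.
#' @param poissonEnabled logical; `FALSE` gives the deterministic pipeline.
#' @param seed integer seed for photon-count sampling.
#' @return `acquisitionModel()` returns an [AcquisitionModel-class] object.
#' @rdname AcquisitionModel-class
#' @export
acquisitionModel <- function(K = 100, c = 1, mA = 700, s = 1,
                             doseFraction = 0.1,
                             bowtie = bowtieProfile("gaussian_edge"),
                             nAngles = NA_real_, muScale = NA_real_,
                             poissonEnabled = TRUE, seed = 1L) {
  new("AcquisitionModel", K = as.numeric(K), c = as.numeric(c),
      mA = as.numeric(mA), s = as.numeric(s),
      doseFraction = as.numeric(doseFraction), bowtie = bowtie,
      nAngles = as.numeric(nAngles), muScale = as.numeric(muScale),
      poissonEnabled = isTRUE(poissonEnabled), seed = as.integer(seed))
}

setMethod("show", "AcquisitionModel", function(object) {
  cat("AcquisitionModel\n")
  cat(sprintf("  I0 = K*c*mA*s = %g cps  (K=%g, c=%g, mA=%g, s=%g)\n",
              object@K * object@c * object@mA * object@s,
              object@K, object@c, object@mA, object@s))
  cat(sprintf("  dose fraction: %g   bowtie: %s (strength %.3g)\n",
              object@doseFraction, object@bowtie@kind,
              object@bowtie@strength))
  cat(sprintf("  angles: %s   muScale: %s   Poisson: %s   seed: %d\n",
              ifelse(is.na(object@nAngles), "auto",
                     format(object@nAngles)),
              ifelse(is.na(object@muScale), "auto",
                     format(object@muScale)),
              object@poissonEnabled, object@seed))
})

## ---------------------------------------------------------------------------
## Sinogram
## ---------------------------------------------------------------------------

#' Parallel-beam projection data
#'
#' Holds the line integrals \eqn{\rho(\omega, \theta)} of an image:
#' rows index the detector position \eqn{\omega}, columns the projection
#' angle \eqn{\theta} (degrees in \[0, 180)).
#'
#' @slot values numeric matrix, detector axis x angle axis; all finite.
#' @slot angles numeric vector of angles in degrees, one per column.
#' @seealso [forwardProject()], [reconstructFBP()]
#' @exportClass Sinogram
setClass("Sinogram",
  representation(values = "matrix", angles = "numeric"))

setValidity("Sinogram", function(object) {
  if (!is.numeric(object@values)) return("values must be numeric")
  if (length(object@angles) != ncol(object@values))
    return("angle count must equal the number of sinogram columns")
  if (!all(is.finite(object@values))) return("sinogram values must be finite")
  if (any(object@angles < 0 | object@angles >= 180))
    return("angles must lie in [0, 180) degrees")
  TRUE
})

#' @param values numeric detector-by-angle matrix.
#' @param angles numeric angles in degrees, one per column.
#' @return `sinogram()` returns a [Sinogram-class] object.
#' @rdname Sinogram-class
#' @export
sinogram <- function(values, angles) {
  new("Sinogram", values = values, angles = as.numeric(angles))
}

#' @param object,x a `Sinogram`.
#' @rdname Sinogram-class
#' @export
sinogramValues <- function(x) x@values

#' @rdname Sinogram-class
#' @export
sinogramAngles <- function(x) x@angles

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram: %d detector bins x %d angles (%.2f..%.2f deg)\n",
              nrow(object@values), ncol(object@values),
              min(object@angles), max(object@angles)))
})

#' @rdname Sinogram-class
#' @export
setMethod("dim", "Sinogram", function(x) dim(x@values))

## ---------------------------------------------------------------------------
## Phantom spec / paired dataset
## ---------------------------------------------------------------------------

#' Specification of a synthetic chest-like phantom
#'
#' Describes a square phantom consisting of one dominant bright body ellipse
#' on a dark background, containing `nStructures` lower- or higher-intensity
#' internal ellipses (the "anatomy"). All intensities are in \[0, 1\];
#' attenuation scaling lives in the acquisition model, not the phantom.
#'
#' @slot size image side length in pixels (>= 16).
#' @slot nStructures number of internal ellipses.
#' @slot intensityRange length-2 range in \[0, 1\] for structure intensities.
#' @slot bodyAxes length-2 body-ellipse semi-axes as fractions of `size`.
#' @slot seed integer seed; identical specs give bit-identical phantoms.
#' @seealso [generatePhantom()]
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(size = "integer", nStructures = "integer",
                 intensityRange = "numeric", bodyAxes = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (object@size < 16L) return("size must be >= 16")
  if (object@nStructures < 0L) return("nStructures must be >= 0")
  ir <- object@intensityRange
  if (length(ir) != 2L || any(!is.finite(ir)) || ir[1] > ir[2] ||
      ir[1] < 0 || ir[2] > 1)
    return("intensityRange must be an ordered pair within [0, 1]")
  ba <- object@bodyAxes
  if (length(ba) != 2L || any(!is.finite(ba)) || any(ba <= 0) || any(ba > 1))
    return("bodyAxes must be a pair of fractions in (0, 1]")
  TRUE
})

#' @param size side length in pixels (square image), at least 16.
#' @param nStructures number of internal ellipses.
#' @param intensityRange range of structure intensities within \[0, 1\].
#' @param bodyAxes body-ellipse semi-axes as fractions of `size`.
#' @param seed integer seed.
#' @return `phantomSpec()` returns a [PhantomSpec-class] object.
#' @rdname PhantomSpec-class
#' @export
phantomSpec <- function(size = 64L, nStructures = 5L,
                        intensityRange = c(0.2, 1), bodyAxes = c(0.8, 0.6),
                        seed = 1L) {
  new("PhantomSpec", size = as.integer(size),
      nStructures = as.integer(nStructures),
      intensityRange = as.numeric(intensityRange),
      bodyAxes = as.numeric(bodyAxes), seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %dx%d px, %d structures in [%.2f, %.2f], body axes (%.2f, %.2f), seed %d\n",
    object@size, object@size, object@nStructures,
    object@intensityRange[1], object@intensityRange[2],
    object@bodyAxes[1], object@bodyAxes[2], object@seed))
})

#' Paired clean / low-dose phantom dataset
#'
#' An ordered collection of clean phantom images with their synthetic
#' low-dose copies, the acquisition model that produced the copies, and the
#' per-pair seeds. Every `clean[[i]]` and `noisy[[i]]` have identical
#' dimensions.
#'
#' @slot clean,noisy lists of numeric image matrices of equal length.
#' @slot acquisition the [AcquisitionModel-class] used for the noisy copies.
#' @slot seeds integer per-pair seeds.
#' @seealso [generatePairedDataset()]
#' @exportClass PairedDataset
setClass("PairedDataset",
  representation(clean = "list", noisy = "list",
                 acquisition = "AcquisitionModel", seeds = "integer"))

setValidity("PairedDataset", function(object) {
  if (length(object@clean) != length(object@noisy))
    return("clean and noisy collections must have equal length")
  if (length(object@seeds) != length(object@clean))
    return("one seed per pair is required")
  for (i in seq_along(object@clean)) {
    if (!identical(dim(object@clean[[i]]), dim(object@noisy[[i]])))
      return(sprintf("pair %d: clean and noisy dimensions differ", i))
  }
  TRUE
})

#' @param object,x a `PairedDataset`.
#' @rdname PairedDataset-class
#' @export
setMethod("length", "PairedDataset", function(x) length(x@clean))

#' @rdname PairedDataset-class
#' @export
cleanImages <- function(x) x@clean

#' @rdname PairedDataset-class
#' @export
noisyImages <- function(x) x@noisy

#' @rdname PairedDataset-class
#' @export
acquisition <- function(x) x@acquisition

setMethod("show", "PairedDataset", function(object) {
  n <- length(object@clean)
  if (n) {
    d <- dim(object@clean[[1]])
    cat(sprintf("PairedDataset: %d pairs of %dx%d images, dose fraction %g\n",
                n, d[1], d[2], object@acquisition@doseFraction))
  } else cat("PairedDataset: empty\n")
})

## ---------------------------------------------------------------------------
## NIQE model
## ---------------------------------------------------------------------------

#' Fitted natural-scene-statistics model for the NIQE score
#'
#' Stores the multivariate Gaussian fit (feature mean vector \eqn{\nu_1}
#' and covariance \eqn{\Sigma_1}) of natural-scene-statistic features
#' extracted from sharp patches of a pristine image corpus, plus the patch
#' geometry used. Features are GGD parameters of the mean-subtracted
#' contrast-normalised (MSCN) coefficients and AGGD parameters of their four
#' orientation products, over `nScales` dyadic scales (18 features per
#' scale).
#'
#' @slot mu numeric feature mean vector \eqn{\nu_1}.
#' @slot sigma symmetric covariance matrix \eqn{\Sigma_1}.
#' @slot patchSize patch side length in pixels (default 48, >= 16).
#' @slot sharpnessThreshold patch-selection threshold T in \[0, 1\].
#' @slot nScales number of dyadic scales (default 2).
#' @seealso [fitNIQEModel()], [niqeScore()]
#' @exportClass NIQEModel
setClass("NIQEModel",
  representation(mu = "numeric", sigma = "matrix", patchSize = "integer",
                 sharpnessThreshold = "numeric", nScales = "integer"))

setValidity("NIQEModel", function(object) {
  d <- length(object@mu)
  if (!identical(dim(object@sigma), c(d, d)))
    return("covariance dimensions must match the mean vector")
  if (max(abs(object@sigma - t(object@sigma))) > 1e-8 * (1 + max(abs(object@sigma))))
    return("covariance must be symmetric")
  if (object@patchSize < 16L) return("patchSize must be >= 16")
  if (object@sharpnessThreshold < 0 || object@sharpnessThreshold > 1)
    return("sharpnessThreshold must be in [0, 1]")
  if (object@nScales < 1L) return("nScales must be >= 1")
  TRUE
})

setMethod("show", "NIQEModel", function(object) {
  cat(sprintf(
    "NIQEModel: %d features (%d scales), patch %d px, sharpness threshold %.2f\n",
    length(object@mu), object@nScales, object@patchSize,
    object@sharpnessThreshold))
})

## ---------------------------------------------------------------------------
## Metric report / comparison table
## ---------------------------------------------------------------------------

#' Per-image quality scores and improvement report
#'
#' One row of `records` per (image, method): PSNR/SSIM/NIQE of the low-dose
#' input and of the denoised output plus the improvement scores. The sign
#' conventions are: PSNR and SSIM improvements are denoised minus low-dose;
#' NIQE improvement is low-dose minus denoised (lower NIQE is better, so a
#' positive improvement always means "better").
#'
#' @slot records data.frame of per-image scores.
#' @slot aggregates data.frame of per-method mean improvements.
#' @seealso [evaluateMethods()], [improvementScores()]
#' @exportClass MetricReport
setClass("MetricReport",
  representation(records = "data.frame", aggregates = "data.frame"))

#' @param object,x a `MetricReport`.
#' @rdname MetricReport-class
#' @export
reportRecords <- function(x) x@records

#' @rdname MetricReport-class
#' @export
reportAggregates <- function(x) x@aggregates

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport: %d records (%d images x %d methods)\n",
              nrow(object@records),
              length(unique(object@records$image)),
              length(unique(object@records$method))))
  print(object@aggregates, row.names = FALSE)
})

#' Noise-level-binned improvement table
#'
#' Mean improvement per (method, noise-level bin), where bins are
#' equal-width intervals over the observed low-dose score range of one
#' metric. The overall column reproduces the per-method mean over all
#' images (the weighted mean of bin means by bin counts).
#'
#' @slot metric which metric the bins refer to ("psnr", "ssim" or "niqe").
#' @slot edges numeric bin edges on the low-dose score axis.
#' @slot cells matrix of mean improvements, methods x bins.
#' @slot counts integer image count per bin.
#' @slot overall named numeric per-method overall mean improvement.
#' @seealso [binImprovements()]
#' @exportClass ComparisonTable
setClass("ComparisonTable",
  representation(metric = "character", edges = "numeric", cells = "matrix",
                 counts = "integer", overall = "numeric"))

setMethod("show", "ComparisonTable", function(object) {
  cat(sprintf("ComparisonTable (%s): %d methods x %d bins\n",
              object@metric, nrow(object@cells), ncol(object@cells)))
  print(round(object@cells, 4))
})
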