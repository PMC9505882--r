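## Image and container I/O.
##
## Images travel as plain numeric matrices; on disk they are 16-bit
## grayscale PNG or TIFF (via EBImage). Sinograms and NIQE models persist
## as portable plain-text containers (CSV matrix + JSON sidecar).

#' Read a grayscale image as a numeric matrix
#'
#' Reads a PNG/TIFF (any bit depth EBImage supports), averages colour
#' channels if present, and rescales code values from \[0, 1\] (EBImage's
#' convention) to \[0, `clipMax`\].
#'
#' @param path image file path.
#' @param clipMax intensity of the maximum code value (default 1.5).
#' @return A numeric matrix (rows x columns).
#' @export
readGrayImage <- function(path, clipMax = 1.5) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  a <- EBImage::imageData(img)
  if (length(d) == 3L) a <- apply(a, c(1, 2), mean)
  t(a) * clipMax
}

#' Write a numeric matrix as a 16-bit grayscale image
#'
#' @param image numeric matrix; values are clipped to \[0, `clipMax`\] and
#'   mapped to the full 16-bit range.
#' @param path output path; format follows the extension (tiff carries the
#'   full 16-bit depth; png is stored at 8 bits by the underlying writer).
#' @param clipMax intensity mapped to the maximum code value.
#' @return Invisibly, `path`.
#' @export
writeGrayImage <- function(image, path, clipMax = 1.5) {
  .assertImage(image)
  a <- pmin(pmax(image, 0), clipMax) / clipMax
  EBImage::writeImage(EBImage::Image(t(a)), path, bits.per.sample = 16L)
  invisible(path)
}

#' Persist a sinogram (or counts array) with its acquisition sidecar
#'
#' Writes the value matrix as CSV and, alongside it, a JSON sidecar
#' (`<path>.json`) recording the projection angles and, optionally, the
#' acquisition model parameters.
#'
#' @param sino a [Sinogram-class].
#' @param path CSV output path.
#' @param model optional [AcquisitionModel-class] recorded in the sidecar.
#' @return Invisibly, `path`.
#' @export
writeSinogram <- function(sino, path, model = NULL) {
  stopifnot(is(sino, "Sinogram"))
  utils::write.table(sino@values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(angles = sino@angles)
  if (!is.null(model)) {
    meta$acquisition <- list(
      K = model@K, c = model@c, mA = model@mA, s = model@s,
      dose_fraction = model@doseFraction,
      bowtie = list(kind = model@bowtie@kind,
                    strength = model@bowtie@strength),
      n_angles = model@nAngles, mu_scale = model@muScale,
      poisson_enabled = model@poissonEnabled, seed = model@seed)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a sinogram written by [writeSinogram()]
#'
#' @param path CSV path (expects the `<path>.json` sidecar next to it).
#' @return A [Sinogram-class].
#' @export
readSinogram <- function(path) {
  vals <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(vals) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sinogram(vals, meta$angles)
}

#' Persist a fitted NIQE model
#'
#' Writes the feature mean, covariance and patch metadata as a single JSON
#' container.
#'
#' @param model a [NIQEModel-class].
#' @param path output path (JSON).
#' @return Invisibly, `path`.
#' @export
writeNIQEModel <- function(model, path) {
  stopifnot(is(model, "NIQEModel"))
  jsonlite::write_json(
    list(mu = model@mu, sigma = model@sigma,
         patch_size = model@patchSize,
         sharpness_threshold = model@sharpnessThreshold,
         n_scales = model@nScales),
    path, digits = NA, matrix = "columnmajor")
  invisible(path)
}

#' Read a NIQE model written by [writeNIQEModel()]
#'
#' @param path JSON path.
#' @return A [NIQEModel-class].
#' @export
readNIQEModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("NIQEModel", mu = as.numeric(x$mu),
      sigma = matrix(as.numeric(x$sigma), length(x$mu), length(x$mu)),
      patchSize = as.integer(x$patch_size),
      sharpnessThreshold = as.numeric(x$sharpness_threshold),
      nScales = as.integer(x$n_scales))
}
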