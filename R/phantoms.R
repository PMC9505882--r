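## Synthetic chest-like phantoms and paired clean/low-dose datasets.

#' Generate a chest-like phantom image
#'
#' Draws a square image consisting of a dominant bright body ellipse on a
#' dark (exactly zero) background, with `nStructures` internal ellipses of
#' varied intensity emulating low-contrast anatomy. Internal ellipses are
#' rejection-sampled so that they lie entirely inside the body: this
#' reproduces the "area of interest" (patient body) that concentrates
#' photon noise, without aiming for anatomical realism. Intensities live in
#' \[0, 1\]; attenuation scaling belongs to the acquisition model.
#'
#' Identical specs (including the seed) give bit-identical images.
#'
#' @param spec a [PhantomSpec-class].
#' @return A `spec@size` x `spec@size` numeric matrix with values in \[0, 1\].
#' @examples
#' ph <- generatePhantom(phantomSpec(size = 64, nStructures = 5, seed = 7))
#' range(ph)
#' @seealso [generatePairedDataset()]
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  n <- spec@size
  ctr <- (n + 1) / 2
  a <- spec@bodyAxes[1] * n / 2
  b <- spec@bodyAxes[2] * n / 2
  x <- matrix(seq_len(n), n, n, byrow = TRUE) - ctr
  y <- matrix(seq_len(n), n, n) - ctr
  bodyDist <- (x / a)^2 + (y / b)^2
  img <- matrix(0, n, n)
  .withSeed(spec@seed, {
    body <- runif(1, 0.75, 0.9)
    img[bodyDist <= 1] <- body
    placed <- 0L
    tries <- 0L
    while (placed < spec@nStructures && tries < 200L * (spec@nStructures + 1L)) {
      tries <- tries + 1L
      ## candidate interior ellipse
      cx <- runif(1, -a, a)
      cy <- runif(1, -b, b)
      sa <- runif(1, 0.04, 0.16) * n / 2
      sb <- runif(1, 0.04, 0.16) * n / 2
      ang <- runif(1, 0, pi)
      ## reject unless fully inside the body: the farthest point of the
      ## ellipse from its centre is max(sa, sb); require the centre to be
      ## deep enough that the whole structure fits
      m <- max(sa, sb)
      if (((abs(cx) + m) / a)^2 + ((abs(cy) + m) / b)^2 > 1) next
      v <- runif(1, spec@intensityRange[1], spec@intensityRange[2])
      xr <- (x - cx) * cos(ang) + (y - cy) * sin(ang)
      yr <- -(x - cx) * sin(ang) + (y - cy) * cos(ang)
      img[(xr / sa)^2 + (yr / sb)^2 <= 1] <- v
      placed <- placed + 1L
    }
  })
  img
}

#' Generate a paired clean / synthetic low-dose dataset
#'
#' Produces `nPairs` phantoms together with their synthetic low-dose copies
#' from [simulateLowDose()]. Per-pair seeds are derived deterministically as
#' `seed + i` (for both the phantom geometry and the Poisson draws), so the
#' dataset is fully reproducible while pairs remain independent.
#'
#' @param spec a [PhantomSpec-class] (its own seed is ignored in favour of
#'   the derived per-pair seeds).
#' @param nPairs number of pairs (>= 1).
#' @param model an [AcquisitionModel-class] for the low-dose copies.
#' @param seed base integer seed.
#' @return A [PairedDataset-class].
#' @examples
#' ds <- generatePairedDataset(phantomSpec(size = 32), nPairs = 2,
#'                             model = acquisitionModel(), seed = 1)
#' length(ds)
#' @export
generatePairedDataset <- function(spec, nPairs, model = acquisitionModel(),
                                  seed = 1L) {
  stopifnot(is(spec, "PhantomSpec"), is(model, "AcquisitionModel"))
  nPairs <- as.integer(nPairs)
  if (nPairs < 1L) stop("nPairs must be >= 1", call. = FALSE)
  seeds <- as.integer(seed) + seq_len(nPairs)
  clean <- vector("list", nPairs)
  noisy <- vector("list", nPairs)
  for (i in seq_len(nPairs)) {
    si <- spec
    si@seed <- seeds[i]
    mi <- model
    mi@seed <- seeds[i]
    clean[[i]] <- generatePhantom(si)
    noisy[[i]] <- simulateLowDose(clean[[i]], mi)
  }
  new("PairedDataset", clean = clean, noisy = noisy, acquisition = model,
      seeds = seeds)
}

#' Write a paired dataset as 16-bit images plus a manifest
#'
#' Saves every clean/noisy pair as 16-bit grayscale TIFF (or 8-bit PNG) files and
#' a `manifest.csv` recording pair index, file paths, per-pair seed and the
#' dose fraction. Intensities are mapped from \[0, `clipMax`\] to the 16-bit
#' range.
#'
#' @param dataset a [PairedDataset-class].
#' @param dir output directory (created if needed).
#' @param format `"tiff"` (16-bit) or `"png"` (8-bit code values).
#' @param clipMax intensity mapped to the maximum code value (default 1.5,
#'   the simulator's reconstruction overshoot allowance).
#' @return Invisibly, the manifest data.frame.
#' @export
writePairedDataset <- function(dataset, dir, format = c("tiff", "png"),
                               clipMax = 1.5) {
  stopifnot(is(dataset, "PairedDataset"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset)
  cleanFiles <- file.path(dir, sprintf("clean_%03d.%s", seq_len(n), format))
  noisyFiles <- file.path(dir, sprintf("lowdose_%03d.%s", seq_len(n), format))
  for (i in seq_len(n)) {
    writeGrayImage(dataset@clean[[i]], cleanFiles[i], clipMax = clipMax)
    writeGrayImage(dataset@noisy[[i]], noisyFiles[i], clipMax = clipMax)
  }
  manifest <- data.frame(
    pair = seq_len(n),
    clean = basename(cleanFiles),
    lowdose = basename(noisyFiles),
    seed = dataset@seeds,
    dose_fraction = dataset@acquisition@doseFraction)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a paired dataset written by [writePairedDataset()]
#'
#' @param dir directory containing the images and `manifest.csv`.
#' @param model the [AcquisitionModel-class] to attach (the manifest stores
#'   only the dose fraction).
#' @param clipMax intensity of the maximum code value used when writing.
#' @return A [PairedDataset-class].
#' @export
readPairedDataset <- function(dir, model = acquisitionModel(),
                              clipMax = 1.5) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  clean <- lapply(file.path(dir, manifest$clean), readGrayImage,
                  clipMax = clipMax)
  noisy <- lapply(file.path(dir, manifest$lowdose), readGrayImage,
                  clipMax = clipMax)
  model@doseFraction <- manifest$dose_fraction[1]
  new("PairedDataset", clean = clean, noisy = noisy, acquisition = model,
      seeds = as.integer(manifest$seed))
}
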