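## Evaluation protocol: per-image scoring of every denoiser over a paired
## test set, noise-level-binned comparison tables, and noise masks.

#' Contrast-windowed noise mask
#'
#' Visualises residual noise as the absolute difference between a
#' reference (full-dose) image and a test image, clipped at
#' `contrastFraction` of the reference maximum and rescaled to \[0, 1\]:
#' the conventional display applies the contrast setting at 10% of the
#' maximum pixel value.
#'
#' @param reference full-dose image.
#' @param test low-dose or denoised image, same shape.
#' @param contrastFraction clip point as a fraction of `max(reference)`,
#'   in (0, 1].
#' @return Mask matrix in \[0, 1\].
#' @export
noiseMask <- function(reference, test, contrastFraction = 0.1) {
  .assertImage(reference); .assertImage(test)
  .assertSameShape(reference, test)
  if (contrastFraction <= 0 || contrastFraction > 1)
    stop("contrastFraction must be in (0, 1]", call. = FALSE)
  peak <- max(reference)
  if (peak <= 0)
    stop("reference image is identically zero", call. = FALSE)
  thr <- contrastFraction * peak
  pmin(abs(reference - test), thr) / thr
}

#' Wrap a trained network as a denoising method
#'
#' @param net an [LDCTNetwork-class] (or a [TrainResult-class], whose best
#'   model is used).
#' @return A function mapping an image matrix to its denoised output, for
#'   use in [evaluateMethods()].
#' @export
networkDenoiser <- function(net) {
  if (is(net, "TrainResult")) net <- net@model
  stopifnot(is(net, "LDCTNetwork"))
  function(image) predictNetwork(net, image)
}

#' Score a set of denoising methods over a paired dataset
#'
#' Runs every method on every low-dose image and records PSNR, SSIM and
#' NIQE of the low-dose input and the denoised output together with the
#' improvement scores ([improvementScores()]); aggregates are per-method
#' means. The NIQE model should be fitted on clean images that are not
#' part of the evaluated pairs (e.g. the training split).
#'
#' @param pairs a [PairedDataset-class] (typically the test split).
#' @param methods named list of functions, each mapping an image matrix to
#'   a same-shape matrix.
#' @param model a fitted [NIQEModel-class].
#' @param fmax data range for PSNR/SSIM (default 1).
#' @return A [MetricReport-class].
#' @export
evaluateMethods <- function(pairs, methods, model, fmax = 1) {
  stopifnot(is(pairs, "PairedDataset"), is(model, "NIQEModel"))
  if (length(pairs) < 1L) stop("no pairs to evaluate", call. = FALSE)
  if (!is.list(methods) || is.null(names(methods)) ||
      any(names(methods) == ""))
    stop("methods must be a named list of functions", call. = FALSE)
  rows <- vector("list", length(pairs) * length(methods))
  at <- 0L
  for (i in seq_along(pairs@clean)) {
    low <- pairs@noisy[[i]]
    ref <- pairs@clean[[i]]
    for (nm in names(methods)) {
      den <- methods[[nm]](low)
      if (!identical(dim(den), dim(low)))
        stop(sprintf("method '%s' changed the image shape", nm),
             call. = FALSE)
      at <- at + 1L
      rows[[at]] <- cbind(data.frame(image = i, method = nm),
                          improvementScores(low, den, ref, model, fmax))
    }
  }
  records <- do.call(rbind, rows)
  aggregates <- do.call(rbind, lapply(split(records, records$method),
    function(d) data.frame(
      method = d$method[1],
      psnr_improvement = mean(d$psnr_improvement),
      ssim_improvement = mean(d$ssim_improvement),
      niqe_improvement = mean(d$niqe_improvement))))
  rownames(aggregates) <- NULL
  new("MetricReport", records = records, aggregates = aggregates)
}

#' Noise-level-binned improvement table
#'
#' Groups images into `nBins` equal-width bins of the low-dose score of
#' one metric (the X axis of the comparison charts) and averages each
#' method's improvement per bin, emulating the per-noise-level comparison
#' of denoisers: higher-noise bins sit at low PSNR/SSIM (or high NIQE).
#'
#' @param report a [MetricReport-class].
#' @param metric `"psnr"`, `"ssim"` or `"niqe"`.
#' @param nBins number of equal-width bins (default 8); if all low-dose
#'   scores coincide a single bin is used.
#' @return A [ComparisonTable-class].
#' @export
binImprovements <- function(report, metric = c("psnr", "ssim", "niqe"),
                            nBins = 8L) {
  stopifnot(is(report, "MetricReport"))
  metric <- match.arg(metric)
  nBins <- as.integer(nBins)
  if (nBins < 1L) stop("nBins must be >= 1", call. = FALSE)
  rec <- report@records
  if (nrow(rec) == 0L) stop("empty report", call. = FALSE)
  lowCol <- paste0(metric, "_low")
  impCol <- paste0(metric, "_improvement")
  lowScores <- rec[[lowCol]]
  finiteLow <- lowScores[is.finite(lowScores)]
  rng <- range(finiteLow)
  if (diff(rng) <= 0) {
    nBins <- 1L
    edges <- c(rng[1] - 0.5, rng[1] + 0.5)
  } else {
    edges <- seq(rng[1], rng[2], length.out = nBins + 1L)
  }
  binOf <- pmin(pmax(findInterval(lowScores, edges,
                                  rightmost.closed = TRUE), 1L), nBins)
  methods <- unique(rec$method)
  cells <- matrix(NA_real_, length(methods), nBins,
                  dimnames = list(methods, NULL))
  counts <- integer(nBins)
  for (b in seq_len(nBins)) {
    inBin <- rec[binOf == b, , drop = FALSE]
    counts[b] <- length(unique(inBin$image))
    for (m in methods) {
      v <- inBin[[impCol]][inBin$method == m]
      if (length(v)) cells[m, b] <- mean(v)
    }
  }
  overall <- vapply(methods, function(m)
    mean(rec[[impCol]][rec$method == m]), 0)
  new("ComparisonTable", metric = metric, edges = edges, cells = cells,
      counts = counts, overall = overall)
}

#' Write a metric report as CSV plus a JSON summary
#'
#' @param report a [MetricReport-class].
#' @param path CSV output path; the JSON summary of per-method aggregates
#'   is written next to it as `<path>.json`.
#' @return Invisibly, `path`.
#' @export
writeMetricReport <- function(report, path) {
  stopifnot(is(report, "MetricReport"))
  write.csv(report@records, path, row.names = FALSE)
  jsonlite::write_json(report@aggregates, paste0(path, ".json"),
                       dataframe = "rows", digits = NA)
  invisible(path)
}

#' Read back a metric report, re-validating the improvement identities
#'
#' Rows whose improvement columns do not equal the documented differences
#' of their components (PSNR/SSIM: denoised - low; NIQE: low - denoised)
#' are rejected.
#'
#' @param path CSV path written by [writeMetricReport()].
#' @return A [MetricReport-class].
#' @export
readMetricReport <- function(path) {
  rec <- read.csv(path)
  chk <- function(a, b) {
    ok <- abs(a - b) <= 1e-8 * pmax(1, abs(a))
    ok | (is.infinite(a) & a == b)
  }
  good <- chk(rec$psnr_improvement, rec$psnr_denoised - rec$psnr_low) &
          chk(rec$ssim_improvement, rec$ssim_denoised - rec$ssim_low) &
          chk(rec$niqe_improvement, rec$niqe_low - rec$niqe_denoised)
  if (!all(good))
    stop("improvement identities violated in stored report", call. = FALSE)
  aggregates <- do.call(rbind, lapply(split(rec, rec$method),
    function(d) data.frame(
      method = d$method[1],
      psnr_improvement = mean(d$psnr_improvement),
      ssim_improvement = mean(d$ssim_improvement),
      niqe_improvement = mean(d$niqe_improvement))))
  rownames(aggregates) <- NULL
  new("MetricReport", records = rec, aggregates = aggregates)
}

#' Plot a binned comparison table
#'
#' Grouped bar chart of mean improvement per noise-level bin, one bar
#' group per bin and one colour per method (base graphics).
#'
#' @param table a [ComparisonTable-class].
#' @param file optional PNG path; when given, the plot is written there.
#' @return Invisibly, the cell matrix.
#' @export
plotComparison <- function(table, file = NULL) {
  stopifnot(is(table, "ComparisonTable"))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  mids <- (table@edges[-1] + table@edges[-length(table@edges)]) / 2
  graphics::barplot(table@cells, beside = TRUE,
                    names.arg = sprintf("%.3g", mids),
                    legend.text = rownames(table@cells),
                    xlab = sprintf("low-dose %s score (bin centre)",
                                   table@metric),
                    ylab = sprintf("%s improvement", table@metric))
  invisible(table@cells)
}
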