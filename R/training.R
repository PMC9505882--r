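## Training engine: Adam with staircase learning-rate decay, RMSE loss,
## mini-batches of two images, best-validation-loss checkpointing, and the
## 50/30/20 random split.

#' Training protocol configuration
#'
#' The full-scale protocol is Adam at its default moments
#' (\eqn{\beta_1 = 0.9}, \eqn{\beta_2 = 0.999}, \eqn{\epsilon = 10^{-8}}),
#' learning rate \eqn{10^{-4}} reduced by a factor 0.8 every ten epochs,
#' 300 epochs in mini-batches of two images, and a random 50/30/20
#' train/validation/test split of the image pairs. The first reduction
#' takes effect at epoch 11, so 29 reductions are applied by epoch 300 and
#' the final learning rate is \eqn{10^{-4} \cdot 0.8^{29} \approx 1.5
#' \times 10^{-7}}.
#'
#' @slot epochs number of training epochs.
#' @slot batchSize images per mini-batch.
#' @slot lr0 initial learning rate.
#' @slot lrFactor per-period decay factor in (0, 1).
#' @slot lrPeriod epochs between reductions.
#' @slot beta1,beta2,eps Adam moment parameters.
#' @slot seed integer seed (shuffling, dropout).
#' @slot splitFractions train/validation/test fractions summing to 1.
#' @seealso [trainNetwork()], [lrAtEpoch()], [splitDataset()]
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(epochs = "integer", batchSize = "integer", lr0 = "numeric",
                 lrFactor = "numeric", lrPeriod = "integer",
                 beta1 = "numeric", beta2 = "numeric", eps = "numeric",
                 seed = "integer", splitFractions = "numeric"))

setValidity("TrainConfig", function(object) {
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@lr0 <= 0) return("lr0 must be positive")
  if (object@lrFactor <= 0 || object@lrFactor >= 1)
    return("lrFactor must be in (0, 1)")
  if (object@lrPeriod < 1L) return("lrPeriod must be >= 1")
  f <- object@splitFractions
  if (length(f) != 3L || any(f <= 0) || any(f >= 1))
    return("splitFractions must be three fractions in (0, 1)")
  if (abs(sum(f) - 1) > 1e-9) return("splitFractions must sum to 1")
  TRUE
})

#' @param epochs,batchSize,lr0,lrFactor,lrPeriod,beta1,beta2,eps,seed,splitFractions
#'   see the class slots.
#' @return `trainConfig()` returns a [TrainConfig-class] with the
#'   full-scale defaults.
#' @rdname TrainConfig-class
#' @export
trainConfig <- function(epochs = 300L, batchSize = 2L, lr0 = 1e-4,
                        lrFactor = 0.8, lrPeriod = 10L, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8, seed = 1L,
                        splitFractions = c(0.5, 0.3, 0.2)) {
  new("TrainConfig", epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), lr0 = as.numeric(lr0),
      lrFactor = as.numeric(lrFactor), lrPeriod = as.integer(lrPeriod),
      beta1 = as.numeric(beta1), beta2 = as.numeric(beta2),
      eps = as.numeric(eps), seed = as.integer(seed),
      splitFractions = as.numeric(splitFractions))
}

#' @param ... overrides passed to [trainConfig()].
#' @details `deskTrainConfig()` is the CPU desk-scale profile used
#'   throughout the examples and tests: 20 epochs at a learning rate of
#'   \eqn{10^{-3}} (the far shorter schedule takes proportionally larger
#'   steps), with the same decay law, batch size and split as the
#'   full-scale protocol.
#' @rdname TrainConfig-class
#' @export
deskTrainConfig <- function(...) {
  args <- modifyList(list(epochs = 20L, lr0 = 1e-3), list(...))
  do.call(trainConfig, args)
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: %d epochs, batch %d, lr %g x %g every %d epochs, split %s\n",
    object@epochs, object@batchSize, object@lr0, object@lrFactor,
    object@lrPeriod, paste(object@splitFractions, collapse = "/")))
})

#' Random train/validation/test partition
#'
#' Splits `nPairs` indices into disjoint train/validation/test sets with
#' `floor(f1 * n)` training and `floor(f2 * n)` validation members; the
#' remainder goes to the test set. Seeded and reproducible.
#'
#' @param nPairs number of image pairs (>= 3).
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed integer seed.
#' @return A list with integer index vectors `train`, `validation`, `test`.
#' @examples
#' lengths(splitDataset(986, c(0.5, 0.3, 0.2), seed = 1))  # 493 295 198
#' @export
splitDataset <- function(nPairs, fractions = c(0.5, 0.3, 0.2), seed = 1L) {
  nPairs <- as.integer(nPairs)
  if (nPairs < 3L) stop("need at least 3 pairs to split", call. = FALSE)
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three positive values summing to 1",
         call. = FALSE)
  perm <- .withSeed(seed, sample.int(nPairs))
  nTrain <- floor(fractions[1] * nPairs)
  nVal <- floor(fractions[2] * nPairs)
  if (nTrain < 1L || nVal < 1L || nTrain + nVal >= nPairs)
    stop("degenerate split for this nPairs/fractions combination",
         call. = FALSE)
  list(train = sort(perm[seq_len(nTrain)]),
       validation = sort(perm[nTrain + seq_len(nVal)]),
       test = sort(perm[(nTrain + nVal + 1L):nPairs]))
}

#' Learning rate at a given epoch
#'
#' Staircase decay: epochs 1..`lrPeriod` run at `lr0`, after which the
#' rate is multiplied by `lrFactor` every `lrPeriod` epochs:
#' \deqn{lr(e) = lr_0 \cdot f^{\lfloor (e-1)/p \rfloor}.}
#' Under the full-scale defaults, \eqn{lr(300) = 10^{-4} \cdot 0.8^{29}
#' \approx 1.5 \times 10^{-7}}.
#'
#' @param config a [TrainConfig-class].
#' @param epoch epoch number in `1..config@epochs`.
#' @return The positive learning rate.
#' @examples
#' lrAtEpoch(trainConfig(), 1)    # 1e-4
#' lrAtEpoch(trainConfig(), 300)  # ~1.5e-7
#' @export
lrAtEpoch <- function(config, epoch) {
  stopifnot(is(config, "TrainConfig"))
  epoch <- as.integer(epoch)
  if (epoch < 1L || epoch > config@epochs)
    stop("epoch out of range", call. = FALSE)
  config@lr0 * config@lrFactor^((epoch - 1L) %/% config@lrPeriod)
}

#' Result of a training run
#'
#' @slot model the [LDCTNetwork-class] restored to the epoch with minimum
#'   validation RMSE (best-validation checkpointing; no early stopping).
#' @slot lossHistory data.frame with per-epoch `epoch`, `lr`, `train_rmse`
#'   and `val_rmse`.
#' @slot bestEpoch epoch whose validation RMSE is minimal.
#' @exportClass TrainResult
setClass("TrainResult",
  representation(model = "LDCTNetwork", lossHistory = "data.frame",
                 bestEpoch = "integer"))

#' @param object,x a `TrainResult`.
#' @rdname TrainResult-class
#' @export
bestModel <- function(x) x@model

#' @rdname TrainResult-class
#' @export
lossHistory <- function(x) x@lossHistory

#' @rdname TrainResult-class
#' @export
bestEpoch <- function(x) x@bestEpoch

setMethod("show", "TrainResult", function(object) {
  h <- object@lossHistory
  cat(sprintf(
    "TrainResult: %d epochs, best epoch %d (val RMSE %.5g, train RMSE %.5g)\n",
    nrow(h), object@bestEpoch, h$val_rmse[object@bestEpoch],
    h$train_rmse[object@bestEpoch]))
})

#' Train a denoising network
#'
#' Minimises the per-image RMSE between the network output and the clean
#' target over the training split with Adam, evaluating the validation
#' RMSE once per epoch and returning the parameters of the epoch with the
#' lowest validation loss (which makes early stopping unnecessary). Fully
#' seeded: identical inputs reproduce the loss history.
#'
#' @param net an [LDCTNetwork-class] (its parameters are the starting
#'   point; the input network is not modified).
#' @param data a [PairedDataset-class]; noisy images are inputs, clean
#'   images are targets.
#' @param config a [TrainConfig-class].
#' @param split index partition from [splitDataset()]; defaults to
#'   splitting `length(data)` with `config@splitFractions` and
#'   `config@seed`.
#' @param verbose print per-epoch losses.
#' @return A [TrainResult-class].
#' @examples
#' \donttest{
#' ds <- generatePairedDataset(phantomSpec(size = 32), 6,
#'                             acquisitionModel(nAngles = 32), seed = 1)
#' net <- buildNetwork(networkConfig("modified_unet", inputSize = 32,
#'                                   filters = 4, encoderDepth = 2))
#' fit <- trainNetwork(net, ds, deskTrainConfig(epochs = 2))
#' }
#' @export
trainNetwork <- function(net, data, config = deskTrainConfig(),
                         split = NULL, verbose = FALSE) {
  stopifnot(is(net, "LDCTNetwork"), is(data, "PairedDataset"),
            is(config, "TrainConfig"))
  validObject(config)
  if (is.null(split))
    split <- splitDataset(length(data), config@splitFractions, config@seed)
  if (length(split$train) < 1L || length(split$validation) < 1L)
    stop("empty training or validation split", call. = FALSE)
  params <- net@params
  ## Adam state
  mom <- lapply(params, function(p)
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0))
  tstep <- 0L
  asTensor <- function(img) array(img, c(nrow(img), ncol(img), 1L))
  valRmse <- function() {
    mean(vapply(split$validation, function(i) {
      out <- .netForward(net, asTensor(data@noisy[[i]]))$out
      sqrt(mean((out - asTensor(data@clean[[i]]))^2))
    }, 0))
  }
  hist <- data.frame(epoch = seq_len(config@epochs), lr = NA_real_,
                     train_rmse = NA_real_, val_rmse = NA_real_)
  best <- list(val = Inf, params = params, epoch = 1L)
  .withSeed(config@seed, {
    for (epoch in seq_len(config@epochs)) {
      lr <- lrAtEpoch(config, epoch)
      idx <- split$train[sample.int(length(split$train))]
      batches <- split(idx, ceiling(seq_along(idx) / config@batchSize))
      epochLosses <- numeric(0)
      for (batch in batches) {
        gacc <- NULL
        for (i in batch) {
          x <- asTensor(data@noisy[[i]])
          tgt <- asTensor(data@clean[[i]])
          net@params <- params
          fw <- .netForward(net, x, training = TRUE, keepCache = TRUE)
          resid <- fw$out - tgt
          l <- sqrt(mean(resid^2))
          epochLosses <- c(epochLosses, l)
          if (l <= 0) next
          dOut <- resid / (length(resid) * l * length(batch))
          g <- .netBackward(net, fw, dOut)
          if (is.null(gacc)) gacc <- g
          else for (nm in names(g)) {
            gacc[[nm]]$W <- gacc[[nm]]$W + g[[nm]]$W
            gacc[[nm]]$b <- gacc[[nm]]$b + g[[nm]]$b
          }
        }
        if (is.null(gacc)) next
        tstep <- tstep + 1L
        b1 <- config@beta1; b2 <- config@beta2
        corr1 <- 1 - b1^tstep; corr2 <- 1 - b2^tstep
        for (nm in names(gacc)) {
          st <- mom[[nm]]
          st$mW <- b1 * st$mW + (1 - b1) * gacc[[nm]]$W
          st$vW <- b2 * st$vW + (1 - b2) * gacc[[nm]]$W^2
          st$mb <- b1 * st$mb + (1 - b1) * gacc[[nm]]$b
          st$vb <- b2 * st$vb + (1 - b2) * gacc[[nm]]$b^2
          mom[[nm]] <- st
          params[[nm]]$W <- params[[nm]]$W -
            lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + config@eps)
          params[[nm]]$b <- params[[nm]]$b -
            lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + config@eps)
        }
      }
      net@params <- params
      hist$lr[epoch] <- lr
      hist$train_rmse[epoch] <- mean(epochLosses)
      hist$val_rmse[epoch] <- valRmse()
      if (hist$val_rmse[epoch] < best$val) {
        best <- list(val = hist$val_rmse[epoch], params = params,
                     epoch = epoch)
      }
      if (verbose)
        message(sprintf("epoch %3d  lr %.3g  train %.5g  val %.5g",
                        epoch, lr, hist$train_rmse[epoch],
                        hist$val_rmse[epoch]))
    }
  })
  net@params <- best$params
  new("TrainResult", model = net, lossHistory = hist,
      bestEpoch = as.integer(best$epoch))
}
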