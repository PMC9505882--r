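## Minimal CPU convolutional-network engine.
##
## Tensors are numeric arrays (H, W, C). Convolutions are evaluated as a
## single GEMM per layer against OpenBLAS, using a precomputed gather
## index ("im2col"): weights are matrices of shape (k*k*Cin) x Cout with
## row ordering (dy, dx, cin). Transpose convolutions are implemented as
## the exact adjoint of the corresponding strided convolution, so decoder
## expansion layers and their gradients share the same primitives.

.idxCache <- new.env(parent = emptyenv())

## Gather index mapping a zero-padded (Hp, Wp, C) array to the im2col
## matrix of a k x k convolution with the given stride ("same" padding).
.im2colIdx <- function(H, W, C, k, stride) {
  key <- paste(H, W, C, k, stride, sep = "_")
  hit <- .idxCache[[key]]
  if (!is.null(hit)) return(hit)
  pad <- (k - 1L) %/% 2L
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (H + stride - 1L) %/% stride
  Wo <- (W + stride - 1L) %/% stride
  start <- as.vector(outer(seq(0L, by = stride, length.out = Ho),
                           seq(0L, by = stride, length.out = Wo) * Hp, "+"))
  off <- as.vector(outer(0:(k - 1L), (0:(k - 1L)) * Hp, "+"))
  off <- as.vector(outer(off, (0:(C - 1L)) * (Hp * Wp), "+"))
  idx <- rep(start, times = length(off)) + rep(off, each = length(start)) + 1L
  out <- list(idx = idx, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, pad = pad)
  .idxCache[[key]] <- out
  out
}

.padArray <- function(x, pad) {
  d <- dim(x)
  if (pad == 0L) return(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), ] <- x
  xp
}

## x: (H, W, Cin) -> list(out = (Ho, Wo, Cout), cols) for y = cols %*% W + b
.convGemm <- function(x, W, b, k, stride) {
  d <- dim(x)
  g <- .im2colIdx(d[1], d[2], d[3], k, stride)
  xp <- .padArray(x, g$pad)
  cols <- xp[g$idx]
  dim(cols) <- c(g$Ho * g$Wo, k * k * d[3])
  y <- cols %*% W
  y <- y + rep(b, each = nrow(y))
  dim(y) <- c(g$Ho, g$Wo, length(b))
  list(out = y, cols = cols, inDim = d, g = g)
}

## Scatter-add the adjoint of the gather: dcols (nOut x k*k*C) accumulated
## back into an (H, W, C) array.
.colScatter <- function(dcols, H, W, C, k, stride, g) {
  pad <- g$pad
  dxp <- array(0, c(g$Hp, g$Wp, C))
  rI <- seq(1L, by = stride, length.out = g$Ho)
  cI <- seq(1L, by = stride, length.out = g$Wo)
  for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    colsIdx <- (dy + dx * k) + 1L + k * k * (0:(C - 1L))
    blk <- dcols[, colsIdx, drop = FALSE]
    dim(blk) <- c(g$Ho, g$Wo, C)
    dxp[rI + dy, cI + dx, ] <- dxp[rI + dy, cI + dx, , drop = FALSE] + blk
  }
  if (pad == 0L) return(dxp)
  dxp[(pad + 1L):(pad + H), (pad + 1L):(pad + W), , drop = FALSE]
}

## --- conv layer ------------------------------------------------------------

.convForward <- function(x, p, k, stride, act) {
  cg <- .convGemm(x, p$W, p$b, k, stride)
  y <- cg$out
  mask <- NULL
  if (act == "relu") { mask <- y > 0; y <- y * mask }
  list(out = y, cache = list(cols = cg$cols, inDim = cg$inDim, g = cg$g,
                             mask = mask))
}

.convBackward <- function(dy, p, cache, k, stride) {
  if (!is.null(cache$mask)) dy <- dy * cache$mask
  dmat <- dy; dim(dmat) <- c(cache$g$Ho * cache$g$Wo, length(p$b))
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- tcrossprod(dmat, p$W)
  dx <- .colScatter(dcols, cache$inDim[1], cache$inDim[2], cache$inDim[3],
                    k, stride, cache$g)
  list(dx = dx, dW = dW, db = db)
}

## --- transpose conv layer ---------------------------------------------------
## Weight shape: (k*k*Cout) x Cin (the adjoint of a Cout -> Cin conv).
## stride 2 doubles the spatial extent; stride 1 preserves it.

.tconvForward <- function(x, p, k, stride, act) {
  d <- dim(x)
  Cout <- length(p$b)
  Ho <- d[1] * stride; Wo <- d[2] * stride
  g <- .im2colIdx(Ho, Wo, Cout, k, stride)
  xmat <- x; dim(xmat) <- c(d[1] * d[2], d[3])
  dcols <- tcrossprod(xmat, p$W)            # (nSmall x k*k*Cout)
  y <- .colScatter(dcols, Ho, Wo, Cout, k, stride, g)
  y <- y + rep(p$b, each = Ho * Wo)
  mask <- NULL
  if (act == "relu") { mask <- y > 0; y <- y * mask }
  list(out = y, cache = list(xmat = xmat, inDim = d, g = g, mask = mask))
}

.tconvBackward <- function(dy, p, cache, k, stride) {
  if (!is.null(cache$mask)) dy <- dy * cache$mask
  d <- cache$inDim
  Cout <- dim(dy)[3]
  db <- colSums(matrix(dy, ncol = Cout))
  dyp <- .padArray(dy, cache$g$pad)
  cols <- dyp[cache$g$idx]
  dim(cols) <- c(cache$g$Ho * cache$g$Wo, nrow(p$W))
  dxmat <- cols %*% p$W                     # (nSmall x Cin)
  dW <- crossprod(cols, cache$xmat)         # (k*k*Cout x Cin)
  dx <- dxmat; dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

## --- max pooling (2x2, stride 2) --------------------------------------------

.poolForward <- function(x) {
  d <- dim(x)
  o1 <- seq(1L, d[1], by = 2L); o2 <- seq(2L, d[1], by = 2L)
  p1 <- seq(1L, d[2], by = 2L); p2 <- seq(2L, d[2], by = 2L)
  s <- list(x[o1, p1, , drop = FALSE], x[o2, p1, , drop = FALSE],
            x[o1, p2, , drop = FALSE], x[o2, p2, , drop = FALSE])
  y <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  arg <- (s[[1]] == y) * 1L
  arg[arg == 0 & s[[2]] == y] <- 2L
  arg[arg == 0 & s[[3]] == y] <- 3L
  arg[arg == 0] <- 4L
  list(out = y, cache = list(arg = arg, inDim = d))
}

.poolBackward <- function(dy, cache) {
  d <- cache$inDim
  dx <- array(0, d)
  o1 <- seq(1L, d[1], by = 2L); o2 <- seq(2L, d[1], by = 2L)
  p1 <- seq(1L, d[2], by = 2L); p2 <- seq(2L, d[2], by = 2L)
  rows <- list(o1, o2, o1, o2); cols <- list(p1, p1, p2, p2)
  for (kk in 1:4) {
    m <- (cache$arg == kk) * dy
    dx[rows[[kk]], cols[[kk]], ] <-
      dx[rows[[kk]], cols[[kk]], , drop = FALSE] + m
  }
  dx
}

## --- dropout ----------------------------------------------------------------

.dropForward <- function(x, rate, training) {
  if (!training || rate <= 0)
    return(list(out = x, cache = list(mask = NULL)))
  mask <- (array(runif(length(x)), dim(x)) >= rate) / (1 - rate)
  list(out = x * mask, cache = list(mask = mask))
}

## --- parameter initialisation ----------------------------------------------

## He-uniform fan-in initialisation; for transpose convolutions the
## effective fan-in of one output unit is k^2 * Cin / stride^2.
.initConv <- function(k, Cin, Cout) {
  lim <- sqrt(6 / (k * k * Cin))
  list(W = matrix(runif(k * k * Cin * Cout, -lim, lim), k * k * Cin, Cout),
       b = numeric(Cout))
}

.initTconv <- function(k, Cin, Cout, stride) {
  lim <- sqrt(6 / (k * k * Cin / stride^2))
  list(W = matrix(runif(k * k * Cout * Cin, -lim, lim), k * k * Cout, Cin),
       b = numeric(Cout))
}
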