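## Declarative network zoo: the proposed stacked modified U-Net and the
## reference encoder-decoder architectures, compiled to a flat op graph.

#' Architecture descriptor for the denoising networks
#'
#' Describes one of six encoder-decoder families for regression-based
#' denoising (1-channel in, 1-channel out, linear output):
#'
#' * `stacked_modified_unet` - the proposed model: two stacked U-Nets with
#'   encoder depth 3, a constant filter count on every layer, stride-2
#'   convolution for contraction, transpose-convolution decoders,
#'   concatenation skips within each network and between the stacks.
#' * `modified_unet` - one such network (no stacking).
#' * `unet` - classical U-Net: filters double per depth from the starting
#'   count, max-pooling contraction, concatenation skips, dropout retained.
#' * `segnet_like` - constant filters, max-pooling contraction, plain
#'   convolution decoder, no skips (upsampling uses a stride-2 transpose
#'   convolution in place of max-unpooling indices, for regression
#'   stability).
#' * `deconvnet_like` - as `segnet_like` but with transpose-convolution
#'   decoder blocks.
#' * `rednet` - symmetric chain of convolutions and transpose convolutions
#'   with no contraction or expansion, summation skips every second layer.
#'
#' Blocks before each contraction/expansion hold `blockLayers` stride-1
#' layers (single/dual/triple) of `kernel` x `kernel` filters, each
#' followed by ReLU.
#'
#' @slot family one of the six family names above.
#' @slot stackCount number of stacked sub-networks (2 for the proposed).
#' @slot encoderDepth encoder stages (3 for the proposed; layer count per
#'   half for `rednet`).
#' @slot filters constant filter count, or the starting count for `unet`.
#' @slot blockLayers layers per block, 1-3 (dual = 2 is the proposed).
#' @slot kernel odd kernel size in \{3, 5, 7\}.
#' @slot inputSize default input side (512 at paper scale; any side
#'   divisible by `2^encoderDepth` works at inference).
#' @slot contraction `"stride2_conv"` or `"maxpool"`.
#' @slot decoderOp `"transpose_conv"` or `"conv"` for decoder blocks.
#' @slot skip `"concat"`, `"sum"` or `"none"`.
#' @slot interStackSkip concatenate the first stack's output and final
#'   decoder features into the second stack's input.
#' @slot dropout dropout rate (0 disables; retained only for `unet`).
#' @slot seed integer seed for the He-uniform initialisation.
#' @seealso [buildNetwork()], [networkConfig()]
#' @exportClass NetworkConfig
setClass("NetworkConfig",
  representation(family = "character", stackCount = "integer",
                 encoderDepth = "integer", filters = "integer",
                 blockLayers = "integer", kernel = "integer",
                 inputSize = "integer", contraction = "character",
                 decoderOp = "character", skip = "character",
                 interStackSkip = "logical", dropout = "numeric",
                 seed = "integer"))

setValidity("NetworkConfig", function(object) {
  fams <- c("stacked_modified_unet", "modified_unet", "unet",
            "segnet_like", "deconvnet_like", "rednet")
  if (!object@family %in% fams)
    return(paste("family must be one of:", paste(fams, collapse = ", ")))
  if (object@stackCount < 1L) return("stackCount must be >= 1")
  if (object@encoderDepth < 1L) return("encoderDepth must be >= 1")
  if (object@filters < 1L) return("filters must be >= 1")
  if (!object@blockLayers %in% 1:3)
    return("blockLayers must be 1, 2 or 3 (single/dual/triple)")
  if (!object@kernel %in% c(3L, 5L, 7L))
    return("kernel must be 3, 5 or 7")
  if (!object@contraction %in% c("stride2_conv", "maxpool"))
    return("contraction must be 'stride2_conv' or 'maxpool'")
  if (!object@decoderOp %in% c("transpose_conv", "conv"))
    return("decoderOp must be 'transpose_conv' or 'conv'")
  if (!object@skip %in% c("concat", "sum", "none"))
    return("skip must be 'concat', 'sum' or 'none'")
  if (object@dropout < 0 || object@dropout >= 1)
    return("dropout must be in [0, 1)")
  if (object@family == "stacked_modified_unet" && object@stackCount < 2L)
    return("stacked_modified_unet requires stackCount >= 2")
  if (object@family == "rednet" && object@stackCount != 1L)
    return("rednet is a single-stack family")
  TRUE
})

#' @param family architecture family (see the class description).
#' @param filters constant filter count (starting count for `unet`);
#'   defaults: 128 for the constant-filter families, 64 for `unet`.
#' @param stackCount,encoderDepth,blockLayers,kernel,inputSize,contraction,decoderOp,skip,interStackSkip,dropout,seed
#'   see the class slots; family-appropriate defaults are filled in.
#' @return `networkConfig()` returns a [NetworkConfig-class].
#' @examples
#' networkConfig("stacked_modified_unet", inputSize = 64, filters = 32)
#' @rdname NetworkConfig-class
#' @export
networkConfig <- function(family = c("stacked_modified_unet",
                                     "modified_unet", "unet", "segnet_like",
                                     "deconvnet_like", "rednet"),
                          filters = NULL, stackCount = NULL,
                          encoderDepth = NULL, blockLayers = 2L,
                          kernel = 3L, inputSize = 512L,
                          contraction = NULL, decoderOp = NULL,
                          skip = NULL, interStackSkip = NULL,
                          dropout = NULL, seed = 1L) {
  family <- match.arg(family)
  def <- switch(family,
    stacked_modified_unet = list(filters = 128L, stackCount = 2L,
      encoderDepth = 3L, contraction = "stride2_conv",
      decoderOp = "transpose_conv", skip = "concat", interStackSkip = TRUE,
      dropout = 0),
    modified_unet = list(filters = 128L, stackCount = 1L, encoderDepth = 3L,
      contraction = "stride2_conv", decoderOp = "transpose_conv",
      skip = "concat", interStackSkip = FALSE, dropout = 0),
    unet = list(filters = 64L, stackCount = 1L, encoderDepth = 4L,
      contraction = "maxpool", decoderOp = "conv", skip = "concat",
      interStackSkip = FALSE, dropout = 0.5),
    segnet_like = list(filters = 128L, stackCount = 1L, encoderDepth = 4L,
      contraction = "maxpool", decoderOp = "conv", skip = "none",
      interStackSkip = FALSE, dropout = 0),
    deconvnet_like = list(filters = 128L, stackCount = 1L,
      encoderDepth = 4L, contraction = "maxpool",
      decoderOp = "transpose_conv", skip = "none", interStackSkip = FALSE,
      dropout = 0),
    rednet = list(filters = 128L, stackCount = 1L, encoderDepth = 10L,
      contraction = "stride2_conv", decoderOp = "transpose_conv",
      skip = "sum", interStackSkip = FALSE, dropout = 0))
  pick <- function(x, d) if (is.null(x)) d else x
  new("NetworkConfig", family = family,
      stackCount = as.integer(pick(stackCount, def$stackCount)),
      encoderDepth = as.integer(pick(encoderDepth, def$encoderDepth)),
      filters = as.integer(pick(filters, def$filters)),
      blockLayers = as.integer(blockLayers), kernel = as.integer(kernel),
      inputSize = as.integer(inputSize),
      contraction = pick(contraction, def$contraction),
      decoderOp = pick(decoderOp, def$decoderOp),
      skip = pick(skip, def$skip),
      interStackSkip = isTRUE(pick(interStackSkip, def$interStackSkip)),
      dropout = as.numeric(pick(dropout, def$dropout)),
      seed = as.integer(seed))
}

#' A built denoising network
#'
#' The compiled op graph and its parameters; create with [buildNetwork()],
#' run with [predictNetwork()], fit with [trainNetwork()].
#'
#' @slot config the [NetworkConfig-class] it was built from.
#' @slot ops list of graph operations (internal representation).
#' @slot params named list of weight/bias tensors.
#' @exportClass LDCTNetwork
setClass("LDCTNetwork",
  representation(config = "NetworkConfig", ops = "list", params = "list"))

setMethod("show", "LDCTNetwork", function(object) {
  cat(sprintf("LDCTNetwork (%s): %d ops, %d parameter tensors, %d parameters\n",
              object@config@family, length(object@ops),
              length(object@params), parameterCount(object)))
})

## ---------------------------------------------------------------------------
## graph compiler
## ---------------------------------------------------------------------------

## Ops are lists: type in {conv, tconv, pool, drop, concat, add}; `ins` and
## `out` are tensor names; conv/tconv carry kernel k, stride, act, Cin,
## Cout and a parameter name.
.graphBuilder <- function() {
  ops <- list()
  chans <- list()
  add <- function(op) ops[[length(ops) + 1L]] <<- op
  list(
    conv = function(inp, out, Cin, Cout, k, stride = 1L, act = "relu") {
      add(list(type = "conv", ins = inp, out = out, k = k, stride = stride,
               act = act, Cin = Cin, Cout = Cout, pname = out))
      chans[[out]] <<- Cout
    },
    tconv = function(inp, out, Cin, Cout, k, stride = 1L, act = "relu") {
      add(list(type = "tconv", ins = inp, out = out, k = k, stride = stride,
               act = act, Cin = Cin, Cout = Cout, pname = out))
      chans[[out]] <<- Cout
    },
    pool = function(inp, out) {
      add(list(type = "pool", ins = inp, out = out))
      chans[[out]] <<- chans[[inp]]
    },
    drop = function(inp, out, rate) {
      add(list(type = "drop", ins = inp, out = out, rate = rate))
      chans[[out]] <<- chans[[inp]]
    },
    concat = function(inps, out) {
      add(list(type = "concat", ins = inps, out = out))
      chans[[out]] <<- sum(unlist(chans[inps]))
    },
    add_ = function(inps, out) {
      add(list(type = "add", ins = inps, out = out))
      chans[[out]] <<- chans[[inps[1]]]
    },
    channels = function(nm) chans[[nm]],
    setChannels = function(nm, C) chans[[nm]] <<- C,
    ops = function() ops)
}

## Compile one U-Net-style stack (used by all families except rednet).
.compileStack <- function(g, cfg, inp, inC, tag) {
  k <- cfg@kernel
  nL <- cfg@blockLayers
  D <- cfg@encoderDepth
  doubling <- cfg@family == "unet"
  fAt <- function(d)
    if (doubling) as.integer(cfg@filters * 2^(d - 1L)) else cfg@filters
  cur <- inp; curC <- inC
  skips <- character(D); skipC <- integer(D)
  for (d in seq_len(D)) {
    Fd <- fAt(d)
    for (l in seq_len(nL)) {
      nm <- sprintf("%s_enc%d_%d", tag, d, l)
      g$conv(cur, nm, curC, Fd, k)
      cur <- nm; curC <- Fd
    }
    skips[d] <- cur; skipC[d] <- Fd
    if (cfg@dropout > 0 && d == D) {   # dropout before the last pooling
      nm <- sprintf("%s_drop_enc%d", tag, d)
      g$drop(cur, nm, cfg@dropout)
      cur <- nm
    }
    if (cfg@contraction == "maxpool") {
      nm <- sprintf("%s_pool%d", tag, d)
      g$pool(cur, nm)
      cur <- nm
    } else {
      nm <- sprintf("%s_down%d", tag, d)
      g$conv(cur, nm, curC, Fd, k, stride = 2L)
      cur <- nm; curC <- Fd
    }
  }
  Fb <- if (doubling) as.integer(cfg@filters * 2^D) else cfg@filters
  for (l in seq_len(nL)) {
    nm <- sprintf("%s_bott_%d", tag, l)
    g$conv(cur, nm, curC, Fb, k)
    cur <- nm; curC <- Fb
  }
  if (cfg@dropout > 0) {               # dropout before the first expansion
    nm <- sprintf("%s_drop_bott", tag)
    g$drop(cur, nm, cfg@dropout)
    cur <- nm
  }
  for (d in rev(seq_len(D))) {
    Fd <- fAt(d)
    nm <- sprintf("%s_up%d", tag, d)
    g$tconv(cur, nm, curC, Fd, k, stride = 2L)
    cur <- nm; curC <- Fd
    if (cfg@skip == "concat") {
      nm <- sprintf("%s_cat%d", tag, d)
      g$concat(c(cur, skips[d]), nm)
      cur <- nm; curC <- curC + skipC[d]
    } else if (cfg@skip == "sum") {
      nm <- sprintf("%s_sum%d", tag, d)
      g$add_(c(cur, skips[d]), nm)
      cur <- nm
    }
    for (l in seq_len(nL)) {
      nm <- sprintf("%s_dec%d_%d", tag, d, l)
      if (cfg@decoderOp == "transpose_conv")
        g$tconv(cur, nm, curC, Fd, k)
      else g$conv(cur, nm, curC, Fd, k)
      cur <- nm; curC <- Fd
    }
  }
  out <- sprintf("%s_out", tag)
  g$conv(cur, out, curC, 1L, k, act = "linear")
  list(out = out, feat = cur, featC = curC)
}

## Compile the rednet family: a symmetric conv / transpose-conv chain with
## no contraction or expansion and summation skips every second layer.
.compileRednet <- function(g, cfg, inp) {
  k <- cfg@kernel
  Fi <- cfg@filters
  L <- cfg@encoderDepth
  cur <- inp; curC <- 1L
  enc <- character(L)
  for (i in seq_len(L)) {
    nm <- sprintf("red_enc%d", i)
    g$conv(cur, nm, curC, Fi, k)
    cur <- nm; curC <- Fi
    enc[i] <- nm
  }
  for (i in seq_len(L - 1L)) {
    nm <- sprintf("red_dec%d", i)
    g$tconv(cur, nm, curC, Fi, k)
    cur <- nm
    j <- L - i
    if (i %% 2L == 0L && j >= 1L) {
      nm <- sprintf("red_sum%d", i)
      g$add_(c(cur, enc[j]), nm)
      cur <- nm
    }
  }
  g$tconv(cur, "red_out", Fi, 1L, k, act = "linear")
  list(out = "red_out")
}

#' Build a denoising network from its configuration
#'
#' Compiles the architecture into an op graph and initialises every
#' convolution with seeded He-uniform weights and zero biases. The forward
#' map takes a 1-channel square image and returns the same shape; any
#' input side divisible by `2^encoderDepth` is accepted at run time.
#'
#' @param config a [NetworkConfig-class].
#' @return An [LDCTNetwork-class].
#' @examples
#' net <- buildNetwork(networkConfig("modified_unet", inputSize = 32,
#'                                   filters = 8))
#' dim(predictNetwork(net, matrix(0.5, 32, 32)))
#' @export
buildNetwork <- function(config) {
  stopifnot(is(config, "NetworkConfig"))
  validObject(config)
  if (config@family != "rednet" &&
      config@inputSize %% 2L^config@encoderDepth != 0L)
    stop("inputSize must be divisible by 2^encoderDepth", call. = FALSE)
  g <- .graphBuilder()
  g$setChannels("input", 1L)
  if (config@family == "rednet") {
    .compileRednet(g, config, "input")
  } else {
    cur <- "input"; curC <- 1L
    prev <- NULL
    for (s in seq_len(config@stackCount)) {
      if (s > 1L) {
        if (config@interStackSkip) {
          nm <- sprintf("stack%d_in", s)
          g$concat(c(prev$out, prev$feat), nm)
          cur <- nm; curC <- 1L + prev$featC
        } else {
          cur <- prev$out; curC <- 1L
        }
      }
      prev <- .compileStack(g, config, cur, curC, sprintf("s%d", s))
    }
  }
  ops <- g$ops()
  params <- .withSeed(config@seed, {
    p <- list()
    for (op in ops) {
      if (op$type == "conv")
        p[[op$pname]] <- .initConv(op$k, op$Cin, op$Cout)
      else if (op$type == "tconv")
        p[[op$pname]] <- .initTconv(op$k, op$Cin, op$Cout, op$stride)
    }
    p
  })
  new("LDCTNetwork", config = config, ops = ops, params = params)
}

## Forward pass over the op graph. Returns the output tensor and, when
## `keepCache` is TRUE, the per-op caches needed for backprop.
.netForward <- function(net, x, training = FALSE, keepCache = FALSE) {
  tensors <- new.env(parent = emptyenv())
  assign("input", x, envir = tensors)
  caches <- if (keepCache) vector("list", length(net@ops)) else NULL
  lastOut <- "input"
  for (i in seq_along(net@ops)) {
    op <- net@ops[[i]]
    res <- switch(op$type,
      conv = .convForward(get(op$ins, envir = tensors),
                          net@params[[op$pname]], op$k, op$stride, op$act),
      tconv = .tconvForward(get(op$ins, envir = tensors),
                            net@params[[op$pname]], op$k, op$stride, op$act),
      pool = .poolForward(get(op$ins, envir = tensors)),
      drop = .dropForward(get(op$ins, envir = tensors), op$rate, training),
      concat = {
        parts <- lapply(op$ins, get, envir = tensors)
        d <- dim(parts[[1]])
        Cs <- vapply(parts, function(p) dim(p)[3], 0)
        y <- array(0, c(d[1], d[2], sum(Cs)))
        at <- 0L
        for (p in parts) {
          y[, , (at + 1L):(at + dim(p)[3])] <- p
          at <- at + dim(p)[3]
        }
        list(out = y, cache = list(Cs = Cs))
      },
      add = {
        parts <- lapply(op$ins, get, envir = tensors)
        list(out = parts[[1]] + parts[[2]], cache = NULL)
      })
    assign(op$out, res$out, envir = tensors)
    if (keepCache) caches[[i]] <- res$cache
    lastOut <- op$out
  }
  list(out = get(lastOut, envir = tensors), outName = lastOut,
       caches = caches, tensors = tensors)
}

## Backward pass: accumulates parameter gradients given the gradient of the
## loss with respect to the network output.
.netBackward <- function(net, fw, dOut) {
  dT <- new.env(parent = emptyenv())
  assign(fw$outName, dOut, envir = dT)
  grads <- list()
  pull <- function(nm) {
    if (exists(nm, envir = dT, inherits = FALSE)) get(nm, envir = dT)
    else NULL
  }
  push <- function(nm, g) {
    cur <- pull(nm)
    assign(nm, if (is.null(cur)) g else cur + g, envir = dT)
  }
  for (i in rev(seq_along(net@ops))) {
    op <- net@ops[[i]]
    dy <- pull(op$out)
    if (is.null(dy)) next
    if (op$type == "conv") {
      bk <- .convBackward(dy, net@params[[op$pname]], fw$caches[[i]],
                          op$k, op$stride)
      grads[[op$pname]] <- list(W = bk$dW, b = bk$db)
      push(op$ins, bk$dx)
    } else if (op$type == "tconv") {
      bk <- .tconvBackward(dy, net@params[[op$pname]], fw$caches[[i]],
                           op$k, op$stride)
      grads[[op$pname]] <- list(W = bk$dW, b = bk$db)
      push(op$ins, bk$dx)
    } else if (op$type == "pool") {
      push(op$ins, .poolBackward(dy, fw$caches[[i]]))
    } else if (op$type == "drop") {
      m <- fw$caches[[i]]$mask
      push(op$ins, if (is.null(m)) dy else dy * m)
    } else if (op$type == "concat") {
      Cs <- fw$caches[[i]]$Cs
      at <- 0L
      for (j in seq_along(op$ins)) {
        push(op$ins[j], dy[, , (at + 1L):(at + Cs[j]), drop = FALSE])
        at <- at + Cs[j]
      }
    } else if (op$type == "add") {
      push(op$ins[1], dy)
      push(op$ins[2], dy)
    }
  }
  grads
}

#' Run a network on an image
#'
#' @param net an [LDCTNetwork-class].
#' @param image square numeric matrix whose side is divisible by
#'   `2^encoderDepth` (for the contracting families).
#' @return Numeric matrix of the same shape (the denoised image).
#' @export
predictNetwork <- function(net, image) {
  stopifnot(is(net, "LDCTNetwork"))
  .assertImage(image)
  x <- array(image, c(nrow(image), ncol(image), 1L))
  y <- .netForward(net, x)$out
  matrix(y, nrow(image), ncol(image))
}

#' Composite receptive field of a stack of stride-1 convolutions
#'
#' A block of `nLayers` stride-1 convolutions with `kernel` x `kernel`
#' filters covers a square input region of side
#' \deqn{k + (n - 1)(k - 1):} a dual 3x3 block covers the same 5x5 area as
#' a single 5x5 filter and a triple 3x3 covers a single 7x7, at fewer
#' weight parameters.
#'
#' @param nLayers number of stacked layers (1-3: single/dual/triple).
#' @param kernel odd kernel size.
#' @return Side length of the composite receptive field in pixels.
#' @examples
#' receptiveField(2, 3)  # 5
#' receptiveField(3, 3)  # 7
#' @export
receptiveField <- function(nLayers, kernel = 3L) {
  nLayers <- as.integer(nLayers); kernel <- as.integer(kernel)
  stopifnot(nLayers >= 1L, kernel %% 2L == 1L)
  kernel + (nLayers - 1L) * (kernel - 1L)
}

#' Empirical receptive field by single-pixel perturbation
#'
#' Builds a block of `nLayers` stride-1 convolutions with strictly positive
#' weights, feeds a single centred unit impulse, and measures the side of
#' the output support. With positive weights and ReLU activations no
#' cancellation can occur, so the measured support equals the analytic
#' receptive field of the block.
#'
#' @param nLayers,kernel block description as in [receptiveField()].
#' @param inputSize probe image side (must exceed the receptive field).
#' @param channels filters per layer (small; default 4).
#' @return Measured support side length in pixels.
#' @export
empiricalReceptiveField <- function(nLayers, kernel = 3L, inputSize = 32L,
                                    channels = 4L) {
  g <- .graphBuilder()
  g$setChannels("input", 1L)
  cur <- "input"; curC <- 1L
  for (l in seq_len(nLayers)) {
    g$conv(cur, sprintf("b_%d", l), curC, as.integer(channels),
           as.integer(kernel))
    cur <- sprintf("b_%d", l); curC <- as.integer(channels)
  }
  ops <- g$ops()
  params <- .withSeed(1L, {
    p <- list()
    for (op in ops) {
      p0 <- .initConv(op$k, op$Cin, op$Cout)
      p0$W <- abs(p0$W)     # positive weights: no cancellation
      p[[op$pname]] <- p0
    }
    p
  })
  net <- new("LDCTNetwork",
             config = networkConfig("modified_unet", inputSize = inputSize,
                                    filters = channels),
             ops = ops, params = params)
  x <- array(0, c(inputSize, inputSize, 1L))
  ctr <- (inputSize + 1L) %/% 2L
  x[ctr, ctr, 1L] <- 1
  y <- .netForward(net, x)$out
  support <- apply(y, c(1, 2), max) > 1e-12
  max(sum(rowSums(support) > 0), sum(colSums(support) > 0))
}

#' Count trainable parameters
#'
#' Exact count of weights plus biases by introspection of the built graph.
#'
#' @param x an [LDCTNetwork-class] or a [NetworkConfig-class] (which is
#'   built first).
#' @return Integer parameter count.
#' @export
parameterCount <- function(x) {
  if (is(x, "NetworkConfig")) x <- buildNetwork(x)
  stopifnot(is(x, "LDCTNetwork"))
  sum(vapply(x@params, function(p) length(p$W) + length(p$b), 0))
}
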