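#' Channel configuration for a PINN input
#'
#' A channel describes how one feature view of one side (compound or
#' protein) enters the network:
#' \describe{
#'   \item{dense}{a precomputed feature vector (ECFP bits, aggregated
#'     sentence embeddings); passed through unchanged to the separated
#'     stack.}
#'   \item{dilated_cnn}{token ids of a fixed-length sequence; a trainable
#'     token-embedding layer, stacked 1-D convolutions (valid padding) with
#'     per-layer dilation rates, then global max pooling.}
#'   \item{lstm / blstm}{token ids; a recurrent stack emitting the final
#'     hidden state (both directions concatenated for blstm).  The one-hot
#'     input is consumed directly through the input weight matrix.}
#' }
#'
#' @param kind `"dense"`, `"dilated_cnn"`, `"lstm"` or `"blstm"`.
#' @param inputDim Feature dimension (dense channels only).
#' @param fixedLength,vocabSize Sequence geometry (sequence channels only).
#' @param nFilters,kernelSize,tokenEmbeddingDim,dilationRates Dilated-CNN
#'   hyperparameters (defaults 16, 12, 16, `c(1, 2, 4)`).
#' @param units LSTM/BLSTM hidden units (default 256).
#' @return A `ChannelConfig` list.
#' @export
channelConfig <- function(kind = c("dense", "dilated_cnn", "lstm", "blstm"),
                          inputDim = NULL, fixedLength = NULL,
                          vocabSize = NULL, nFilters = 16L, kernelSize = 12L,
                          tokenEmbeddingDim = 16L, dilationRates = c(1L, 2L, 4L),
                          units = 256L) {
  kind <- match.arg(kind)
  if (kind == "dense") {
    if (is.null(inputDim) || inputDim < 1) {
      stop("dense channel requires inputDim >= 1", call. = FALSE)
    }
  } else {
    if (is.null(fixedLength) || is.null(vocabSize)) {
      stop("sequence channels require fixedLength and vocabSize", call. = FALSE)
    }
    if (kind == "dilated_cnn") {
      rf <- 1L + (kernelSize - 1L) * sum(dilationRates)
      if (rf > fixedLength) {
        stop(sprintf("receptive field %d exceeds fixed length %d", rf,
                     fixedLength), call. = FALSE)
      }
    }
  }
  asInt <- function(x) if (is.null(x)) NULL else as.integer(x)
  structure(list(kind = kind, inputDim = asInt(inputDim),
                 fixedLength = asInt(fixedLength),
                 vocabSize = asInt(vocabSize), nFilters = asInt(nFilters),
                 kernelSize = asInt(kernelSize),
                 tokenEmbeddingDim = asInt(tokenEmbeddingDim),
                 dilationRates = asInt(dilationRates), units = asInt(units)),
            class = "ChannelConfig")
}

# output dimension of a channel before its separated stack
.channelOutDim <- function(cc) {
  switch(cc$kind,
    dense = cc$inputDim,
    dilated_cnn = cc$nFilters,
    lstm = cc$units,
    blstm = 2L * cc$units)
}

#' Full PINN architecture description
#'
#' A pairwise-input neural network: every channel feeds its own *separated*
#' dense stack (no cross-connections before the merge), all channel outputs
#' are concatenated, and a *concatenated* dense stack followed by a single
#' sigmoid unit classifies the pair.  Because each channel contributes
#' exactly its last separated width to the merge, the architecture balances
#' feature ratios regardless of raw input dimensions.
#'
#' Reference widths: separated `c(1024, 256)` per channel for single-channel
#' models (2 separated layers), `256` for multi-channel models (1 layer);
#' one concatenated layer of 256.  Dropout 0.1 on the initial layer, 0.5 on
#' hidden dense layers.
#'
#' @param compoundChannels,proteinChannels Lists of [channelConfig()]s
#'   (at least one per side).
#' @param separatedWidths Integer vector of separated-layer widths applied
#'   to every channel stack (may be empty for a direct merge).
#' @param concatenatedWidths Integer vector of concatenated-layer widths
#'   (at least one).
#' @param dropoutInitial,dropoutHidden Dropout rates in `[0, 1)`.
#' @param activation `"elu"` (default) or `"relu"` is reserved; the engine
#'   implements ELU with slope `eluAlpha`.
#' @param eluAlpha Positive ELU saturation scale.
#' @return A `PinnConfig` list.
#' @export
pinnConfig <- function(compoundChannels, proteinChannels,
                       separatedWidths = c(1024L, 256L),
                       concatenatedWidths = 256L,
                       dropoutInitial = 0.1, dropoutHidden = 0.5,
                       activation = "elu", eluAlpha = 1) {
  if (inherits(compoundChannels, "ChannelConfig")) compoundChannels <- list(compoundChannels)
  if (inherits(proteinChannels, "ChannelConfig")) proteinChannels <- list(proteinChannels)
  if (length(compoundChannels) < 1L || length(proteinChannels) < 1L) {
    stop("at least one channel per side", call. = FALSE)
  }
  if (length(concatenatedWidths) < 1L) {
    stop("at least one concatenated layer", call. = FALSE)
  }
  if (any(c(separatedWidths, concatenatedWidths) < 1L)) {
    stop("layer widths must be positive", call. = FALSE)
  }
  if (dropoutInitial < 0 || dropoutInitial >= 1 ||
      dropoutHidden < 0 || dropoutHidden >= 1) {
    stop("dropout rates must lie in [0, 1)", call. = FALSE)
  }
  structure(list(compoundChannels = compoundChannels,
                 proteinChannels = proteinChannels,
                 separatedWidths = as.integer(separatedWidths),
                 concatenatedWidths = as.integer(concatenatedWidths),
                 dropoutInitial = dropoutInitial,
                 dropoutHidden = dropoutHidden,
                 activation = activation, eluAlpha = eluAlpha),
            class = "PinnConfig")
}

#' Built pairwise-input neural network
#'
#' Handle to a trainable network built by [buildPinn()]: the flat layer
#' list, the wiring of channels into separated and concatenated stacks, and
#' the seed it was initialized from.  Inspect with [layerManifest()] and
#' [countParameters()].
#'
#' @slot config The [pinnConfig()] used to build the model.
#' @slot layers Flat list of layer objects in topological order.
#' @slot channels Wiring: per channel, the layer indices of its chain.
#' @slot top Layer indices of the concatenated stack and output layer.
#' @slot seed Integer initialization seed.
#' @name PinnModel-class
#' @aliases PinnModel
#' @exportClass PinnModel
setClass("PinnModel",
         representation(config = "list", layers = "list", channels = "list",
                        top = "integer", seed = "integer"))

setMethod("show", "PinnModel", function(object) {
  m <- layerManifest(object)
  cat(sprintf("PinnModel: %d channels, %d layers, %s parameters (%s trainable)\n",
              length(object@channels), nrow(m),
              format(countParameters(object), big.mark = ","),
              format(countParameters(object, trainableOnly = TRUE),
                     big.mark = ",")))
})

#' Build a PINN from its configuration
#'
#' All dense weights are drawn Lecun-uniform; biases start at zero (LSTM
#' forget gates at one).  Building is deterministic for a fixed seed.
#'
#' @param config A [pinnConfig()].
#' @param seed Integer seed for the initialization draws.
#' @return A [PinnModel-class].
#' @export
buildPinn <- function(config, seed = 1L) {
  stopifnot(inherits(config, "PinnConfig"))
  .withSeed(seed, {
    layers <- list()
    channels <- list()
    add <- function(l) { layers[[length(layers) + 1L]] <<- l; length(layers) }
    allCc <- c(config$compoundChannels, config$proteinChannels)
    sides <- rep(c("compound", "protein"),
                 c(length(config$compoundChannels),
                   length(config$proteinChannels)))
    for (ci in seq_along(allCc)) {
      cc <- allCc[[ci]]
      nm <- sprintf("%s_ch%d", sides[ci], ci)
      chain <- integer(0)
      blstmPair <- NULL
      if (cc$kind == "dense") {
        chain <- c(chain, add(.dropoutLayer(paste0(nm, "_dropin"),
                                            config$dropoutInitial)))
      } else if (cc$kind == "dilated_cnn") {
        chain <- c(chain, add(.embeddingLayer(paste0(nm, "_embed"),
                                              cc$vocabSize,
                                              cc$tokenEmbeddingDim)))
        inDim <- cc$tokenEmbeddingDim
        for (di in seq_along(cc$dilationRates)) {
          chain <- c(chain, add(.convLayer(sprintf("%s_conv%d", nm, di),
                                           inDim, cc$nFilters, cc$kernelSize,
                                           cc$dilationRates[di],
                                           config$eluAlpha)))
          inDim <- cc$nFilters
        }
        chain <- c(chain, add(.gmaxpoolLayer(paste0(nm, "_pool"))))
      } else if (cc$kind == "lstm") {
        chain <- c(chain, add(.lstmLayer(paste0(nm, "_lstm"), cc$vocabSize,
                                         cc$units)))
      } else {  # blstm
        iF <- add(.lstmLayer(paste0(nm, "_lstm_fwd"), cc$vocabSize, cc$units))
        iR <- add(.lstmLayer(paste0(nm, "_lstm_rev"), cc$vocabSize, cc$units,
                             reverse = TRUE))
        blstmPair <- c(iF, iR)
      }
      dim <- .channelOutDim(cc)
      for (si in seq_along(config$separatedWidths)) {
        w <- config$separatedWidths[si]
        chain <- c(chain, add(.denseLayer(sprintf("%s_sep%d", nm, si),
                                          dim, w, "elu", config$eluAlpha)))
        chain <- c(chain, add(.dropoutLayer(sprintf("%s_sep%d_drop", nm, si),
                                            config$dropoutHidden)))
        dim <- w
      }
      channels[[ci]] <- list(name = nm, side = sides[ci], kind = cc$kind,
                             chain = chain, blstmPair = blstmPair,
                             outDim = dim)
    }
    top <- integer(0)
    dim <- sum(vapply(channels, function(ch) ch$outDim, integer(1)))
    for (ti in seq_along(config$concatenatedWidths)) {
      w <- config$concatenatedWidths[ti]
      top <- c(top, add(.denseLayer(sprintf("concat%d", ti), dim, w, "elu",
                                    config$eluAlpha)))
      top <- c(top, add(.dropoutLayer(sprintf("concat%d_drop", ti),
                                      config$dropoutHidden)))
      dim <- w
    }
    top <- c(top, add(.denseLayer("output", dim, 1L, "linear")))
    new("PinnModel", config = unclass(config), layers = layers,
        channels = channels, top = as.integer(top), seed = as.integer(seed))
  })
}

#' Layer manifest of a built model
#'
#' One row per layer: name, type, parameter count, frozen flag.  The
#' manifest is the surface that transfer-learning freeze masks address.
#'
#' @param model A [PinnModel-class].
#' @return A `data.frame`.
#' @export
layerManifest <- function(model) {
  stopifnot(is(model, "PinnModel"))
  data.frame(
    name = vapply(model@layers, function(l) l$name, character(1)),
    type = vapply(model@layers, function(l) l$type, character(1)),
    n_params = vapply(model@layers, .layerParamCount, integer(1)),
    frozen = vapply(model@layers, function(l) isTRUE(l$frozen), logical(1)),
    stringsAsFactors = FALSE)
}

#' Count model parameters
#'
#' Exact element count of weights and biases, optionally restricted to
#' trainable (unfrozen) layers.
#'
#' @param model A [PinnModel-class].
#' @param trainableOnly Count only unfrozen layers.
#' @return Integer.
#' @export
countParameters <- function(model, trainableOnly = FALSE) {
  m <- layerManifest(model)
  if (trainableOnly) m <- m[!m$frozen, , drop = FALSE]
  sum(m$n_params)
}

#' Parameter count of a plain feed-forward baseline
#'
#' Closed-form count for a fully connected network on a single concatenated
#' input: `inputDim -> hiddenWidths... -> 1`, weights plus biases.  Used to
#' audit the parameter-reduction property of the pairwise architecture.
#'
#' @param inputDim Input dimension of the concatenated feature vector.
#' @param hiddenWidths Integer vector of hidden-layer widths.
#' @return Integer parameter count.
#' @export
ffnnParameterCount <- function(inputDim, hiddenWidths) {
  dims <- c(inputDim, hiddenWidths, 1L)
  sum(dims[-length(dims)] * dims[-1] + dims[-1])
}

## ---- forward / backward over a whole model ------------------------------

# inputs: list, one element per channel in model order (compound channels
# first), each a B x D matrix (dense) or B x L integer id matrix (sequence).
.pinnForward <- function(model, inputs, training = FALSE) {
  layers <- model@layers
  caches <- vector("list", length(layers))
  outs <- vector("list", length(model@channels))
  for (ci in seq_along(model@channels)) {
    ch <- model@channels[[ci]]
    x <- inputs[[ci]]
    if (!is.null(ch$blstmPair)) {
      fF <- .layerForward(layers[[ch$blstmPair[1]]], x, training)
      fR <- .layerForward(layers[[ch$blstmPair[2]]], x, training)
      caches[[ch$blstmPair[1]]] <- fF$cache
      caches[[ch$blstmPair[2]]] <- fR$cache
      x <- cbind(fF$out, fR$out)
    }
    for (li in ch$chain) {
      f <- .layerForward(layers[[li]], x, training)
      caches[[li]] <- f$cache
      x <- f$out
    }
    outs[[ci]] <- x
  }
  x <- do.call(cbind, outs)
  for (li in model@top) {
    f <- .layerForward(layers[[li]], x, training)
    caches[[li]] <- f$cache
    x <- f$out
  }
  list(logits = x[, 1], caches = caches,
       channelDims = vapply(outs, ncol, integer(1)))
}

# dlogits: numeric vector of dLoss/dlogit.  Returns grads indexed like layers.
.pinnBackward <- function(model, fw, dlogits) {
  layers <- model@layers
  grads <- vector("list", length(layers))
  dx <- matrix(dlogits, ncol = 1)
  for (li in rev(model@top)) {
    b <- .layerBackward(layers[[li]], fw$caches[[li]], dx)
    grads[[li]] <- b$grads
    dx <- b$dx
  }
  offsets <- c(0L, cumsum(fw$channelDims))
  for (ci in seq_along(model@channels)) {
    ch <- model@channels[[ci]]
    dch <- dx[, (offsets[ci] + 1L):offsets[ci + 1L], drop = FALSE]
    for (li in rev(ch$chain)) {
      b <- .layerBackward(layers[[li]], fw$caches[[li]], dch)
      grads[[li]] <- b$grads
      dch <- b$dx
      if (is.null(dch)) break  # reached a token-consuming layer
    }
    if (!is.null(ch$blstmPair) && !is.null(dch)) {
      H <- layers[[ch$blstmPair[1]]]$units
      bF <- .layerBackward(layers[[ch$blstmPair[1]]],
                           fw$caches[[ch$blstmPair[1]]],
                           dch[, 1:H, drop = FALSE])
      bR <- .layerBackward(layers[[ch$blstmPair[2]]],
                           fw$caches[[ch$blstmPair[2]]],
                           dch[, (H + 1):(2 * H), drop = FALSE])
      grads[[ch$blstmPair[1]]] <- bF$grads
      grads[[ch$blstmPair[2]]] <- bR$grads
    }
  }
  grads
}

#' Predict interaction probabilities
#'
#' Forward pass with dropout disabled; deterministic for fixed weights.
#'
#' @param model A [PinnModel-class].
#' @param inputs List with one element per channel (compound channels first,
#'   in configuration order): a `B x D` numeric matrix for dense channels or
#'   a `B x L` integer token-id matrix for sequence channels.
#' @return Numeric vector of B probabilities in (0, 1).
#' @export
pinnPredict <- function(model, inputs) {
  stopifnot(is(model, "PinnModel"))
  plogis(.pinnForward(model, inputs, training = FALSE)$logits)
}
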