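# Internal neural-network layer primitives.
#
# A layer is a plain list: list(type, name, params = list(...), frozen,
# ...metadata).  Every layer implements a forward pass returning
# list(out, cache) and a backward pass returning list(dx, grads), with
# grads shaped exactly like params.  Batches are row-major: vectors are
# B x D matrices; sequence activations are lists
# list(mat = (B*L) x C, B = B, L = L) with row index b + (l-1)*B, i.e. the
# column-major flattening of a B x L grid.  Token inputs are B x L integer
# matrices of 1-based ids with 0 marking end-padding.

#' Exponential linear unit
#'
#' `elu(x) = x` for `x >= 0` and `alpha * (exp(x) - 1)` for `x < 0`.
#'
#' @param x Numeric vector/matrix.
#' @param alpha Positive scale of the negative saturation (default 1).
#' @return Same shape as `x`.
#' @export
elu <- function(x, alpha = 1) {
  .assertScalarNumber(alpha, "alpha", positive = TRUE)
  ifelse(x >= 0, x, alpha * (exp(x) - 1))
}

# derivative given pre-activation z and activation a = elu(z)
.eluGrad <- function(z, a, alpha = 1) ifelse(z >= 0, 1, a + alpha)

#' Lecun uniform weight initialization
#'
#' Draws uniformly from `[-sqrt(3 / fanIn), +sqrt(3 / fanIn)]`, the scaling
#' that keeps activation variance stable under fan-in `fanIn`.
#'
#' @param fanIn Positive integer, number of input units feeding a weight.
#' @param dim Integer vector, the shape of the tensor to draw.
#' @param seed Optional integer seed; when `NULL`, draws from the current
#'   RNG state (the model builder seeds once for the whole network).
#' @return An array (matrix for length-2 `dim`) of draws.
#' @export
lecunUniform <- function(fanIn, dim, seed = NULL) {
  if (!is.numeric(fanIn) || length(fanIn) != 1L || fanIn < 1) {
    stop("fanIn must be a positive integer", call. = FALSE)
  }
  bound <- sqrt(3 / fanIn)
  draw <- function() array(runif(prod(dim), -bound, bound), dim = dim)
  if (is.null(seed)) draw() else .withSeed(seed, draw())
}

## ---- constructors -------------------------------------------------------

.denseLayer <- function(name, inDim, outDim, activation = "elu", alpha = 1) {
  list(type = "dense", name = name, frozen = FALSE,
       activation = activation, alpha = alpha,
       inDim = inDim, outDim = outDim,
       params = list(W = lecunUniform(inDim, c(inDim, outDim)),
                     b = matrix(0, nrow = 1, ncol = outDim)))
}

.dropoutLayer <- function(name, rate) {
  list(type = "dropout", name = name, frozen = TRUE, rate = rate,
       params = list())
}

.embeddingLayer <- function(name, vocabSize, dim) {
  list(type = "embedding", name = name, frozen = FALSE,
       vocabSize = vocabSize, dim = dim,
       params = list(E = matrix(runif(vocabSize * dim, -0.05, 0.05),
                                nrow = vocabSize)))
}

.convLayer <- function(name, inDim, nFilters, kernel, dilation, alpha = 1) {
  list(type = "conv1d", name = name, frozen = FALSE,
       inDim = inDim, nFilters = nFilters, kernel = kernel,
       dilation = dilation, alpha = alpha,
       params = list(W = lecunUniform(kernel * inDim,
                                      c(kernel * inDim, nFilters)),
                     b = matrix(0, nrow = 1, ncol = nFilters)))
}

.gmaxpoolLayer <- function(name) {
  list(type = "gmaxpool", name = name, frozen = TRUE, params = list())
}

.lstmLayer <- function(name, vocabSize, units, reverse = FALSE) {
  H <- units
  b <- matrix(0, nrow = 1, ncol = 4 * H)
  b[1, (H + 1):(2 * H)] <- 1  # forget-gate bias
  list(type = "lstm", name = name, frozen = FALSE,
       vocabSize = vocabSize, units = H, reverse = reverse,
       params = list(Wx = lecunUniform(vocabSize, c(vocabSize, 4 * H)),
                     Wh = lecunUniform(H, c(H, 4 * H)),
                     b = b))
}

## ---- forward ------------------------------------------------------------

.layerForward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    dense = {
      Z <- x %*% layer$params$W
      Z <- sweep(Z, 2, layer$params$b, "+")
      A <- if (layer$activation == "elu") elu(Z, layer$alpha) else Z
      list(out = A, cache = list(x = x, Z = Z, A = A))
    },
    dropout = {
      if (!training || layer$rate <= 0) {
        list(out = x, cache = list(mask = NULL))
      } else {
        mask <- (matrix(runif(length(x)), nrow = nrow(x)) >= layer$rate) /
          (1 - layer$rate)
        list(out = x * mask, cache = list(mask = mask))
      }
    },
    embedding = {
      ids <- as.vector(x)              # B x L, column-major
      B <- nrow(x); L <- ncol(x)
      M <- matrix(0, nrow = B * L, ncol = layer$dim)
      nz <- ids > 0L
      M[nz, ] <- layer$params$E[ids[nz], , drop = FALSE]
      list(out = list(mat = M, B = B, L = L),
           cache = list(ids = ids, nz = nz, B = B, L = L))
    },
    conv1d = {
      B <- x$B; L <- x$L; k <- layer$kernel; dil <- layer$dilation
      Lout <- L - (k - 1L) * dil
      if (Lout < 1L) {
        stop(sprintf("receptive field %d exceeds sequence length %d",
                     1L + (k - 1L) * dil, L), call. = FALSE)
      }
      idx <- lapply(0:(k - 1L), function(j)
        rep(seq_len(B), times = Lout) +
          (rep(seq_len(Lout), each = B) + j * dil - 1L) * B)
      Xcol <- do.call(cbind, lapply(idx, function(i) x$mat[i, , drop = FALSE]))
      Z <- Xcol %*% layer$params$W
      Z <- sweep(Z, 2, layer$params$b, "+")
      A <- elu(Z, layer$alpha)
      list(out = list(mat = A, B = B, L = Lout),
           cache = list(Xcol = Xcol, Z = Z, A = A, idx = idx,
                        Bin = B, Lin = L))
    },
    gmaxpool = {
      B <- x$B; L <- x$L; nF <- ncol(x$mat)
      arr <- array(x$mat, dim = c(B, L, nF))
      best <- arr[, 1, , drop = FALSE]; dim(best) <- c(B, nF)
      arg <- matrix(1L, nrow = B, ncol = nF)
      if (L > 1L) for (l in 2:L) {
        cur <- arr[, l, , drop = FALSE]; dim(cur) <- c(B, nF)
        upd <- cur > best
        best[upd] <- cur[upd]
        arg[upd] <- l
      }
      list(out = best, cache = list(arg = arg, B = B, L = L, nF = nF))
    },
    lstm = {
      B <- nrow(x); L <- ncol(x); H <- layer$units
      Wx <- layer$params$Wx; Wh <- layer$params$Wh; b <- layer$params$b
      h <- matrix(0, B, H); cc <- matrix(0, B, H)
      order <- if (isTRUE(layer$reverse)) rev(seq_len(L)) else seq_len(L)
      steps <- vector("list", L)
      for (s in seq_len(L)) {
        t <- order[s]
        ids <- x[, t]
        Xc <- matrix(0, B, 4 * H)
        nz <- ids > 0L
        if (any(nz)) Xc[nz, ] <- Wx[ids[nz], , drop = FALSE]
        G <- Xc + h %*% Wh
        G <- sweep(G, 2, b, "+")
        i <- plogis(G[, 1:H, drop = FALSE])
        f <- plogis(G[, (H + 1):(2 * H), drop = FALSE])
        g <- tanh(G[, (2 * H + 1):(3 * H), drop = FALSE])
        o <- plogis(G[, (3 * H + 1):(4 * H), drop = FALSE])
        cPrev <- cc
        cc <- f * cPrev + i * g
        tc <- tanh(cc)
        hPrev <- h
        h <- o * tc
        steps[[s]] <- list(ids = ids, i = i, f = f, g = g, o = o,
                           cPrev = cPrev, tc = tc, hPrev = hPrev)
      }
      list(out = h, cache = list(steps = steps, B = B, L = L))
    },
    stop("unknown layer type: ", layer$type)
  )
}

## ---- backward -----------------------------------------------------------

.layerBackward <- function(layer, cache, dout) {
  switch(layer$type,
    dense = {
      dZ <- if (layer$activation == "elu") {
        dout * .eluGrad(cache$Z, cache$A, layer$alpha)
      } else dout
      list(dx = dZ %*% t(layer$params$W),
           grads = list(W = crossprod(cache$x, dZ),
                        b = matrix(colSums(dZ), nrow = 1)))
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = list())
      else list(dx = dout * cache$mask, grads = list())
    },
    embedding = {
      dE <- matrix(0, nrow = layer$vocabSize, ncol = layer$dim)
      nz <- cache$nz
      if (any(nz)) {
        agg <- rowsum(dout$mat[nz, , drop = FALSE], group = cache$ids[nz])
        dE[as.integer(rownames(agg)), ] <- agg
      }
      list(dx = NULL, grads = list(E = dE))
    },
    conv1d = {
      dZ <- dout$mat * .eluGrad(cache$Z, cache$A, layer$alpha)
      dW <- crossprod(cache$Xcol, dZ)
      db <- matrix(colSums(dZ), nrow = 1)
      dXcol <- dZ %*% t(layer$params$W)
      Cin <- layer$inDim
      dX <- matrix(0, nrow = cache$Bin * cache$Lin, ncol = Cin)
      for (j in seq_along(cache$idx)) {
        cols <- ((j - 1L) * Cin + 1L):(j * Cin)
        dX[cache$idx[[j]], ] <- dX[cache$idx[[j]], , drop = FALSE] +
          dXcol[, cols, drop = FALSE]
      }
      list(dx = list(mat = dX, B = cache$Bin, L = cache$Lin),
           grads = list(W = dW, b = db))
    },
    gmaxpool = {
      B <- cache$B; nF <- cache$nF
      dX <- matrix(0, nrow = B * cache$L, ncol = nF)
      rows <- rep(seq_len(B), nF) + (as.vector(cache$arg) - 1L) * B
      cols <- rep(seq_len(nF), each = B)
      dX[cbind(rows, cols)] <- as.vector(dout)
      list(dx = list(mat = dX, B = B, L = cache$L), grads = list())
    },
    lstm = {
      B <- cache$B; L <- cache$L; H <- layer$units
      Wh <- layer$params$Wh
      dWx <- matrix(0, nrow = layer$vocabSize, ncol = 4 * H)
      dWh <- matrix(0, nrow = H, ncol = 4 * H)
      db <- matrix(0, nrow = 1, ncol = 4 * H)
      dh <- dout; dc <- matrix(0, B, H)
      for (s in rev(seq_len(L))) {
        st <- cache$steps[[s]]
        dO <- dh * st$tc
        dc <- dc + dh * st$o * (1 - st$tc^2)
        cNew <- st$f * st$cPrev + st$i * st$g   # = c_t
        dI <- dc * st$g
        dF <- dc * st$cPrev
        dG <- dc * st$i
        dcPrev <- dc * st$f
        dGate <- cbind(dI * st$i * (1 - st$i),
                       dF * st$f * (1 - st$f),
                       dG * (1 - st$g^2),
                       dO * st$o * (1 - st$o))
        nz <- st$ids > 0L
        if (any(nz)) {
          agg <- rowsum(dGate[nz, , drop = FALSE], group = st$ids[nz])
          ridx <- as.integer(rownames(agg))
          dWx[ridx, ] <- dWx[ridx, , drop = FALSE] + agg
        }
        dWh <- dWh + crossprod(st$hPrev, dGate)
        db <- db + colSums(dGate)
        dh <- dGate %*% t(Wh)
        dc <- dcPrev
      }
      list(dx = NULL, grads = list(Wx = dWx, Wh = dWh, b = db))
    },
    stop("unknown layer type: ", layer$type)
  )
}

# number of scalar parameters in a layer
.layerParamCount <- function(layer) {
  if (length(layer$params) == 0L) return(0L)
  sum(vapply(layer$params, length, integer(1)))
}
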