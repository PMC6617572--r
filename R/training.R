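#' Training configuration
#'
#' Adam with the reference hyperparameters: learning rate 5e-4, beta1 0.9,
#' beta2 0.999, mini-batch 1024 and weight decay 1e-5, where *weight decay*
#' reduces the learning rate over updates (`lr_t = lr / (1 + decay * t)`);
#' an optional `l2` penalty is available separately for comparison.  The
#' epoch budget defaults to 400 (the cross-validation protocol; 500 is the
#' final-training setting) with early stopping on validation MCC.
#'
#' @param learningRate Initial Adam step size.
#' @param beta1,beta2 Adam moment decays.
#' @param weightDecay Learning-rate decay per update.
#' @param l2 Optional L2 coefficient added to weight gradients (default 0).
#' @param batchSize Mini-batch size (scale down for desk-scale runs).
#' @param maxEpochs Epoch budget.
#' @param patience Early-stopping patience in epochs (on validation MCC).
#' @param seed Integer seed governing shuffling, dropout and initialization
#'   of re-drawn layers.
#' @return A `TrainConfig` list.
#' @export
trainConfig <- function(learningRate = 5e-4, beta1 = 0.9, beta2 = 0.999,
                        weightDecay = 1e-5, l2 = 0, batchSize = 1024L,
                        maxEpochs = 400L, patience = 20L, seed = 1L) {
  for (nm in c("learningRate", "beta1", "beta2", "batchSize", "maxEpochs",
               "patience")) {
    .assertScalarNumber(get(nm), nm, positive = TRUE)
  }
  if (weightDecay < 0 || l2 < 0) stop("decay rates must be >= 0", call. = FALSE)
  structure(list(learningRate = learningRate, beta1 = beta1, beta2 = beta2,
                 weightDecay = weightDecay, l2 = l2,
                 batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Per-feature standardization fitted on a training split
#'
#' Centers to zero mean and scales to unit variance using *population*
#' statistics of the fitting rows only.  Zero-variance features map to 0.
#'
#' @slot center,scale Numeric vectors of per-feature means and standard
#'   deviations (population, i.e. divisor n).
#' @slot degenerate Logical vector flagging zero-variance features.
#' @slot fittedOn Free-text identifier of the fitting split.
#' @name Normalizer-class
#' @aliases Normalizer
#' @exportClass Normalizer
setClass("Normalizer",
         representation(center = "numeric", scale = "numeric",
                        degenerate = "logical", fittedOn = "character"))

setMethod("show", "Normalizer", function(object) {
  cat(sprintf("Normalizer: %d features (%d degenerate), fitted on %s\n",
              length(object@center), sum(object@degenerate), object@fittedOn))
})

#' @param features Numeric matrix (rows = examples).
#' @param trainIdx Row indices of the fitting split (default: all rows).
#' @param fittedOn Identifier recorded on the object.
#' @rdname Normalizer-class
#' @export
fitNormalizer <- function(features, trainIdx = seq_len(nrow(features)),
                          fittedOn = "train") {
  if (length(trainIdx) == 0L) stop("empty split", call. = FALSE)
  X <- features[trainIdx, , drop = FALSE]
  if (nrow(X) < 2L) stop("need at least 2 rows to fit a normalizer", call. = FALSE)
  mu <- colMeans(X)
  sdev <- sqrt(colMeans(sweep(X, 2, mu)^2))  # population sd
  degen <- sdev <= .Machine$double.eps * 10
  sdev[degen] <- 1
  new("Normalizer", center = mu, scale = sdev, degenerate = degen,
      fittedOn = fittedOn)
}

#' Apply or invert a fitted normalizer
#'
#' @param normalizer A [Normalizer-class].
#' @param features Numeric matrix with the same columns as the fitting data.
#' @return Transformed matrix; zero-variance columns become identically 0
#'   under `normalizeFeatures` (and are not restored by
#'   `denormalizeFeatures` beyond their constant fitted mean).
#' @export
normalizeFeatures <- function(normalizer, features) {
  X <- sweep(sweep(features, 2, normalizer@center), 2, normalizer@scale, "/")
  X[, normalizer@degenerate] <- 0
  X
}

#' @rdname normalizeFeatures
#' @export
denormalizeFeatures <- function(normalizer, features) {
  X <- sweep(features, 2, normalizer@scale, "*")
  X <- sweep(X, 2, normalizer@center, "+")
  X[, normalizer@degenerate] <- rep(normalizer@center[normalizer@degenerate],
                                    each = nrow(features))
  X
}

#' Class weights for imbalanced binary training
#'
#' The balanced heuristic: negatives weigh 1, positives weigh
#' `n_neg / n_pos`, so the two classes contribute equal total loss mass.
#'
#' @param labels 0/1 vector with both classes present.
#' @return Named numeric vector `c(wPos = ..., wNeg = 1)`.
#' @export
computeClassWeights <- function(labels) {
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0L || nNeg == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  c(wPos = nNeg / nPos, wNeg = 1)
}

# class-weighted binary cross-entropy on logits; returns loss and dlogit
.weightedBce <- function(logits, y, wPos, wNeg) {
  p <- plogis(logits)
  w <- ifelse(y == 1, wPos, wNeg)
  eps <- 1e-12
  loss <- -mean(w * (y * log(p + eps) + (1 - y) * log(1 - p + eps)))
  list(loss = loss, dlogits = w * (p - y) / length(y))
}

## ---- Adam ---------------------------------------------------------------

.adamInit <- function(model) {
  list(step = 0L,
       m = lapply(model@layers, function(l) lapply(l$params, function(p) p * 0)),
       v = lapply(model@layers, function(l) lapply(l$params, function(p) p * 0)))
}

.adamStep <- function(model, grads, opt, tc) {
  opt$step <- opt$step + 1L
  lr <- tc$learningRate / (1 + tc$weightDecay * opt$step)
  b1 <- tc$beta1; b2 <- tc$beta2; eps <- 1e-8
  c1 <- 1 - b1^opt$step; c2 <- 1 - b2^opt$step
  for (li in seq_along(model@layers)) {
    layer <- model@layers[[li]]
    if (isTRUE(layer$frozen) || length(layer$params) == 0L ||
        is.null(grads[[li]])) next
    for (pn in names(layer$params)) {
      g <- grads[[li]][[pn]]
      if (tc$l2 > 0 && pn != "b") g <- g + tc$l2 * layer$params[[pn]]
      m <- b1 * opt$m[[li]][[pn]] + (1 - b1) * g
      v <- b2 * opt$v[[li]][[pn]] + (1 - b2) * g * g
      opt$m[[li]][[pn]] <- m
      opt$v[[li]][[pn]] <- v
      model@layers[[li]]$params[[pn]] <- layer$params[[pn]] -
        lr * (m / c1) / (sqrt(v / c2) + eps)
    }
  }
  list(model = model, opt = opt)
}

## ---- training loop ------------------------------------------------------

.subsetInputs <- function(inputs, idx) {
  lapply(inputs, function(x) x[idx, , drop = FALSE])
}

# Core epoch loop shared by train, pretraining and finetuning.
# data: list(inputs = list of per-pair channel matrices, labels,
#            trainIdx, valIdx, [testIdx]).
# Continues from a supplied optimizer state; RNG is the caller's.
.nnTrainEpochs <- function(model, data, tc, epochs, opt, classWeights,
                           startEpoch = 0L, evalTest = FALSE) {
  trainIdx <- data$trainIdx
  history <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    t0 <- proc.time()[3]
    ord <- trainIdx[sample.int(length(trainIdx))]
    totalLoss <- 0; nBatches <- 0L
    for (start in seq(1L, length(ord), by = tc$batchSize)) {
      idx <- ord[start:min(start + tc$batchSize - 1L, length(ord))]
      fw <- .pinnForward(model, .subsetInputs(data$inputs, idx),
                         training = TRUE)
      lb <- .weightedBce(fw$logits, data$labels[idx],
                         classWeights["wPos"], classWeights["wNeg"])
      if (!is.finite(lb$loss)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d",
                     startEpoch + ep), call. = FALSE)
      }
      totalLoss <- totalLoss + lb$loss; nBatches <- nBatches + 1L
      grads <- .pinnBackward(model, fw, lb$dlogits)
      st <- .adamStep(model, grads, opt, tc)
      model <- st$model; opt <- st$opt
    }
    valScores <- pinnPredict(model, .subsetInputs(data$inputs, data$valIdx))
    valLabels <- data$labels[data$valIdx]
    rec <- data.frame(
      epoch = startEpoch + ep,
      loss = totalLoss / nBatches,
      valMcc = mcc(confusionCounts(valScores, valLabels)),
      valRoc = rocAuc(valScores, valLabels),
      seconds = proc.time()[3] - t0)
    if (evalTest && !is.null(data$testIdx)) {
      ts <- pinnPredict(model, .subsetInputs(data$inputs, data$testIdx))
      tl <- data$labels[data$testIdx]
      rec$testMcc <- mcc(confusionCounts(ts, tl))
      rec$testPrc <- prcAuc(ts, tl)
    }
    history[[ep]] <- rec
  }
  list(model = model, opt = opt, history = do.call(rbind, history))
}

#' Train a PINN on a split dataset
#'
#' Minimizes class-weighted binary cross-entropy with Adam, recording one
#' history row per completed epoch (training loss, validation MCC and ROC,
#' wall-clock seconds; test MCC/PRC when `evalTest` and a test split are
#' given).  Stops at `maxEpochs` or when validation MCC has not improved
#' for `patience` epochs; the returned model carries the best-validation
#' weights.  Deterministic for a fixed `config$seed` under single-threaded
#' execution.
#'
#' @param model A built [PinnModel-class].
#' @param data List with elements `inputs` (list of per-pair channel
#'   matrices, compound channels first), `labels` (0/1), `trainIdx`,
#'   `valIdx`, optionally `testIdx`.
#' @param config A [trainConfig()].
#' @param classWeights `"balanced"` (default; computed from the training
#'   labels via [computeClassWeights()]), `"none"`, or a vector
#'   `c(wPos=, wNeg=)`.
#' @param evalTest Also evaluate the test split every epoch.
#' @return List with `model` (best weights), `history` (data frame),
#'   `optimizer` (final Adam state), `bestEpoch`.
#' @export
trainPinn <- function(model, data, config = trainConfig(),
                      classWeights = "balanced", evalTest = FALSE) {
  stopifnot(is(model, "PinnModel"), inherits(config, "TrainConfig"))
  if (is.null(data$trainIdx) || is.null(data$valIdx)) {
    stop("data must carry trainIdx and valIdx splits", call. = FALSE)
  }
  cw <- .resolveClassWeights(classWeights, data$labels[data$trainIdx])
  .withSeed(config$seed, {
    opt <- .adamInit(model)
    best <- list(metric = -Inf, model = model, epoch = 0L)
    history <- NULL
    done <- 0L
    while (done < config$maxEpochs) {
      out <- .nnTrainEpochs(model, data, config, 1L, opt, cw,
                            startEpoch = done, evalTest = evalTest)
      model <- out$model; opt <- out$opt
      history <- rbind(history, out$history)
      done <- done + 1L
      cur <- out$history$valMcc[1]
      if (cur > best$metric) {
        best <- list(metric = cur, model = model, epoch = done)
      }
      if (done - best$epoch >= config$patience) break
    }
    list(model = best$model, history = history, optimizer = opt,
         bestEpoch = best$epoch)
  })
}

.resolveClassWeights <- function(classWeights, trainLabels) {
  if (identical(classWeights, "balanced")) {
    computeClassWeights(trainLabels)
  } else if (identical(classWeights, "none")) {
    c(wPos = 1, wNeg = 1)
  } else {
    stopifnot(all(c("wPos", "wNeg") %in% names(classWeights)))
    classWeights
  }
}

#' Stratified k-fold cross-validation over the validation portion
#'
#' Splits the validation indices into k label-stratified folds; each fold
#' serves once as the monitored validation set while training on the full
#' training split.  Fold assignment is reproducible from `config$seed`.
#'
#' @param modelFactory Zero-argument function returning a fresh
#'   [PinnModel-class].
#' @param data As in [trainPinn()].
#' @param config A [trainConfig()].
#' @param k Number of folds (default 5).
#' @param classWeights Passed to [trainPinn()].
#' @return List with `folds` (list of per-fold results), `metrics` (numeric
#'   vector of best validation MCC per fold), `mean`, `sem`,
#'   `foldAssignment`.
#' @export
crossValidate <- function(modelFactory, data, config = trainConfig(), k = 5L,
                          classWeights = "balanced") {
  valIdx <- data$valIdx
  labels <- data$labels[valIdx]
  assign <- .withSeed(config$seed, .stratifiedFolds(labels, k))
  if (any(vapply(seq_len(k), function(f)
    length(unique(labels[assign == f])) < 2L, logical(1)))) {
    stop("a fold is missing a class; reduce k or rebalance", call. = FALSE)
  }
  folds <- lapply(seq_len(k), function(f) {
    d <- data
    d$valIdx <- valIdx[assign == f]
    fit <- trainPinn(modelFactory(), d, config, classWeights)
    list(fit = fit, metric = max(fit$history$valMcc))
  })
  metrics <- vapply(folds, function(f) f$metric, numeric(1))
  list(folds = folds, metrics = metrics, mean = mean(metrics),
       sem = .sem(metrics), foldAssignment = assign)
}

# label-stratified fold ids (1..k) for a 0/1 label vector
.stratifiedFolds <- function(labels, k) {
  assign <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    assign[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(k), length(idx))
  }
  assign
}
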