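#' Pretraining checkpoint schedule
#'
#' Checkpoints are taken every `interval` pretraining epochs; `PM_0` is the
#' untrained initialization.  Reference protocol: 140 pretraining epochs,
#' checkpoint every 5, 200 finetuning epochs with early stopping.
#'
#' @param totalEpochs Pretraining epoch budget (default 140).
#' @param interval Checkpoint interval in epochs (default 5).
#' @return A `PretrainSchedule` list with the checkpoint epoch vector.
#' @export
pretrainSchedule <- function(totalEpochs = 140L, interval = 5L) {
  .assertScalarNumber(totalEpochs, "totalEpochs", positive = TRUE)
  .assertScalarNumber(interval, "interval", positive = TRUE)
  structure(list(totalEpochs = as.integer(totalEpochs),
                 interval = as.integer(interval),
                 epochs = seq(0L, as.integer(totalEpochs),
                              by = as.integer(interval))),
            class = "PretrainSchedule")
}

#' Pretrain a model, checkpointing every few epochs
#'
#' Trains on the source task without early stopping (the schedule owns the
#' budget), snapshotting the full model at every schedule point; `PM_0` is
#' saved before any update.  Optimizer state persists across the whole
#' pretraining run; each later finetune starts its own fresh optimizer.
#'
#' @param model A built [PinnModel-class].
#' @param data Source-task tensors as in [trainPinn()].
#' @param schedule A [pretrainSchedule()].
#' @param config A [trainConfig()] (its `maxEpochs`/`patience` are ignored
#'   here).
#' @param classWeights As in [trainPinn()].
#' @param dir Optional directory: checkpoints are also written to
#'   `pm_<epoch>/` via [writeCheckpoint()].
#' @return Named list `pm_0`, `pm_<interval>`, ...: each a checkpoint list
#'   with `model`, `epoch`, `history` (cumulative), `seed`.
#' @export
pretrainWithCheckpoints <- function(model, data, schedule = pretrainSchedule(),
                                    config = trainConfig(),
                                    classWeights = "balanced", dir = NULL) {
  stopifnot(is(model, "PinnModel"), inherits(schedule, "PretrainSchedule"))
  cw <- .resolveClassWeights(classWeights, data$labels[data$trainIdx])
  .withSeed(config$seed, {
    opt <- .adamInit(model)
    history <- NULL
    checkpoints <- list()
    snap <- function(epoch) {
      list(model = model, epoch = epoch, history = history,
           seed = config$seed)
    }
    checkpoints[["pm_0"]] <- snap(0L)
    done <- 0L
    for (target in schedule$epochs[-1]) {
      out <- .nnTrainEpochs(model, data, config, target - done, opt, cw,
                            startEpoch = done)
      model <- out$model; opt <- out$opt
      history <- rbind(history, out$history)
      done <- target
      checkpoints[[sprintf("pm_%d", target)]] <- snap(target)
    }
    if (!is.null(dir)) {
      for (nm in names(checkpoints)) {
        writeCheckpoint(checkpoints[[nm]],
                        file.path(dir, sub("^pm_", "pm_", nm)))
      }
    }
    checkpoints
  })
}

#' Write and restore a checkpoint directory
#'
#' Layout: `pm_<epoch>/` containing `weights.rds` (the full model object),
#' `config.yaml` (architecture configuration) and `seed.txt`.  Restoring
#' returns a checkpoint whose model is bit-identical to the saved one.
#'
#' @param checkpoint A checkpoint list from [pretrainWithCheckpoints()].
#' @param path Checkpoint directory.
#' @export
writeCheckpoint <- function(checkpoint, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({
    saveRDS(checkpoint$model, file.path(path, "weights.rds"))
    yaml::write_yaml(checkpoint$model@config, file.path(path, "config.yaml"))
    writeLines(as.character(c(checkpoint$seed, checkpoint$epoch)),
               file.path(path, "seed.txt"))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    stop(sprintf("checkpoint write failed at epoch %d", checkpoint$epoch),
         call. = FALSE)
  }
  invisible(path)
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(path) {
  meta <- as.integer(readLines(file.path(path, "seed.txt")))
  list(model = readRDS(file.path(path, "weights.rds")),
       epoch = meta[2], history = NULL, seed = meta[1])
}

#' Finetuning strategy: freeze and re-initialization masks
#'
#' The four standard transfer scenarios, expressed as masks over the layer
#' manifest.  "Top" layers are the concatenated stack plus the output
#' layer (the task-specific representation); "bottom" layers are the
#' channel featurizers and separated stacks.
#' \describe{
#'   \item{1}{finetune the full network (large, similar test task).}
#'   \item{2}{re-initialize the top layers, finetune everything (large,
#'     dissimilar task).}
#'   \item{3}{freeze the bottom, finetune the top as-is (small, similar
#'     task).}
#'   \item{4}{freeze the bottom, re-initialize and train the top (small,
#'     dissimilar task -- the pretrain/finetune setting studied here).}
#' }
#'
#' @param model A [PinnModel-class] (to resolve layer names).
#' @param scenario Integer 1-4.
#' @return A `FinetuneStrategy` list with logical `freezeMask` and
#'   `reinitMask` over the layer manifest.
#' @export
finetuneStrategy <- function(model, scenario = 4L) {
  stopifnot(is(model, "PinnModel"), scenario %in% 1:4)
  n <- length(model@layers)
  topIdx <- model@top
  bottom <- setdiff(seq_len(n), topIdx)
  freeze <- reinit <- logical(n)
  if (scenario == 2L) reinit[topIdx] <- TRUE
  if (scenario == 3L) freeze[bottom] <- TRUE
  if (scenario == 4L) { freeze[bottom] <- TRUE; reinit[topIdx] <- TRUE }
  names(freeze) <- names(reinit) <-
    vapply(model@layers, function(l) l$name, character(1))
  structure(list(scenario = scenario, freezeMask = freeze,
                 reinitMask = reinit), class = "FinetuneStrategy")
}

# apply a strategy: set frozen flags; redraw re-initialized layers
.applyStrategy <- function(model, strategy, seed) {
  n <- length(model@layers)
  if (length(strategy$freezeMask) != n || length(strategy$reinitMask) != n) {
    stop("strategy masks do not match the model's layer manifest",
         call. = FALSE)
  }
  .withSeed(seed, {
    for (li in seq_len(n)) {
      layer <- model@layers[[li]]
      if (strategy$reinitMask[li] && length(layer$params)) {
        fresh <- switch(layer$type,
          dense = .denseLayer(layer$name, layer$inDim, layer$outDim,
                              layer$activation, layer$alpha),
          embedding = .embeddingLayer(layer$name, layer$vocabSize, layer$dim),
          conv1d = .convLayer(layer$name, layer$inDim, layer$nFilters,
                              layer$kernel, layer$dilation, layer$alpha),
          lstm = .lstmLayer(layer$name, layer$vocabSize, layer$units,
                            layer$reverse),
          stop("cannot re-initialize layer type ", layer$type))
        model@layers[[li]]$params <- fresh$params
      }
      if (length(layer$params)) {
        model@layers[[li]]$frozen <- unname(strategy$freezeMask[li])
      }
    }
    model
  })
}

#' Finetune a pretrained checkpoint on a target task
#'
#' Applies the strategy's freeze/re-initialization masks (re-drawn layers
#' use Lecun-uniform initialization from `config$seed`), then trains on
#' the target task with a fresh optimizer and early stopping on target
#' validation MCC.  Frozen layers receive no updates.  Test-set MCC and
#' PRC are recorded every epoch when a test split is present.
#'
#' @param checkpoint A checkpoint from [pretrainWithCheckpoints()] (or a
#'   bare [PinnModel-class]).
#' @param data Target-task tensors as in [trainPinn()].
#' @param strategy A [finetuneStrategy()]; default scenario 4.
#' @param config A [trainConfig()] (epoch budget 200 with early stopping
#'   is the reference protocol).
#' @param classWeights As in [trainPinn()].
#' @return As [trainPinn()]: list with `model`, `history`, `optimizer`,
#'   `bestEpoch`.
#' @export
finetune <- function(checkpoint, data, strategy = NULL,
                     config = trainConfig(maxEpochs = 200L),
                     classWeights = "balanced") {
  model <- if (is(checkpoint, "PinnModel")) checkpoint else checkpoint$model
  if (is.null(strategy)) strategy <- finetuneStrategy(model, 4L)
  model <- .applyStrategy(model, strategy,
                          .childSeed(config$seed, "reinit"))
  trainPinn(model, data, config, classWeights, evalTest = TRUE)
}

#' Compare finetuning runs across pretraining checkpoints
#'
#' For each checkpoint: initial performance (epoch-1 test metric), epochs
#' to 95% of the run's best, and the highest test metric, averaged over
#' replicates; plus paired t tests of the best metric against `pm_0`
#' (pairing by replicate; degenerate no-difference comparisons report
#' p = 1).
#'
#' @param runs Named list (`pm_0`, `pm_5`, ...).  Each element is either a
#'   single finetune history data frame or a list of them (replicates).
#' @param metric History column to compare (default `"testMcc"`).
#' @param fraction Convergence threshold (default 0.95).
#' @return List of class `TransferReport`: `summary` data frame and
#'   `pValues` (paired t vs `pm_0`).
#' @export
comparePretraining <- function(runs, metric = "testMcc", fraction = 0.95) {
  if (length(runs) < 2L) stop("need at least two checkpoints", call. = FALSE)
  norm <- lapply(runs, function(r) if (is.data.frame(r)) list(r) else r)
  nRep <- unique(lengths(norm))
  if (length(nRep) != 1L) {
    stop("all checkpoints need the same number of replicate runs",
         call. = FALSE)
  }
  stat <- function(h, f) f(.historyMetric(h, metric))
  initials <- lapply(norm, vapply, function(h) initialPerformance(h, metric),
                     numeric(1))
  bests <- lapply(norm, vapply, function(h) max(.historyMetric(h, metric)),
                  numeric(1))
  conv <- lapply(norm, vapply, function(h)
    as.numeric(convergenceEpoch(h, fraction, metric)), numeric(1))
  summary <- data.frame(
    pm = names(runs),
    initial = vapply(initials, mean, numeric(1)),
    epochsToFraction = vapply(conv, mean, numeric(1)),
    best = vapply(bests, mean, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  ref <- bests[["pm_0"]]
  pv <- vapply(names(runs), function(nm) {
    if (nm == "pm_0" || is.null(ref)) return(NA_real_)
    .safeTest(function() stats::t.test(bests[[nm]], ref, paired = TRUE)$p.value)
  }, numeric(1))
  structure(list(summary = summary, pValues = pv, fraction = fraction,
                 metric = metric),
            class = "TransferReport")
}

#' @export
print.TransferReport <- function(x, ...) {
  cat(sprintf("Transfer comparison on %s (convergence at %.0f%% of best):\n",
              x$metric, 100 * x$fraction))
  print(cbind(x$summary, pVsPm0 = signif(x$pValues, 3)), row.names = FALSE)
  invisible(x)
}
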