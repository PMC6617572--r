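#' Confusion counts at a score threshold
#'
#' @param scores Numeric scores (higher = more positive), or omit `labels`
#'   and pass a list with elements TP/FP/TN/FN.
#' @param labels 0/1 vector.
#' @param threshold Hard-label cut (default 0.5; scores `>= threshold` are
#'   called positive).
#' @return A list of class `ConfusionCounts` with elements TP, FP, TN, FN.
#' @export
confusionCounts <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  out <- list(TP = sum(pred == 1 & labels == 1),
              FP = sum(pred == 1 & labels == 0),
              TN = sum(pred == 0 & labels == 0),
              FN = sum(pred == 0 & labels == 1))
  structure(out, class = "ConfusionCounts")
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in `[-1, 1]`
#' (+1 perfect, 0 random, -1 totally wrong).  When any factor of the
#' denominator is zero the coefficient is defined as 0.
#'
#' @param counts A `ConfusionCounts` list (or any list with TP/FP/TN/FN).
#' @return Numeric scalar.
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Area under the ROC curve
#'
#' Computed via the rank (Mann-Whitney) formulation with average ranks for
#' ties: the probability that a random positive outscores a random
#' negative, counting ties as one half.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 vector; both classes must be present.
#' @return Numeric scalar in `[0, 1]`.
#' @export
rocAuc <- function(scores, labels) {
  n1 <- as.numeric(sum(labels == 1)); n0 <- as.numeric(sum(labels == 0))
  if (n1 == 0 || n0 == 0) {
    stop("both classes required for ROC AUC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' The step-wise rule without linear interpolation: thresholds descend over
#' distinct score values; each threshold group contributes
#' `(recall gain) * precision` at that operating point.  Identical scores
#' form a single operating point, so a constant scorer yields the
#' prevalence.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 vector with at least one positive.
#' @return Numeric scalar in `(0, 1]`.
#' @export
prcAuc <- function(scores, labels) {
  nPos <- sum(labels == 1)
  if (nPos == 0L) stop("at least one positive label required", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  groupEnd <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[groupEnd]
  n <- groupEnd
  precision <- tp / n
  recall <- tp / nPos
  sum(diff(c(0, recall)) * precision)
}

#' Bundle the three classification metrics
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels 0/1 vector.
#' @param threshold Hard-label threshold for the MCC (default 0.5).
#' @return List of class `MetricsReport`: `mcc`, `rocAuc`, `prcAuc`,
#'   `threshold`.
#' @export
metricsReport <- function(scores, labels, threshold = 0.5) {
  structure(list(mcc = mcc(confusionCounts(scores, labels, threshold)),
                 rocAuc = rocAuc(scores, labels),
                 prcAuc = prcAuc(scores, labels),
                 threshold = threshold),
            class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("MCC %.4f | ROC AUC %.4f | PRC AUC %.4f (threshold %.2f)\n",
              x$mcc, x$rocAuc, x$prcAuc, x$threshold))
  invisible(x)
}

#' Rank models by z-scores across replicates and metrics
#'
#' Standardizes metric values across models within every
#' (replicate, metric) slice (population standard deviation, so each slice
#' has mean 0 and unit variance), averages the z-scores per model over
#' metrics and replicates, and reports the SEM over replicates.  For every
#' model pair, a paired Student's t test (pairing by replicate on the
#' metric-averaged z-scores) and a variance-ratio F test are computed;
#' degenerate no-difference comparisons report p = 1.
#'
#' @param metricValues 3-d array `models x replicates x metrics` with
#'   dimnames on the first margin (model names).
#' @param pooled Standardize over all replicates of a metric at once
#'   instead of per (replicate, metric) slice.
#' @return List of class `ComparisonReport`: `summary` data frame (model,
#'   meanZ, sem, per-metric means), `tTest` and `fTest` p-value matrices,
#'   `z` (the z-score array).
#' @export
zscoreRanking <- function(metricValues, pooled = FALSE) {
  d <- dim(metricValues)
  if (length(d) != 3L || d[1] < 2L || d[2] < 2L) {
    stop("need a models x replicates x metrics array with >= 2 models and >= 2 replicates",
         call. = FALSE)
  }
  nM <- d[1]; nR <- d[2]; nK <- d[3]
  models <- dimnames(metricValues)[[1]]
  if (is.null(models)) models <- sprintf("model%d", seq_len(nM))
  z <- metricValues
  for (k in seq_len(nK)) {
    if (pooled) {
      v <- metricValues[, , k]
      mu <- mean(v); sdev <- sqrt(mean((v - mu)^2))
      if (sdev == 0) stop("zero variance across models", call. = FALSE)
      z[, , k] <- (v - mu) / sdev
    } else {
      for (r in seq_len(nR)) {
        v <- metricValues[, r, k]
        mu <- mean(v); sdev <- sqrt(mean((v - mu)^2))
        if (sdev == 0) {
          stop(sprintf("zero variance across models in replicate %d, metric %d",
                       r, k), call. = FALSE)
        }
        z[, r, k] <- (v - mu) / sdev
      }
    }
  }
  perRep <- apply(z, c(1, 2), mean)          # model x replicate, metric-avg
  meanZ <- rowMeans(perRep)
  sem <- apply(perRep, 1, .sem)
  perMetric <- apply(z, c(1, 3), mean)
  colnames(perMetric) <- dimnames(metricValues)[[3]] %||%
    sprintf("metric%d", seq_len(nK))
  tT <- fT <- matrix(NA_real_, nM, nM, dimnames = list(models, models))
  for (a in seq_len(nM - 1L)) for (b in (a + 1L):nM) {
    xa <- perRep[a, ]; xb <- perRep[b, ]
    tT[a, b] <- tT[b, a] <- .safeTest(function()
      stats::t.test(xa, xb, paired = TRUE)$p.value)
    fT[a, b] <- fT[b, a] <- .safeTest(function()
      stats::var.test(xa, xb)$p.value)
  }
  summary <- data.frame(model = models, meanZ = meanZ, sem = sem,
                        perMetric, row.names = NULL,
                        check.names = FALSE, stringsAsFactors = FALSE)
  summary <- summary[order(-summary$meanZ), ]
  structure(list(summary = summary, tTest = tT, fTest = fT, z = z),
            class = "ComparisonReport")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# degenerate comparisons (constant or identical data) report p = 1
.safeTest <- function(f) {
  p <- tryCatch(f(), error = function(e) 1)
  if (!is.finite(p)) 1 else p
}

#' @export
print.ComparisonReport <- function(x, ...) {
  cat("Model ranking by mean z-score:\n")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write a comparison report as delimited text
#'
#' One row per model: mean z, SEM and per-metric mean z-scores.
#'
#' @param report A `ComparisonReport`.
#' @param path Output TSV path.
#' @export
writeComparisonReport <- function(report, path) {
  write.table(report$summary, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# metric column lookup shared by the history readouts
.historyMetric <- function(history, metric) {
  if (is.numeric(history)) return(as.numeric(history))
  if (!metric %in% names(history)) {
    stop(sprintf("history has no column '%s'", metric), call. = FALSE)
  }
  history[[metric]][order(history$epoch)]
}

#' Initial performance of a training run
#'
#' The validation metric at the first epoch.
#'
#' @param history A training-history data frame (from [trainPinn()]) or a
#'   plain numeric metric series ordered by epoch.
#' @param metric History column to read (default `"valMcc"`).
#' @return Numeric scalar.
#' @export
initialPerformance <- function(history, metric = "valMcc") {
  v <- .historyMetric(history, metric)
  if (length(v) == 0L) stop("empty history", call. = FALSE)
  v[1]
}

#' Epochs to reach a fraction of the best performance
#'
#' The smallest epoch whose metric reaches `fraction * max(metric)`; the
#' convergence-speed readout (98% is the usual threshold, 95% for
#' finetuning comparisons).
#'
#' @inheritParams initialPerformance
#' @param fraction Fraction of the run's maximum, in (0, 1].
#' @return Integer epoch index (1-based).
#' @export
convergenceEpoch <- function(history, fraction = 0.98, metric = "valMcc") {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]", call. = FALSE)
  v <- .historyMetric(history, metric)
  if (length(v) == 0L) stop("empty history", call. = FALSE)
  which(v >= fraction * max(v))[1]
}
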