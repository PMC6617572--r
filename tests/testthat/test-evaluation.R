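test_that("MCC matches the closed form and its conventions", {
  expect_equal(mcc(list(TP = 5, TN = 5, FP = 0, FN = 0)), 1)
  expect_equal(mcc(list(TP = 0, TN = 0, FP = 5, FN = 5)), -1)
  expect_equal(mcc(list(TP = 3, TN = 4, FP = 1, FN = 2)), 10 / sqrt(600))
  expect_equal(mcc(list(TP = 3, TN = 4, FP = 1, FN = 2)), 0.40825,
               tolerance = 1e-4)
  # zero-denominator convention
  expect_equal(mcc(list(TP = 0, TN = 5, FP = 0, FN = 0)), 0)
  # symmetry under simultaneous label/prediction flip
  set.seed(1)
  for (i in 1:50) {
    cts <- as.list(rpois(4, 5)); names(cts) <- c("TP", "FP", "TN", "FN")
    flip <- list(TP = cts$TN, FP = cts$FN, TN = cts$TP, FN = cts$FP)
    expect_equal(mcc(cts), mcc(flip))
  }
})

test_that("confusion counts threshold scores at 0.5 by default", {
  cc <- confusionCounts(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))
  expect_equal(unclass(cc)[c("TP", "FP", "TN", "FN")],
               list(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
})

test_that("ROC AUC equals pairwise concordance, including ties", {
  expect_equal(rocAuc(1:6, c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(rocAuc(6:1, c(0, 0, 0, 1, 1, 1)), 0)
  expect_equal(rocAuc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_error(rocAuc(1:3, c(1, 1, 1)), "both classes")

  bruteForce <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    gr <- outer(pos, neg, ">"); eq <- outer(pos, neg, "==")
    (sum(gr) + 0.5 * sum(eq)) / (length(pos) * length(neg))
  }
  set.seed(12)
  for (i in 1:1000) {
    n <- sample(2:12, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # heavy ties
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))[sample(n)]
    expect_equal(rocAuc(s, y), bruteForce(s, y), tolerance = 1e-12)
  }
})

test_that("PRC AUC follows the step rule without interpolation", {
  expect_equal(prcAuc(c(0.9, 0.7, 0.5), c(1, 1, 1)), 1)
  # constant scorer: one operating point at the prevalence
  expect_equal(prcAuc(rep(0.5, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  expect_equal(prcAuc(c(0.9, 0.8, 0.4), c(1, 0, 1)),
               0.5 * 1 + 0.5 * (2 / 3))
  expect_equal(prcAuc(c(0.9, 0.8, 0.4), c(1, 0, 1)), 0.8333, tolerance = 1e-4)
  expect_error(prcAuc(c(0.2, 0.4), c(0, 0)), "positive")
  # step-rule oracle on small fuzzed cases
  stepOracle <- function(s, y) {
    ord <- order(-s); s <- s[ord]; y <- y[ord]
    ap <- 0; lastR <- 0
    for (th in unique(s)) {
      keep <- s >= th
      p <- sum(y[keep]) / sum(keep)
      r <- sum(y[keep]) / sum(y)
      ap <- ap + (r - lastR) * p
      lastR <- r
    }
    ap
  }
  set.seed(21)
  for (i in 1:300) {
    n <- sample(2:10, 1)
    s <- sample(seq(0, 1, 0.2), n, replace = TRUE)
    y <- c(1, rbinom(n - 1, 1, 0.4))[sample(n)]
    expect_equal(prcAuc(s, y), stepOracle(s, y), tolerance = 1e-12)
  }
})

test_that("a random scorer has chance-level ROC and prevalence-level PRC", {
  set.seed(33)
  n <- 20000
  y <- rbinom(n, 1, 0.1)
  s <- runif(n)
  se <- sqrt(0.0833 / min(sum(y), n - sum(y)))  # conservative AUC SE bound
  expect_lt(abs(rocAuc(s, y) - 0.5), 3 * se)
  expect_lt(abs(prcAuc(s, y) - mean(y)), 0.02)  # imbalance sensitivity
})

test_that("z-score ranking standardizes slices and runs the paired tests", {
  # two models, one slice pair {0.6, 0.8} -> z = -1, +1 (population sd)
  arr <- array(c(0.6, 0.8, 0.7, 0.9), dim = c(2, 2, 1),
               dimnames = list(c("m1", "m2"), NULL, "mcc"))
  rep1 <- zscoreRanking(arr)
  expect_equal(unname(rep1$z[, 1, 1]), c(-1, 1))
  expect_equal(rep1$summary$meanZ[rep1$summary$model == "m2"], 1)

  # conservation: mean of all reported z-scores is 0
  set.seed(2)
  big <- array(runif(15 * 4 * 2), dim = c(15, 4, 2),
               dimnames = list(sprintf("mod%02d", 1:15), NULL,
                               c("mcc", "roc")))
  repBig <- zscoreRanking(big)
  expect_lt(abs(mean(repBig$summary$meanZ)), 1e-9)
  # each slice has mean 0 and unit (population) variance
  for (r in 1:4) for (k in 1:2) {
    zi <- repBig$z[, r, k]
    expect_lt(abs(mean(zi)), 1e-9)
    expect_equal(mean(zi^2), 1, tolerance = 1e-9)
  }

  # two identical models among three: their pairwise tests report p = 1
  tri <- array(c(0.5, 0.5, 0.9, 0.52, 0.52, 0.8), dim = c(3, 2, 1),
               dimnames = list(c("a", "b", "c"), NULL, "mcc"))
  repTri <- zscoreRanking(tri)
  expect_equal(repTri$z["a", , 1], repTri$z["b", , 1])
  expect_equal(repTri$tTest["a", "b"], 1)
  expect_equal(repTri$fTest["a", "b"], 1)
  # non-degenerate comparisons produce proper p-values
  off <- repBig$tTest[upper.tri(repBig$tTest)]
  expect_true(all(off >= 0 & off <= 1))
  expect_true(any(off < 1))

  # degenerate slice: all models equal -> error
  flat <- array(0.5, dim = c(2, 2, 1))
  expect_error(zscoreRanking(flat), "zero variance")
  expect_error(zscoreRanking(array(1, dim = c(1, 2, 1))), ">= 2 models")
})

test_that("comparison reports serialize as one row per model", {
  arr <- array(runif(12), dim = c(3, 2, 2),
               dimnames = list(c("x", "y", "z"), NULL, c("mcc", "roc")))
  f <- tempfile(fileext = ".tsv")
  writeComparisonReport(zscoreRanking(arr), f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 3L)
  expect_true(all(c("model", "meanZ", "sem", "mcc", "roc") %in% names(tab)))
})

test_that("initial performance and convergence epochs read the history", {
  h <- data.frame(epoch = 1:2, valMcc = c(0.40, 0.55))
  expect_equal(initialPerformance(h), 0.40)
  expect_equal(initialPerformance(0.73), 0.73)
  expect_equal(initialPerformance(c(0.47, 0.52, 0.50)), 0.47)

  expect_equal(convergenceEpoch(c(0.2, 0.4, 0.6, 0.8, 1.0), 0.98), 5L)
  expect_equal(convergenceEpoch(c(0.5, 0.97, 0.96, 1.0), 0.95), 2L)
  # fraction 1: first attainment of the maximum
  expect_equal(convergenceEpoch(c(0.1, 0.9, 0.9, 0.2), 1), 2L)
  expect_error(convergenceEpoch(c(0.1), 1.2), "fraction")
  expect_error(initialPerformance(numeric(0)), "empty history")
})
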