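test_that("normalizer standardizes on the training split with population sd", {
  X <- cbind(a = c(0, 2, 5, 9), b = rep(3, 4))
  nz <- fitNormalizer(X, trainIdx = 1:2)
  # two-point column {0, 2}: mean 1, population sd 1 -> {-1, +1}
  Xt <- normalizeFeatures(nz, X)
  expect_equal(Xt[1:2, "a"], c(-1, 1), ignore_attr = TRUE)
  # constant feature maps to identically zero
  expect_true(all(Xt[, "b"] == 0))
  expect_error(fitNormalizer(X, integer(0)), "empty split")

  set.seed(8)
  Y <- matrix(rnorm(300), 60)
  nz2 <- fitNormalizer(Y, 1:40)
  Yt <- normalizeFeatures(nz2, Y)[1:40, ]
  expect_true(all(abs(colMeans(Yt)) < 1e-9))
  expect_true(all(abs(colMeans(Yt^2) - 1) < 1e-9))
  # affine and invertible on non-degenerate features
  expect_equal(denormalizeFeatures(nz2, normalizeFeatures(nz2, Y)), Y,
               tolerance = 1e-12)
})

test_that("class weights follow the balanced heuristic", {
  expect_equal(computeClassWeights(rep(c(0, 1), 50))[["wPos"]], 1)
  w <- computeClassWeights(c(rep(1, 5957), rep(0, 73628)))
  expect_equal(w[["wPos"]], 73628 / 5957)
  expect_equal(w[["wPos"]], 12.360, tolerance = 1e-3)
  w2 <- computeClassWeights(c(rep(1, 547), rep(0, 453)))
  expect_equal(w2[["wPos"]], 453 / 547)
  expect_equal(w2[["wPos"]], 0.828, tolerance = 1e-3)
  expect_error(computeClassWeights(rep(1, 10)), "both classes")
})

test_that("weighted cross-entropy reduces to unweighted under unit weights", {
  ns <- asNamespace("pinnCPI")
  set.seed(5)
  logits <- rnorm(50); y <- rbinom(50, 1, 0.5)
  lw <- ns$.weightedBce(logits, y, 1, 1)
  p <- plogis(logits)
  expect_equal(lw$loss, -mean(y * log(p + 1e-12) + (1 - y) * log(1 - p + 1e-12)))
  l2 <- ns$.weightedBce(logits, y, 3, 1)
  expect_gt(l2$loss, 0)
})

test_that("an optimizer step with zero gradients leaves parameters unchanged", {
  prob <- makeDenseProblem()
  m <- prob$model
  ns <- asNamespace("pinnCPI")
  opt <- ns$.adamInit(m)
  zero <- lapply(m@layers, function(l) lapply(l$params, function(p) p * 0))
  st <- ns$.adamStep(m, zero, opt, trainConfig())
  expect_paramsEqual(st$model, m)
})

test_that("training fits a separable task to near-perfect MCC, like the logistic oracle", {
  ds <- makeDenseFixture(nPairs = 2000L, seed = 2, separable = TRUE)
  prob <- makeDenseProblem(ds, sep = c(12L, 6L), concat = 8L)
  fit <- trainPinn(prob$model, prob$asm,
                   trainConfig(learningRate = 5e-3, batchSize = 64L,
                               maxEpochs = 50L, patience = 50L, seed = 4))
  trainScores <- pinnPredict(fit$model,
                             lapply(prob$asm$inputs, function(x)
                               x[prob$asm$trainIdx, , drop = FALSE]))
  trainMcc <- mcc(confusionCounts(trainScores,
                                  prob$asm$labels[prob$asm$trainIdx]))
  expect_gt(trainMcc, 0.95)
  expect_gt(glmOracleMcc(prob$asm), 0.95)  # oracle agrees the task is separable
  # history bookkeeping: one row per epoch, strictly increasing epochs
  expect_true(all(diff(fit$history$epoch) == 1))
})

test_that("shuffled labels yield no validation signal", {
  set.seed(9)
  mccs <- vapply(1:3, function(s) {
    ds <- makeDenseFixture(nPairs = 700L, seed = s, separable = FALSE)
    prob <- makeDenseProblem(ds, seed = s + 10)
    fit <- trainPinn(prob$model, prob$asm,
                     trainConfig(batchSize = 64L, maxEpochs = 5L,
                                 patience = 5L, seed = s))
    fit$history$valMcc[5]
  }, numeric(1))
  expect_true(all(abs(mccs) < 0.25))
  expect_lt(abs(mean(mccs)), 0.15)
})

test_that("early stopping halts after the patience window", {
  ds <- makeDenseFixture(nPairs = 500L, seed = 3)
  prob <- makeDenseProblem(ds)
  fit <- trainPinn(prob$model, prob$asm,
                   trainConfig(batchSize = 64L, maxEpochs = 60L,
                               patience = 3L, seed = 2))
  expect_lte(nrow(fit$history), fit$bestEpoch + 3L)
  expect_lt(nrow(fit$history), 60L)
})

test_that("training reports non-finite losses with the failing epoch", {
  ds <- makeDenseFixture(nPairs = 300L, seed = 6)
  prob <- makeDenseProblem(ds)
  broken <- prob$model
  broken@layers[[2]]$params$W[1] <- NaN  # poisoned weight propagates
  expect_error(
    trainPinn(broken, prob$asm,
              trainConfig(batchSize = 32L, maxEpochs = 5L, seed = 1)),
    "non-finite loss.*epoch 1")
})

test_that("cross-validation builds disjoint stratified folds, reproducibly", {
  ds <- makeDenseFixture(nPairs = 1000L, seed = 5)
  prob <- makeDenseProblem(ds, sep = c(6L, 3L), concat = 4L)
  cfg <- trainConfig(batchSize = 128L, maxEpochs = 2L, patience = 2L, seed = 7)
  cv <- crossValidate(function() prob$model, prob$asm, cfg, k = 5)
  expect_length(cv$metrics, 5L)
  # folds partition the validation portion evenly
  expect_equal(sort(unique(cv$foldAssignment)), 1:5)
  expect_true(max(table(cv$foldAssignment)) -
                min(table(cv$foldAssignment)) <= 2)
  cv2 <- crossValidate(function() prob$model, prob$asm, cfg, k = 5)
  expect_identical(cv$foldAssignment, cv2$foldAssignment)
  expect_equal(cv$mean, mean(cv$metrics))
  expect_equal(cv$sem, sd(cv$metrics) / sqrt(5))
})
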