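test_that("elu is identity for non-negatives and alpha*(exp(x)-1) below zero", {
  expect_equal(elu(0, 1), 0)
  expect_equal(elu(1.5, 1), 1.5)
  expect_equal(elu(-1, 1), exp(-1) - 1, tolerance = 1e-9)
  expect_equal(elu(-1, 1), -0.63212, tolerance = 1e-4)
  expect_equal(elu(-2, 0.5), 0.5 * (exp(-2) - 1))
  expect_error(elu(1, alpha = -1), "positive")
})

test_that("Lecun uniform draws respect the fan-in bound and seed", {
  w <- lecunUniform(3, c(100, 10), seed = 1)
  expect_true(all(abs(w) <= 1))           # sqrt(3/3) = 1
  big <- lecunUniform(300, 1e5, seed = 2)
  expect_true(all(abs(big) <= 0.1))       # sqrt(3/300) = 0.1
  expect_lt(abs(mean(big)), 0.002)
  expect_identical(lecunUniform(5, c(4, 4), seed = 9),
                   lecunUniform(5, c(4, 4), seed = 9))
  expect_error(lecunUniform(0, 3), "positive")
})

test_that("channel configs validate geometry and receptive fields", {
  expect_error(channelConfig("dense"), "inputDim")
  cc <- channelConfig("dilated_cnn", fixedLength = 100, vocabSize = 57,
                      dilationRates = c(1, 2, 4))
  expect_equal(1 + 11 * 7, 78)  # receptive-field arithmetic for kernel 12
  expect_error(channelConfig("dilated_cnn", fixedLength = 100, vocabSize = 57,
                             dilationRates = c(1, 2, 4, 8)),
               "receptive field 166")
  expect_error(pinnConfig(list(), list(cc)), "at least one channel")
})

test_that("toy PINN parameter count matches the hand count", {
  pc <- pinnConfig(channelConfig("dense", inputDim = 4),
                   channelConfig("dense", inputDim = 3),
                   separatedWidths = 2L, concatenatedWidths = 2L,
                   dropoutInitial = 0, dropoutHidden = 0)
  m <- buildPinn(pc, seed = 1)
  # (4*2+2) + (3*2+2) + (4*2+2) + (2*1+1)
  expect_identical(countParameters(m), 31L)
  # dense layer m -> k has m*k + k parameters
  man <- layerManifest(m)
  expect_equal(man$n_params[man$name == "compound_ch1_sep1"], 4 * 2 + 2)
})

test_that("a PINN with no separated layers equals the plain feed-forward count", {
  pc <- pinnConfig(channelConfig("dense", inputDim = 7),
                   channelConfig("dense", inputDim = 5),
                   separatedWidths = integer(0),
                   concatenatedWidths = c(6L, 3L))
  m <- buildPinn(pc, seed = 1)
  expect_identical(countParameters(m),
                   as.integer(ffnnParameterCount(12, c(6, 3))))
})

test_that("reference-width PINN halves the parameters of the concatenated baseline", {
  pc <- pinnConfig(channelConfig("dense", inputDim = 1024),  # fingerprint
                   channelConfig("dense", inputDim = 300),   # protein embed
                   separatedWidths = c(1024L, 256L),
                   concatenatedWidths = 256L)
  m <- buildPinn(pc, seed = 1)
  baseline <- ffnnParameterCount(1324, c(2048, 512, 256))
  ratio <- countParameters(m) / baseline
  expect_gte(ratio, 0.45)
  expect_lte(ratio, 0.55)
})

test_that("channel contribution to the merge equals its last separated width", {
  cfg <- pinnConfig(list(channelConfig("dense", inputDim = 500),
                         channelConfig("dense", inputDim = 3)),
                    channelConfig("dense", inputDim = 40),
                    separatedWidths = c(16L, 6L), concatenatedWidths = 4L)
  m <- buildPinn(cfg, seed = 2)
  expect_true(all(vapply(m@channels, function(ch) ch$outDim, integer(1)) == 6L))
  # the first concatenated layer sees 3 channels x 6 units
  concat1 <- m@layers[[m@top[1]]]
  expect_equal(nrow(concat1$params$W), 18L)
})

test_that("forward pass yields probabilities and is deterministic without dropout", {
  prob <- makeDenseProblem()
  m <- prob$model; asm <- prob$asm
  idx <- asm$valIdx[1:20]
  inputs <- lapply(asm$inputs, function(x) x[idx, , drop = FALSE])
  p1 <- pinnPredict(m, inputs)
  p2 <- pinnPredict(m, inputs)
  expect_length(p1, 20L)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, p2)
})

test_that("backpropagation matches numerical gradients for every layer kind", {
  set.seed(42)
  cfgC <- channelConfig("dilated_cnn", fixedLength = 12, vocabSize = 5,
                        nFilters = 3, kernelSize = 3, tokenEmbeddingDim = 2,
                        dilationRates = c(1, 2))
  cfgP <- channelConfig("blstm", fixedLength = 6, vocabSize = 4, units = 3)
  pc <- pinnConfig(list(cfgC), list(cfgP), separatedWidths = 4L,
                   concatenatedWidths = 3L, dropoutInitial = 0,
                   dropoutHidden = 0)
  m <- buildPinn(pc, seed = 7)
  B <- 4
  inputs <- list(matrix(sample(0:5, B * 12, TRUE), B, 12),
                 matrix(sample(0:4, B * 6, TRUE), B, 6))
  y <- rbinom(B, 1, 0.5)
  ns <- asNamespace("pinnCPI")
  fw <- ns$.pinnForward(m, inputs, training = FALSE)
  lb <- ns$.weightedBce(fw$logits, y, 1.3, 1.0)
  grads <- ns$.pinnBackward(m, fw, lb$dlogits)
  lossOf <- function(model) {
    f <- ns$.pinnForward(model, inputs, training = FALSE)
    ns$.weightedBce(f$logits, y, 1.3, 1.0)$loss
  }
  eps <- 1e-6
  for (li in seq_along(m@layers)) {
    lay <- m@layers[[li]]
    if (!length(lay$params)) next
    for (pn in names(lay$params)) {
      P <- lay$params[[pn]]
      for (ix in sample(length(P), min(4, length(P)))) {
        mp <- m; mp@layers[[li]]$params[[pn]][ix] <- P[ix] + eps
        mm <- m; mm@layers[[li]]$params[[pn]][ix] <- P[ix] - eps
        num <- (lossOf(mp) - lossOf(mm)) / (2 * eps)
        expect_equal(grads[[li]][[pn]][ix], num, tolerance = 1e-4,
                     label = sprintf("d%s/%s[%d]", lay$name, pn, ix))
      }
    }
  }
})

test_that("lstm channels consume tokens and emit final-state vectors", {
  cfg <- channelConfig("lstm", fixedLength = 5, vocabSize = 6, units = 4)
  pc <- pinnConfig(channelConfig("dense", inputDim = 3), list(cfg),
                   separatedWidths = integer(0), concatenatedWidths = 4L,
                   dropoutInitial = 0, dropoutHidden = 0)
  m <- buildPinn(pc, seed = 2)
  p <- pinnPredict(m, list(matrix(rnorm(6), 2, 3),
                           matrix(sample(0:6, 10, TRUE), 2, 5)))
  expect_length(p, 2L)
  # forget-gate bias initialized to one
  lstm <- m@layers[[which(layerManifest(m)$type == "lstm")[1]]]
  H <- lstm$units
  expect_true(all(lstm$params$b[1, (H + 1):(2 * H)] == 1))
  expect_true(all(lstm$params$b[1, 1:H] == 0))
})
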