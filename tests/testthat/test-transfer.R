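# Small shared setup: a dense-feature source/target problem pair.
transferProblem <- function(seed = 1L) {
  ds <- makeDenseFixture(nPairs = 500L, seed = seed)
  makeDenseProblem(ds, sep = c(6L, 4L), concat = 4L, seed = seed + 1)
}

test_that("the checkpoint schedule enumerates multiples of the interval", {
  s <- pretrainSchedule(20, 5)
  expect_equal(s$epochs, c(0L, 5L, 10L, 15L, 20L))
  expect_equal(pretrainSchedule()$epochs, seq(0L, 140L, 5L))
  expect_error(pretrainSchedule(0, 5), "positive")
})

test_that("pretraining snapshots PM_0 before any update and checkpoints in order", {
  prob <- transferProblem(2)
  tc <- trainConfig(batchSize = 64L, seed = 5)
  cps <- pretrainWithCheckpoints(prob$model, prob$asm,
                                 pretrainSchedule(6L, 2L), tc)
  expect_equal(names(cps), c("pm_0", "pm_2", "pm_4", "pm_6"))
  # PM_0 equals the freshly initialized model
  expect_paramsEqual(cps$pm_0$model, prob$model)
  # cumulative histories grow with the checkpoint epoch
  expect_null(cps$pm_0$history)
  expect_equal(nrow(cps$pm_6$history), 6L)
  # later checkpoints differ from the initialization
  expect_false(identical(cps$pm_6$model@layers, prob$model@layers))
})

test_that("checkpoint write/restore round-trips bit-identically", {
  prob <- transferProblem(3)
  tc <- trainConfig(batchSize = 64L, seed = 6)
  cps <- pretrainWithCheckpoints(prob$model, prob$asm,
                                 pretrainSchedule(2L, 2L), tc)
  dir <- file.path(tempdir(), "cps")
  writeCheckpoint(cps$pm_2, file.path(dir, "pm_2"))
  back <- readCheckpoint(file.path(dir, "pm_2"))
  expect_paramsEqual(back$model, cps$pm_2$model)
  idx <- prob$asm$valIdx[1:10]
  inputs <- lapply(prob$asm$inputs, function(x) x[idx, , drop = FALSE])
  expect_identical(pinnPredict(back$model, inputs),
                   pinnPredict(cps$pm_2$model, inputs))
  expect_equal(back$epoch, 2L)
  unlink(dir, recursive = TRUE)
})

test_that("finetuning strategies partition the manifest as specified", {
  prob <- transferProblem(4)
  m <- prob$model
  topNames <- vapply(m@layers[m@top], function(l) l$name, character(1))

  s1 <- finetuneStrategy(m, 1)
  expect_false(any(s1$freezeMask) || any(s1$reinitMask))
  # scenario 1 applied with no training leaves the model identical
  ns <- asNamespace("pinnCPI")
  m1 <- ns$.applyStrategy(m, s1, seed = 99)
  expect_paramsEqual(m1, m)

  s4 <- finetuneStrategy(m, 4)
  expect_true(all(s4$freezeMask[setdiff(names(s4$freezeMask), topNames)]))
  expect_false(any(s4$freezeMask[topNames]))
  expect_true(all(s4$reinitMask[topNames]))
  m4 <- ns$.applyStrategy(m, s4, seed = 99)
  # separated layers untouched, concatenated stack re-drawn
  sepIdx <- which(!s4$freezeMask %in% TRUE)
  outLayer <- m@top[length(m@top)]
  expect_false(identical(m4@layers[[outLayer]]$params$W,
                         m@layers[[outLayer]]$params$W))
  firstSep <- which(vapply(m@layers, function(l)
    grepl("_sep1$", l$name), logical(1)))[1]
  expect_identical(m4@layers[[firstSep]]$params, m@layers[[firstSep]]$params)
})

test_that("frozen layers are bit-identical through finetuning", {
  prob <- transferProblem(5)
  tc <- trainConfig(batchSize = 64L, seed = 7)
  cps <- pretrainWithCheckpoints(prob$model, prob$asm,
                                 pretrainSchedule(4L, 4L), tc)
  tgt <- makeDenseFixture(nPairs = 400L, seed = 50)
  asmT <- assemblePinnData(tgt, "xc", "xp")
  strat <- finetuneStrategy(cps$pm_4$model, 4)
  fit <- finetune(cps$pm_4, asmT, strat,
                  trainConfig(batchSize = 64L, maxEpochs = 6L,
                              patience = 6L, seed = 8))
  frozenIdx <- which(strat$freezeMask &
                       vapply(cps$pm_4$model@layers, function(l)
                         length(l$params) > 0, logical(1)))
  for (li in frozenIdx) {
    expect_identical(fit$model@layers[[li]]$params,
                     cps$pm_4$model@layers[[li]]$params)
  }
  # trainable-parameter accounting reflects the freeze
  man <- layerManifest(fit$model)
  expect_equal(countParameters(fit$model, trainableOnly = TRUE),
               sum(man$n_params[!man$frozen]))
  expect_lt(countParameters(fit$model, trainableOnly = TRUE),
            countParameters(fit$model))
  # per-epoch test metrics are recorded
  expect_true(all(c("testMcc", "testPrc") %in% names(fit$history)))
})

test_that("mismatched strategy masks are rejected", {
  prob <- transferProblem(6)
  strat <- finetuneStrategy(prob$model, 4)
  strat$freezeMask <- strat$freezeMask[-1]
  expect_error(finetune(prob$model, prob$asm, strat,
                        trainConfig(maxEpochs = 1L, seed = 1)),
               "manifest")
})

test_that("pretraining comparisons report initials, convergence, and paired tests", {
  h1 <- data.frame(epoch = 1:5, testMcc = c(0.16, 0.3, 0.35, 0.36, 0.36))
  h2 <- data.frame(epoch = 1:5, testMcc = c(0.11, 0.33, 0.40, 0.42, 0.43))
  # identical histories for all checkpoints: zero deltas, p = 1
  repEq <- comparePretraining(list(pm_0 = list(h1, h1), pm_5 = list(h1, h1)))
  expect_equal(repEq$summary$best[1], repEq$summary$best[2])
  expect_equal(unname(repEq$pValues["pm_5"]), 1)

  rep2 <- comparePretraining(list(pm_0 = h1, pm_55 = h2))
  expect_equal(rep2$summary$initial,
               c(0.16, 0.11))
  expect_equal(rep2$summary$best, c(0.36, 0.43))
  expect_equal(rep2$summary$epochsToFraction[2],
               convergenceEpoch(h2$testMcc, 0.95))
  expect_error(comparePretraining(list(pm_0 = h1)), "at least two")
  expect_error(comparePretraining(list(pm_0 = list(h1, h1),
                                       pm_5 = list(h1))),
               "same number")
})
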