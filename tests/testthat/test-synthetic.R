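smallSpec <- function(seed = 1L, nPairs = 1500L, nCompounds = 120L,
                      nProteins = 40L, ...) {
  syntheticSpec(nCompounds = nCompounds, nProteins = nProteins,
                nPairs = nPairs, seed = seed, ...)
}

test_that("compound generation is deterministic, valid, and length-calibrated", {
  spec <- smallSpec(seed = 5)
  c1 <- generateCompounds(1, spec)
  c2 <- generateCompounds(1, spec)
  expect_identical(c1, c2)

  # every generated SMILES parses
  tab <- generateCompounds(150, spec)
  graphs <- parseSmiles(tab$smiles)
  expect_length(graphs, 150L)
  expect_true(all(vapply(graphs, function(g) length(g$element) > 0,
                         logical(1))))

  # length calibration against the generator's own p75 target
  big <- generateCompounds(10000, syntheticSpec(seed = 2))
  p75 <- unname(quantile(nchar(big$smiles), 0.75))
  expect_gte(p75, 55)
  expect_lte(p75, 71)
})

test_that("protein generation uses the canonical alphabet with calibrated lengths", {
  spec <- smallSpec(seed = 3)
  p1 <- generateProteins(1, spec)
  expect_true(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", p1$sequence))
  expect_identical(p1, generateProteins(1, spec))

  big <- generateProteins(5000, syntheticSpec(seed = 4))
  p75 <- unname(quantile(nchar(big$sequence), 0.75))
  expect_gte(p75, 108)
  expect_lte(p75, 132)
})

test_that("label generation calibrates the positive rate by bisection", {
  # balanced regime at the default pair count
  spec <- syntheticSpec(nCompounds = 400L, nProteins = 80L, nPairs = 20000L,
                        seed = 11)
  ds <- simulateCpiDataset(spec)
  rate <- mean(cpiPairs(ds)$label)
  expect_gte(rate, 0.542)
  expect_lte(rate, 0.552)

  # strongly imbalanced regime
  spec2 <- syntheticSpec(nCompounds = 400L, nProteins = 80L, nPairs = 20000L,
                         positiveRate = 0.0749, seed = 12)
  ds2 <- simulateCpiDataset(spec2)
  rate2 <- mean(cpiPairs(ds2)$label)
  expect_gte(rate2, 0.070)
  expect_lte(rate2, 0.080)
})

test_that("an extreme interaction scale makes labels deterministic in the latent rule", {
  spec <- smallSpec(seed = 7, interactionScale = 1e6)
  ds <- simulateCpiDataset(spec)
  tr <- cpiTruth(ds)
  labels <- cpiPairs(ds)$label
  # the latent logits separate the classes perfectly
  expect_identical(labels, as.integer(tr$logits > 0))
  expect_equal(mcc(confusionCounts(tr$logits, labels, threshold = 0)), 1)
  expect_equal(rocAuc(tr$logits, labels), 1)
})

test_that("datasets are reproducible and structurally sound", {
  spec <- smallSpec(seed = 9)
  d1 <- simulateCpiDataset(spec)
  d2 <- simulateCpiDataset(spec)
  expect_identical(cpiPairs(d1), cpiPairs(d2))
  expect_identical(cpiCompounds(d1), cpiCompounds(d2))
  sp <- cpiSplits(d1)
  all_idx <- sort(unlist(sp, use.names = FALSE))
  expect_equal(all_idx, seq_len(nrow(cpiPairs(d1))))  # disjoint cover
  # stratification: split rates within 3 points of the global rate
  g <- mean(cpiPairs(d1)$label)
  for (s in sp) expect_lt(abs(mean(cpiPairs(d1)$label[s]) - g), 0.03)
})

test_that("task-pair similarity controls the latent-rule correlation", {
  spec <- smallSpec(seed = 21, nPairs = 1500L)
  # similarity 1 with shared entities reproduces the rule exactly
  tp1 <- generateTaskPair(spec, similarity = 1, shareEntities = TRUE)
  expect_equal(cpiTruth(tp1$source)$dotStd, cpiTruth(tp1$target)$dotStd,
               tolerance = 1e-9)

  # similarity 0: unrelated logits
  tp0 <- generateTaskPair(smallSpec(seed = 22, nPairs = 10000L,
                                    nCompounds = 300L, nProteins = 60L),
                          similarity = 0, shareEntities = TRUE)
  r0 <- cor(cpiTruth(tp0$source)$dotStd, cpiTruth(tp0$target)$dotStd)
  expect_lt(abs(r0), 0.05)

  # correlation grows monotonically with similarity
  meds <- vapply(c(0, 0.4, 0.8), function(sim) {
    median(vapply(1:3, function(s) {
      tp <- generateTaskPair(smallSpec(seed = 30 + s), similarity = sim,
                             shareEntities = TRUE)
      cor(cpiTruth(tp$source)$dotStd, cpiTruth(tp$target)$dotStd)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meds) > 0))

  # target regime defaults to the imbalanced positive rate
  expect_lt(mean(cpiPairs(tp1$target)$label), 0.12)
  expect_error(generateTaskPair(spec, similarity = 2), "similarity")
})

test_that("plain-text dataset serialization round-trips", {
  spec <- smallSpec(seed = 13, nPairs = 300L)
  ds <- simulateCpiDataset(spec)
  dir <- file.path(tempdir(), "synth_rt")
  writeCpiDataset(ds, dir)
  expect_true(all(file.exists(file.path(dir,
    c("compounds.tsv", "proteins.fasta", "pairs.tsv", "splits.tsv",
      "truth.tsv")))))
  back <- readCpiDataset(dir)
  expect_equal(cpiPairs(back)$label, cpiPairs(ds)$label)
  expect_equal(cpiCompounds(back)$smiles, cpiCompounds(ds)$smiles)
  expect_equal(cpiProteins(back)$sequence, cpiProteins(ds)$sequence)
  expect_equal(sort(unlist(cpiSplits(back))), sort(unlist(cpiSplits(ds))))
  unlink(dir, recursive = TRUE)
})
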