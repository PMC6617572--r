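# Shared fixtures, built in code.

# A tiny CPIDataset with dense random features carrying a learnable linear
# signal; avoids SMILES parsing so model/training tests stay fast.
makeDenseFixture <- function(nPairs = 600L, dC = 6L, dP = 4L, seed = 1L,
                             separable = TRUE) {
  set.seed(seed)
  nC <- 40L; nP <- 15L
  compounds <- data.frame(compound_id = sprintf("C%02d", 1:nC),
                          smiles = rep("CCO", nC),
                          stringsAsFactors = FALSE)
  proteins <- data.frame(protein_id = sprintf("P%02d", 1:nP),
                         sequence = rep("MKVLAG", nP),
                         stringsAsFactors = FALSE)
  Xc <- matrix(rnorm(nC * dC), nC)
  Xp <- matrix(rnorm(nP * dP), nP)
  cIdx <- sample(nC, nPairs, replace = TRUE)
  pIdx <- sample(nP, nPairs, replace = TRUE)
  score <- Xc[cIdx, 1] + Xp[pIdx, 1]
  labels <- if (separable) as.integer(score > 0) else rbinom(nPairs, 1, 0.5)
  pairs <- data.frame(compound_id = compounds$compound_id[cIdx],
                      protein_id = proteins$protein_id[pIdx],
                      label = labels, stringsAsFactors = FALSE)
  ds <- cpiDataset(compounds, proteins, pairs)
  ds <- setCompoundFeature(ds, "xc", Xc)
  ds <- setProteinFeature(ds, "xp", Xp)
  n <- nPairs
  idx <- sample(n)
  ds@splits <- list(train = sort(idx[1:(0.6 * n)]),
                    validation = sort(idx[(0.6 * n + 1):(0.8 * n)]),
                    test = sort(idx[(0.8 * n + 1):n]))
  ds
}

# assembled tensors + a small PINN for the dense fixture
makeDenseProblem <- function(ds = makeDenseFixture(), sep = c(8L, 4L),
                             concat = 8L, seed = 3L, dropout = 0) {
  asm <- assemblePinnData(ds, "xc", "xp")
  pc <- pinnConfig(asm$compoundConfigs, asm$proteinConfigs,
                   separatedWidths = sep, concatenatedWidths = concat,
                   dropoutInitial = 0, dropoutHidden = dropout)
  list(asm = asm, model = buildPinn(pc, seed = seed))
}

# reference logistic-regression MCC on the same per-pair features
glmOracleMcc <- function(asm) {
  X <- do.call(cbind, asm$inputs)
  df <- data.frame(y = asm$labels, X)
  fit <- suppressWarnings(
    glm(y ~ ., data = df[asm$trainIdx, ], family = binomial()))
  p <- suppressWarnings(predict(fit, df[asm$trainIdx, ], type = "response"))
  mcc(confusionCounts(p, asm$labels[asm$trainIdx]))
}

expect_paramsEqual <- function(m1, m2) {
  expect_identical(lapply(m1@layers, `[[`, "params"),
                   lapply(m2@layers, `[[`, "params"))
}
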