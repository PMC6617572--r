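#' Specification of a synthetic CPI dataset
#'
#' The generator emulates the two dataset regimes of interest at desk
#' scale: a balanced bioactivity-style corpus (54.7% positives) and a
#' strongly imbalanced toxicology-style corpus (7.49% positives), with
#' SMILES lengths targeting a 75th percentile of 63 characters and protein
#' lengths targeting a (scaled-down) 75th percentile of 120 residues.
#'
#' Labels arise from a low-rank latent interaction rule: each entity
#' receives a `latentDim`-vector that is a seeded random projection of its
#' *observable composition* (circular-fingerprint substructure indicators
#' for compounds, amino-acid composition for proteins), so the signal is
#' recoverable from featurized inputs; pair logits are the standardized
#' latent dot products scaled by `interactionScale`, plus Gaussian noise
#' `noiseSd` and an intercept calibrated by bisection to hit the target
#' positive rate.
#'
#' @param nCompounds,nProteins,nPairs Entity and pair counts (defaults
#'   2000, 200, 20000; `nPairs <= nCompounds * nProteins`).
#' @param positiveRate Target positive fraction in (0, 1) (default 0.547).
#' @param latentDim Rank of the latent interaction (default 2).
#' @param noiseSd Logit-scale noise standard deviation (default 0).
#' @param interactionScale Logit scale of the standardized latent dot
#'   product (default 20, an effectively deterministic rule; stochastic
#'   label noise is introduced separately via `noiseSd`).
#' @param smilesP75,proteinP75 Length targets (75th percentiles; defaults
#'   63 and 120).
#' @param seed Integer seed; all generation is deterministic given it.
#' @return A `SyntheticSpec` list.
#' @export
syntheticSpec <- function(nCompounds = 2000L, nProteins = 200L,
                          nPairs = 20000L, positiveRate = 0.547,
                          latentDim = 2L, noiseSd = 0,
                          interactionScale = 20, smilesP75 = 63L,
                          proteinP75 = 120L, seed = 1L) {
  if (nPairs > nCompounds * nProteins) {
    stop("nPairs exceeds nCompounds * nProteins", call. = FALSE)
  }
  if (positiveRate <= 0 || positiveRate >= 1) {
    stop("positiveRate must lie in (0, 1)", call. = FALSE)
  }
  if (noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
  structure(list(nCompounds = as.integer(nCompounds),
                 nProteins = as.integer(nProteins),
                 nPairs = as.integer(nPairs), positiveRate = positiveRate,
                 latentDim = as.integer(latentDim), noiseSd = noiseSd,
                 interactionScale = interactionScale,
                 smilesP75 = as.integer(smilesP75),
                 proteinP75 = as.integer(proteinP75),
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

# SMILES fragment grammar: every unit is a valid inline fragment that can
# follow an atom and ends on an atom (or closed ring) available for one
# further bond, so any concatenation parses.
.SMILES_UNITS <- c("C", "CC", "CCC", "O", "N", "CO", "CN", "C(C)C",
                   "C(=O)", "C(=O)O", "C(=O)N", "CS", "C(F)(F)F",
                   "c1ccccc1", "c1ccncc1", "c1ccoc1", "c1ccsc1",
                   "C1CCCCC1", "C1CCNCC1", "C1CCOCC1")
.SMILES_UNIT_W <- c(8, 8, 6, 3, 3, 4, 3, 3,
                    3, 3, 3, 1, 1,
                    6, 3, 2, 1,
                    3, 2, 2)

#' Generate synthetic compounds, proteins, and labelled pairs
#'
#' `generateCompounds` assembles SMILES from a fragment grammar (alkyl
#' chains, aromatic and saturated rings, carbonyl/amine/ether units) with
#' target lengths drawn log-normally so the 75th length percentile matches
#' the spec; every string parses.  `generateProteins` draws sequences over
#' the 20 canonical amino acids with log-normal lengths and residue
#' frequencies typical of globular proteins.  `generateLabels` samples
#' distinct pairs and labels them from the latent interaction rule (see
#' [syntheticSpec()]).
#'
#' @param n Number of entities.
#' @param spec A [syntheticSpec()].
#' @return `generateCompounds`: `data.frame(compound_id, smiles)`;
#'   `generateProteins`: `data.frame(protein_id, sequence)`.
#' @export
generateCompounds <- function(n, spec = syntheticSpec()) {
  stopifnot(n >= 1L)
  .withSeed(.childSeed(spec$seed, "compounds"), {
    # p75 of exp(N(mu, 0.5^2)) = exp(mu + 0.674 * 0.5); solve for the target
    mu <- log(spec$smilesP75) - 0.674 * 0.5
    targets <- pmax(5, pmin(95, round(exp(rnorm(n, mu, 0.5)))))
    smiles <- vapply(seq_len(n), function(i) {
      s <- ""
      while (nchar(s) < targets[i]) {
        s <- paste0(s, sample(.SMILES_UNITS, 1, prob = .SMILES_UNIT_W))
      }
      s
    }, character(1))
    data.frame(compound_id = sprintf("CPD%05d", seq_len(n)),
               smiles = smiles, stringsAsFactors = FALSE)
  })
}

# residue frequencies of globular proteins (approximate, renormalized)
.AA_FREQ <- c(A = 8.3, R = 5.5, N = 4.1, D = 5.5, C = 1.4, Q = 3.9, E = 6.8,
              G = 7.1, H = 2.3, I = 5.9, L = 9.7, K = 5.8, M = 2.4, F = 3.9,
              P = 4.7, S = 6.6, T = 5.4, W = 1.1, Y = 2.9, V = 6.9)

#' @rdname generateCompounds
#' @export
generateProteins <- function(n, spec = syntheticSpec()) {
  stopifnot(n >= 1L)
  .withSeed(.childSeed(spec$seed, "proteins"), {
    mu <- log(spec$proteinP75) - 0.674 * 0.45
    lens <- pmax(25, pmin(4 * spec$proteinP75, round(exp(rnorm(n, mu, 0.45)))))
    aa <- names(.AA_FREQ)
    seqs <- vapply(lens, function(L)
      paste(sample(aa, L, replace = TRUE, prob = .AA_FREQ), collapse = ""),
      character(1))
    data.frame(protein_id = sprintf("PROT%04d", seq_len(n)),
               sequence = seqs, stringsAsFactors = FALSE)
  })
}

# standardized composition matrix -> latent vectors via word-keyed random
# projections.  projSeeds/weights allow blending two rules for task pairs.
.latentFromComposition <- function(Z, latentDim, projSeeds, weights) {
  words <- colnames(Z)
  G <- matrix(0, nrow = length(words), ncol = latentDim)
  for (k in seq_along(projSeeds)) {
    Gk <- t(vapply(words, .keyedGaussian, numeric(latentDim),
                   n = latentDim, seed = projSeeds[k]))
    G <- G + weights[k] * Gk
  }
  (Z %*% G) / sqrt(ncol(Z))
}

.standardizeColumns <- function(Z) {
  mu <- colMeans(Z)
  sdev <- sqrt(colMeans(sweep(Z, 2, mu)^2))
  keep <- sdev > 1e-12
  Zs <- sweep(Z, 2, mu)
  Zs[, keep] <- sweep(Zs[, keep, drop = FALSE], 2, sdev[keep], "/")
  Zs[, !keep] <- 0
  Zs
}

# binary substructure-indicator matrix: the reference circular-fingerprint
# view (1024 bits, radius 2), so the latent signal lives exactly in the
# feature space a fingerprint channel observes
.compoundComposition <- function(smiles) {
  Z <- ecfpFingerprint(smiles, nBits = 1024L, radius = 2L)
  colnames(Z) <- sprintf("bit%04d", seq_len(ncol(Z)))
  Z
}

# amino-acid composition (length-normalized counts)
.proteinComposition <- function(sequences) {
  aa <- names(.AA_FREQ)
  Z <- t(vapply(sequences, function(s) {
    cnt <- table(factor(strsplit(s, "")[[1]], levels = aa))
    as.numeric(cnt) / nchar(s)
  }, numeric(length(aa)), USE.NAMES = FALSE))
  colnames(Z) <- aa
  Z
}

#' @param compounds,proteins Entity tables from the generators above.
#' @param projectionSeeds Optional list with elements `compound` and
#'   `protein`, each `list(seeds =, weights =)`, defining the (possibly
#'   blended) latent projection; defaults derive from `spec$seed`.
#' @return `generateLabels`: list with `pairs` (data frame with labels),
#'   `truth` (latent vectors `u`, `v`, `intercept`, `scale`, per-pair
#'   `logits`, `dotStd`).
#' @rdname generateCompounds
#' @export
generateLabels <- function(compounds, proteins, spec = syntheticSpec(),
                           projectionSeeds = NULL) {
  stopifnot(nrow(compounds) >= 1L, nrow(proteins) >= 1L)
  if (is.null(projectionSeeds)) {
    projectionSeeds <- list(
      compound = list(seeds = .childSeed(spec$seed, "projC"), weights = 1),
      protein = list(seeds = .childSeed(spec$seed, "projP"), weights = 1))
  }
  # compounds: centered bit indicators (no variance scaling, so common
  # substructures carry most of the signal and rare bits stay negligible);
  # proteins: standardized amino-acid composition
  Zc <- scale(.compoundComposition(compounds$smiles), center = TRUE,
              scale = FALSE)
  Zp <- .standardizeColumns(.proteinComposition(proteins$sequence))
  u <- .latentFromComposition(Zc, spec$latentDim,
                              projectionSeeds$compound$seeds,
                              projectionSeeds$compound$weights)
  v <- .latentFromComposition(Zp, spec$latentDim,
                              projectionSeeds$protein$seeds,
                              projectionSeeds$protein$weights)
  .withSeed(.childSeed(spec$seed, "pairs"), {
    nC <- nrow(compounds); nP <- nrow(proteins)
    cell <- sample(as.numeric(nC) * nP, spec$nPairs)  # distinct pairs
    cIdx <- ((cell - 1) %% nC) + 1
    pIdx <- ((cell - 1) %/% nC) + 1
    dots <- rowSums(u[cIdx, , drop = FALSE] * v[pIdx, , drop = FALSE])
    dotStd <- (dots - mean(dots)) / sqrt(mean((dots - mean(dots))^2))
    noise <- if (spec$noiseSd > 0) rnorm(spec$nPairs, 0, spec$noiseSd) else 0
    base <- spec$interactionScale * dotStd + noise
    unif <- runif(spec$nPairs)
    b <- .calibrateIntercept(base, unif, spec$positiveRate)
    labels <- as.integer(unif < plogis(base + b))
    pairs <- data.frame(compound_id = compounds$compound_id[cIdx],
                        protein_id = proteins$protein_id[pIdx],
                        label = labels, stringsAsFactors = FALSE)
    list(pairs = pairs,
         truth = list(u = u, v = v, intercept = b,
                      scale = spec$interactionScale,
                      logits = base + b, dotStd = dotStd))
  })
}

# bisection on the intercept so the realized positive rate hits the target
.calibrateIntercept <- function(base, unif, target) {
  rate <- function(b) mean(unif < plogis(base + b))
  lo <- -max(base) - 40
  hi <- -min(base) + 40
  tol <- max(0.0005, 2 / length(unif))
  for (i in seq_len(100L)) {
    mid <- (lo + hi) / 2
    r <- rate(mid)
    if (abs(r - target) <= tol) return(mid)
    if (r < target) lo <- mid else hi <- mid
  }
  if (abs(rate((lo + hi) / 2) - target) > 0.005) {
    stop("positive-rate calibration failed after 100 bisection steps",
         call. = FALSE)
  }
  (lo + hi) / 2
}

#' Simulate a complete synthetic CPI dataset
#'
#' Generates compounds, proteins and labelled pairs per the spec, assigns
#' label-stratified train/validation/test splits (64/16/20%), and returns
#' a [CPIDataset-class] carrying the latent truth.
#'
#' @param spec A [syntheticSpec()].
#' @param projectionSeeds See [generateLabels()].
#' @param entities Optional list `list(compounds =, proteins =)` to reuse
#'   existing entity tables (shared-entity task pairs).
#' @return A [CPIDataset-class].
#' @export
simulateCpiDataset <- function(spec = syntheticSpec(),
                               projectionSeeds = NULL, entities = NULL) {
  compounds <- entities$compounds %||% generateCompounds(spec$nCompounds, spec)
  proteins <- entities$proteins %||% generateProteins(spec$nProteins, spec)
  lab <- generateLabels(compounds, proteins, spec, projectionSeeds)
  ds <- cpiDataset(compounds, proteins, lab$pairs, truth = lab$truth)
  ds@splits <- .withSeed(.childSeed(spec$seed, "splits"), {
    .stratifiedSplit(ds@pairs$label,
                     c(train = 0.64, validation = 0.16, test = 0.20))
  })
  ds
}

.stratifiedSplit <- function(labels, fractions) {
  out <- lapply(fractions, function(f) integer(0))
  cuts <- cumsum(fractions) / sum(fractions)
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    bnd <- round(cuts * length(idx))
    start <- 1L
    for (k in seq_along(fractions)) {
      if (bnd[k] >= start) {
        out[[k]] <- c(out[[k]], idx[start:bnd[k]])
        start <- bnd[k] + 1L
      }
    }
  }
  lapply(out, sort)
}

#' Generate a related source/target task pair for transfer experiments
#'
#' Both tasks share the entity-generation machinery; the target's latent
#' projection is a `similarity`-weighted blend of the source projection and
#' an independent one (`sqrt(1 - similarity^2)` on the independent part, so
#' latent scale is preserved): similarity 1 reproduces the source rule
#' exactly, similarity 0 gives an unrelated rule.  The target defaults to
#' the imbalanced positive-rate regime.
#'
#' @param spec A [syntheticSpec()] for the source task.
#' @param similarity Blend weight in `[0, 1]`.
#' @param targetPositiveRate Positive rate of the target task (default
#'   0.0749).
#' @param targetSpec Optional full [syntheticSpec()] for the target;
#'   defaults to the source spec with the target positive rate and a
#'   derived seed.
#' @param shareEntities Reuse the source entity tables (and pair sampling
#'   seed) for the target, so the two rules are directly comparable on the
#'   same pairs.
#' @return List with elements `source` and `target` ([CPIDataset-class]s).
#' @export
generateTaskPair <- function(spec = syntheticSpec(), similarity = 0.8,
                             targetPositiveRate = 0.0749, targetSpec = NULL,
                             shareEntities = FALSE) {
  if (similarity < 0 || similarity > 1) {
    stop("similarity must lie in [0, 1]", call. = FALSE)
  }
  srcSeeds <- list(
    compound = list(seeds = .childSeed(spec$seed, "projC"), weights = 1),
    protein = list(seeds = .childSeed(spec$seed, "projP"), weights = 1))
  source <- simulateCpiDataset(spec, projectionSeeds = srcSeeds)
  if (is.null(targetSpec)) {
    targetSpec <- spec
    targetSpec$positiveRate <- targetPositiveRate
    targetSpec$seed <- if (shareEntities) spec$seed else
      .childSeed(spec$seed, "targetTask")
  }
  w2 <- sqrt(1 - similarity^2)
  tgtSeeds <- list(
    compound = list(seeds = c(srcSeeds$compound$seeds,
                              .childSeed(spec$seed, "projC_indep")),
                    weights = c(similarity, w2)),
    protein = list(seeds = c(srcSeeds$protein$seeds,
                             .childSeed(spec$seed, "projP_indep")),
                   weights = c(similarity, w2)))
  entities <- if (shareEntities) {
    list(compounds = source@compounds, proteins = source@proteins)
  } else NULL
  target <- simulateCpiDataset(targetSpec, projectionSeeds = tgtSeeds,
                               entities = entities)
  list(source = source, target = target)
}

#' Write and read a synthetic dataset as plain text
#'
#' Writes `compounds.tsv`, `proteins.fasta`, `pairs.tsv`, `splits.tsv` and
#' (when present) `truth.tsv` holding the latent entity vectors plus the
#' calibrated intercept and scale, for parameter-recovery audits.
#'
#' @param dataset A [CPIDataset-class].
#' @param dir Output directory (created if missing).
#' @export
writeCpiDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(dataset@compounds, file.path(dir, "compounds.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste0(">", dataset@proteins$protein_id, "\n",
                    dataset@proteins$sequence),
             file.path(dir, "proteins.fasta"))
  write.table(dataset@pairs[, c("compound_id", "protein_id", "label")],
              file.path(dir, "pairs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (length(dataset@splits)) {
    sp <- data.frame(
      pair_row = unlist(dataset@splits, use.names = FALSE),
      split = rep(names(dataset@splits), lengths(dataset@splits)))
    write.table(sp, file.path(dir, "splits.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tr <- dataset@truth
  if (length(tr)) {
    u <- data.frame(entity = dataset@compounds$compound_id, tr$u)
    v <- data.frame(entity = dataset@proteins$protein_id, tr$v)
    both <- rbind(u, v)
    both$intercept <- tr$intercept
    both$scale <- tr$scale
    write.table(both, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(dir)
}

#' @param dir Directory written by [writeCpiDataset()].
#' @rdname writeCpiDataset
#' @export
readCpiDataset <- function(dir) {
  compounds <- readCompoundTable(file.path(dir, "compounds.tsv"))
  names(compounds) <- c("compound_id", "smiles")
  proteins <- readProteinFasta(file.path(dir, "proteins.fasta"))
  pairs <- readPairTable(file.path(dir, "pairs.tsv"))
  splits <- list()
  sf <- file.path(dir, "splits.tsv")
  if (file.exists(sf)) {
    sp <- read.delim(sf, stringsAsFactors = FALSE)
    splits <- split(sp$pair_row, sp$split)
    splits <- splits[intersect(c("train", "validation", "test"),
                               names(splits))]
  }
  cpiDataset(compounds, proteins, pairs, splits = splits)
}
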