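# Named feature-pair presets: six single-channel (SC) and nine
# multi-channel (MC) combinations of compound features (SMILES tokens,
# ECFP bits, Mol2vec embeddings) and protein features (AA-sequence tokens,
# ProtVec embeddings).
.PRESETS <- list(
  SC_1 = list(compound = "smiles", protein = "aa"),
  SC_2 = list(compound = "smiles", protein = "protvec"),
  SC_3 = list(compound = "mol2vec", protein = "aa"),
  SC_4 = list(compound = "mol2vec", protein = "protvec"),
  SC_5 = list(compound = "ecfp", protein = "aa"),
  SC_6 = list(compound = "ecfp", protein = "protvec"),
  MC_1 = list(compound = "smiles", protein = c("aa", "protvec")),
  MC_2 = list(compound = "mol2vec", protein = c("aa", "protvec")),
  MC_3 = list(compound = "ecfp", protein = c("aa", "protvec")),
  MC_4 = list(compound = c("smiles", "mol2vec"), protein = "aa"),
  MC_5 = list(compound = c("smiles", "mol2vec"), protein = "protvec"),
  MC_6 = list(compound = c("smiles", "ecfp"), protein = "aa"),
  MC_7 = list(compound = c("smiles", "ecfp"), protein = "protvec"),
  MC_8 = list(compound = c("smiles", "mol2vec"), protein = c("aa", "protvec")),
  MC_9 = list(compound = c("smiles", "ecfp"), protein = c("aa", "protvec")))

#' Named model presets
#'
#' The fifteen single-channel (`SC_1`..`SC_6`) and multi-channel
#' (`MC_1`..`MC_9`) feature-pair combinations.  Single-channel presets use
#' two separated layers per channel (reference widths 1024 and 256),
#' multi-channel presets one (256), both with one concatenated layer
#' of 256.
#'
#' @param name Preset name.
#' @return List with `compound` and `protein` channel-name vectors and the
#'   default `separatedWidths`.
#' @export
modelPreset <- function(name) {
  if (!name %in% names(.PRESETS)) {
    stop(sprintf("unknown preset '%s'; valid presets: %s", name,
                 paste(names(.PRESETS), collapse = ", ")), call. = FALSE)
  }
  p <- .PRESETS[[name]]
  p$separatedWidths <- if (grepl("^SC", name)) c(1024L, 256L) else 256L
  p
}

#' @rdname modelPreset
#' @export
listPresets <- function() names(.PRESETS)

#' Experiment configuration
#'
#' Bundles everything one training run needs: the dataset (a
#' [CPIDataset-class] or a [syntheticSpec()] to simulate), the channel
#' selection (a preset name or explicit channel vectors), featurization
#' and architecture parameters, and the training configuration.
#'
#' @param dataset A [CPIDataset-class] or [syntheticSpec()].
#' @param preset A preset name (see [listPresets()]); overridden by
#'   explicit `compoundChannels`/`proteinChannels`.
#' @param compoundChannels,proteinChannels Explicit channel-name vectors
#'   (see [assemblePinnData()]).
#' @param separatedWidths,concatenatedWidths Dense-stack widths; defaults
#'   follow the preset (SC: 2 separated layers, MC: 1).
#' @param mol2vecScheme,protvecScheme Sentence-aggregation schemes
#'   (defaults `"mean"` and `"tfidf"`, the best-performing pairing).
#' @param embeddingDim Skip-gram dimension for dataset-trained embedding
#'   tables (default 64; the full-scale reference is 300).
#' @param protvecN Protein N-gram word size (default 3).
#' @param ecfpBits Fingerprint width (default 1024).
#' @param fixedLengths Token-channel lengths, named `smiles` and `aa`.
#' @param channelArgs Extra [channelConfig()] arguments per channel name.
#' @param dropoutInitial,dropoutHidden Dropout rates passed to
#'   [pinnConfig()] (reference defaults 0.1 and 0.5; reduce for small
#'   desk-scale networks).
#' @param train A [trainConfig()].
#' @param outDir Optional run directory for [runExperiment()] outputs.
#' @param seed Integer seed for model initialization (training uses
#'   `train$seed`).
#' @param force Overwrite an existing run directory.
#' @return A `RunConfig` list.
#' @export
runConfig <- function(dataset, preset = "SC_6", compoundChannels = NULL,
                      proteinChannels = NULL, separatedWidths = NULL,
                      concatenatedWidths = 256L, mol2vecScheme = "mean",
                      protvecScheme = "tfidf", embeddingDim = 64L,
                      protvecN = 3L, ecfpBits = 1024L,
                      fixedLengths = c(smiles = 100L, aa = 700L),
                      channelArgs = list(), dropoutInitial = 0.1,
                      dropoutHidden = 0.5, train = trainConfig(),
                      outDir = NULL, seed = 1L, force = FALSE) {
  p <- modelPreset(preset)
  structure(list(dataset = dataset, preset = preset,
                 compoundChannels = compoundChannels %||% p$compound,
                 proteinChannels = proteinChannels %||% p$protein,
                 separatedWidths = separatedWidths %||% p$separatedWidths,
                 concatenatedWidths = concatenatedWidths,
                 mol2vecScheme = mol2vecScheme,
                 protvecScheme = protvecScheme,
                 embeddingDim = as.integer(embeddingDim),
                 protvecN = as.integer(protvecN),
                 ecfpBits = as.integer(ecfpBits),
                 fixedLengths = fixedLengths, channelArgs = channelArgs,
                 dropoutInitial = dropoutInitial,
                 dropoutHidden = dropoutHidden,
                 train = train, outDir = outDir, seed = as.integer(seed),
                 force = force),
            class = "RunConfig")
}

# materialize the dataset and any missing feature views a config needs
.prepareDataset <- function(config) {
  ds <- config$dataset
  if (inherits(ds, "SyntheticSpec")) ds <- simulateCpiDataset(ds)
  chans <- c(config$compoundChannels, config$proteinChannels)
  if ("ecfp" %in% chans && !"ecfp" %in% names(ds@compoundFeatures)) {
    ds <- featurizeCompoundsEcfp(ds, nBits = config$ecfpBits)
  }
  if ("mol2vec" %in% chans && !"mol2vec" %in% names(ds@compoundFeatures)) {
    ds <- featurizeCompoundsMol2vec(ds, scheme = config$mol2vecScheme,
                                    d = config$embeddingDim,
                                    seed = .childSeed(config$seed, "mol2vec"))
  }
  if ("protvec" %in% chans && !"protvec" %in% names(ds@proteinFeatures)) {
    ds <- featurizeProteinsProtvec(ds, scheme = config$protvecScheme,
                                   n = config$protvecN,
                                   d = config$embeddingDim,
                                   seed = .childSeed(config$seed, "protvec"))
  }
  ds
}

#' Run one end-to-end experiment
#'
#' Featurizes the dataset as the channel selection requires, assembles the
#' tensors, builds the PINN, trains with early stopping, and evaluates on
#' the test split.  When `config$outDir` is set, writes `metrics.tsv`,
#' `history.tsv`, `config.yaml` and `seed.txt` there (refusing to
#' overwrite an existing run unless `config$force`).
#'
#' @param config A [runConfig()].
#' @return List: `dataset`, `fit` (see [trainPinn()]), `metrics`
#'   (test-split [metricsReport()]), `outDir`.
#' @export
runExperiment <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  if (!is.null(config$outDir)) {
    if (dir.exists(config$outDir) && !config$force) {
      stop(sprintf("run directory '%s' exists; use force = TRUE to rerun",
                   config$outDir), call. = FALSE)
    }
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  }
  ds <- .prepareDataset(config)
  asm <- assemblePinnData(ds, config$compoundChannels,
                          config$proteinChannels,
                          fixedLengths = config$fixedLengths,
                          channelArgs = config$channelArgs)
  pc <- pinnConfig(asm$compoundConfigs, asm$proteinConfigs,
                   separatedWidths = config$separatedWidths,
                   concatenatedWidths = config$concatenatedWidths,
                   dropoutInitial = config$dropoutInitial,
                   dropoutHidden = config$dropoutHidden)
  model <- buildPinn(pc, seed = config$seed)
  fit <- trainPinn(model, asm, config$train)
  testScores <- pinnPredict(fit$model, .subsetInputs(asm$inputs, asm$testIdx))
  metrics <- metricsReport(testScores, asm$labels[asm$testIdx])
  if (!is.null(config$outDir)) {
    write.table(data.frame(metric = c("mcc", "rocAuc", "prcAuc"),
                           value = c(metrics$mcc, metrics$rocAuc,
                                     metrics$prcAuc)),
                file.path(config$outDir, "metrics.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(fit$history, file.path(config$outDir, "history.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cfg <- config
    cfg$dataset <- NULL  # not serializable as text; seed + spec suffice
    yaml::write_yaml(lapply(cfg, function(x)
      if (is.atomic(x) || is.list(x)) x else NULL),
      file.path(config$outDir, "config.yaml"))
    writeLines(as.character(c(config$seed, config$train$seed)),
               file.path(config$outDir, "seed.txt"))
  }
  list(dataset = ds, fit = fit, metrics = metrics, outDir = config$outDir)
}

#' Train several configurations repeatedly and rank them
#'
#' Runs every configuration `replicates` times with distinct derived
#' seeds, collects test MCC and ROC, and delegates to [zscoreRanking()].
#'
#' @param configs Named list of [runConfig()]s (names label the models).
#' @param replicates Number of replicate trainings per configuration
#'   (>= 2; the SEM is undefined otherwise).
#' @return List: `ranking` (a `ComparisonReport`), `metrics` (the
#'   models x replicates x metrics array), `runs` (nested run results).
#' @export
runComparison <- function(configs, replicates = 3L) {
  if (length(configs) < 2L) stop("need at least two configs", call. = FALSE)
  if (replicates < 2L) {
    stop("need >= 2 replicates (SEM undefined otherwise)", call. = FALSE)
  }
  if (is.null(names(configs))) {
    names(configs) <- vapply(configs, function(cf) cf$preset, character(1))
  }
  arr <- array(NA_real_,
               dim = c(length(configs), replicates, 2),
               dimnames = list(names(configs), NULL, c("mcc", "roc")))
  runs <- list()
  for (mi in seq_along(configs)) {
    for (r in seq_len(replicates)) {
      cf <- configs[[mi]]
      cf$seed <- .childSeed(cf$seed, sprintf("rep%d_init", r))
      cf$train$seed <- .childSeed(cf$train$seed, sprintf("rep%d_train", r))
      res <- runExperiment(cf)
      arr[mi, r, "mcc"] <- res$metrics$mcc
      arr[mi, r, "roc"] <- res$metrics$rocAuc
      runs[[names(configs)[mi]]][[r]] <- res
    }
  }
  list(ranking = zscoreRanking(arr), metrics = arr, runs = runs)
}
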