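#' Compound-protein interaction dataset
#'
#' The central data container: compound and protein entity tables, the
#' labelled pair table, named per-entity feature views (added by the
#' `featurize*` functions), split assignments over pairs, and -- for
#' synthetic data -- the latent ground truth used to generate the labels.
#'
#' @slot compounds `data.frame` with columns `compound_id`, `smiles`.
#' @slot proteins `data.frame` with columns `protein_id`, `sequence`.
#' @slot pairs `data.frame` with `compound_id`, `protein_id`, `label` and
#'   resolved row indices `cIdx`, `pIdx`.
#' @slot splits Named list of pair-row index vectors (`train`,
#'   `validation`, `test`).
#' @slot compoundFeatures,proteinFeatures Named lists of per-entity
#'   feature matrices (rows follow the entity tables).
#' @slot truth List; for synthetic data: latent entity vectors, intercept,
#'   scale and per-pair logits.
#' @name CPIDataset-class
#' @aliases CPIDataset
#' @exportClass CPIDataset
setClass("CPIDataset",
         representation(compounds = "data.frame", proteins = "data.frame",
                        pairs = "data.frame", splits = "list",
                        compoundFeatures = "list", proteinFeatures = "list",
                        truth = "list"))

setValidity("CPIDataset", function(object) {
  p <- object@pairs
  if (!all(c("compound_id", "protein_id", "label") %in% names(p))) {
    return("pairs must have compound_id, protein_id, label")
  }
  if (!all(p$label %in% c(0L, 1L))) return("labels must be 0/1")
  if (!all(p$compound_id %in% object@compounds$compound_id)) {
    return("pairs reference unknown compounds")
  }
  if (!all(p$protein_id %in% object@proteins$protein_id)) {
    return("pairs reference unknown proteins")
  }
  TRUE
})

#' @param compounds,proteins,pairs Entity and pair tables (see slots).
#' @param splits Optional named list of pair-row indices.
#' @param truth Optional ground-truth list.
#' @rdname CPIDataset-class
#' @export
cpiDataset <- function(compounds, proteins, pairs, splits = list(),
                       truth = list()) {
  pairs$cIdx <- match(pairs$compound_id, compounds$compound_id)
  pairs$pIdx <- match(pairs$protein_id, proteins$protein_id)
  new("CPIDataset", compounds = compounds, proteins = proteins,
      pairs = pairs, splits = splits,
      compoundFeatures = list(), proteinFeatures = list(), truth = truth)
}

setMethod("show", "CPIDataset", function(object) {
  cat(sprintf(paste0("CPIDataset: %d compounds x %d proteins, %d pairs ",
                     "(%.1f%% positive)\n"),
              nrow(object@compounds), nrow(object@proteins),
              nrow(object@pairs), 100 * mean(object@pairs$label)))
  if (length(object@splits)) {
    cat("  splits:", paste(sprintf("%s=%d", names(object@splits),
                                   lengths(object@splits)), collapse = ", "),
        "\n")
  }
  fn <- c(names(object@compoundFeatures), names(object@proteinFeatures))
  if (length(fn)) cat("  features:", paste(fn, collapse = ", "), "\n")
})

#' CPIDataset accessors
#'
#' @param dataset A [CPIDataset-class].
#' @return The corresponding table or list.
#' @export
cpiCompounds <- function(dataset) dataset@compounds

#' @rdname cpiCompounds
#' @export
cpiProteins <- function(dataset) dataset@proteins

#' @rdname cpiCompounds
#' @export
cpiPairs <- function(dataset) dataset@pairs

#' @rdname cpiCompounds
#' @export
cpiSplits <- function(dataset) dataset@splits

#' @rdname cpiCompounds
#' @export
cpiTruth <- function(dataset) dataset@truth

#' Attach feature matrices and sentence featurizers
#'
#' `featurizeCompoundsEcfp` adds ECFP-style fingerprint bits;
#' `featurizeCompoundsMol2vec` and `featurizeProteinsProtvec` add
#' aggregated sentence embeddings (training a skip-gram table on the
#' dataset's own sentences when none is supplied, and fitting the TF-IDF
#' corpus on those sentences for the `"tfidf"` scheme);
#' `setCompoundFeature` / `setProteinFeature` attach arbitrary per-entity
#' matrices.
#'
#' @param dataset A [CPIDataset-class].
#' @param nBits,radius Fingerprint parameters (defaults 1024, 2).
#' @param name Feature-view name.
#' @return The dataset with the feature view attached.
#' @export
featurizeCompoundsEcfp <- function(dataset, nBits = 1024L, radius = 2L,
                                   name = "ecfp") {
  fp <- ecfpFingerprint(.compoundGraphs(dataset), nBits = nBits,
                        radius = radius)
  setCompoundFeature(dataset, name, fp)
}

#' @param table An [EmbeddingTable-class]; `NULL` trains one on the
#'   dataset's sentences.
#' @param radii Morgan radii for compound words.
#' @param scheme Aggregation scheme: `"sum"`, `"mean"` or `"tfidf"`.
#' @param d,window,minCount,seed,epochs Skip-gram parameters used when
#'   `table` is `NULL`.
#' @rdname featurizeCompoundsEcfp
#' @export
featurizeCompoundsMol2vec <- function(dataset, table = NULL,
                                      radii = c(0L, 1L), scheme = "mean",
                                      d = 64L, window = 5L, minCount = 1L,
                                      seed = 1L, epochs = 3L,
                                      name = "mol2vec") {
  sentences <- lapply(.compoundGraphs(dataset), compoundToWords, radii = radii)
  .featurizeSentences(dataset, sentences, table, scheme, d, window, minCount,
                      seed, epochs, name, side = "compound")
}

#' @param n Protein N-gram word size.
#' @rdname featurizeCompoundsEcfp
#' @export
featurizeProteinsProtvec <- function(dataset, table = NULL, n = 3L,
                                     scheme = "tfidf", d = 64L, window = 5L,
                                     minCount = 1L, seed = 1L, epochs = 3L,
                                     name = "protvec") {
  sentences <- lapply(dataset@proteins$sequence, proteinToWords, n = n)
  .featurizeSentences(dataset, sentences, table, scheme, d, window, minCount,
                      seed, epochs, name, side = "protein")
}

.featurizeSentences <- function(dataset, sentences, table, scheme, d, window,
                                minCount, seed, epochs, name, side) {
  if (is.null(table)) {
    table <- trainWordEmbeddings(sentences, d = d, window = window,
                                 minCount = minCount, seed = seed,
                                 epochs = epochs)
  }
  tfidf <- if (scheme == "tfidf") fitTfIdf(sentences) else NULL
  M <- t(vapply(sentences, aggregateSentence, numeric(embeddingDim(table)),
                table = table, scheme = scheme, tfidf = tfidf))
  if (side == "compound") setCompoundFeature(dataset, name, M)
  else setProteinFeature(dataset, name, M)
}

#' @param features Numeric matrix, one row per entity in table order.
#' @rdname featurizeCompoundsEcfp
#' @export
setCompoundFeature <- function(dataset, name, features) {
  stopifnot(nrow(features) == nrow(dataset@compounds))
  dataset@compoundFeatures[[name]] <- features
  dataset
}

#' @rdname featurizeCompoundsEcfp
#' @export
setProteinFeature <- function(dataset, name, features) {
  stopifnot(nrow(features) == nrow(dataset@proteins))
  dataset@proteinFeatures[[name]] <- features
  dataset
}

# parsed molecular graphs, cached in the truth slot is not appropriate;
# recompute (cheap relative to training) unless already memoized
.compoundGraphs <- function(dataset) {
  parseSmiles(dataset@compounds$smiles)
}

#' Assemble per-pair training tensors for a channel selection
#'
#' Expands per-entity feature views to per-pair matrices, standardizes
#' dense features on the training split (zero mean, unit variance), builds
#' token-id matrices for the sequence channels, and returns matching
#' [channelConfig()]s -- everything [trainPinn()] and [buildPinn()] need.
#'
#' @param dataset A [CPIDataset-class] with the required feature views and
#'   splits.
#' @param compoundChannels,proteinChannels Character vectors naming
#'   channels per side: a feature-view name (dense channel) or `"smiles"` /
#'   `"aa"` / `"smiles_lstm"` / `"aa_lstm"` / `"smiles_blstm"` /
#'   `"aa_blstm"` for token channels (dilated CNN by default).
#' @param smilesVocab,aaVocab [TokenVocabulary-class]s for the token
#'   channels; built from the dataset's own strings when `NULL`.
#' @param fixedLengths Named vector with elements `smiles` and `aa`
#'   (defaults 100 and 700).
#' @param normalize Standardize dense channels on the training split.
#' @param channelArgs Named list of extra [channelConfig()] arguments per
#'   channel name (e.g. `list(aa = list(dilationRates = c(1, 2, 4, 8)))`).
#' @return List: `inputs`, `labels`, `trainIdx`, `valIdx`, `testIdx`,
#'   `compoundConfigs`, `proteinConfigs`, `normalizers`.
#' @export
assemblePinnData <- function(dataset, compoundChannels, proteinChannels,
                             smilesVocab = NULL, aaVocab = NULL,
                             fixedLengths = c(smiles = 100L, aa = 700L),
                             normalize = TRUE, channelArgs = list()) {
  sp <- dataset@splits
  if (is.null(sp$train) || is.null(sp$validation)) {
    stop("dataset needs train and validation splits", call. = FALSE)
  }
  pairs <- dataset@pairs
  inputs <- list(); configs <- list(compound = list(), protein = list())
  normalizers <- list()
  for (side in c("compound", "protein")) {
    chans <- if (side == "compound") compoundChannels else proteinChannels
    feats <- if (side == "compound") dataset@compoundFeatures else dataset@proteinFeatures
    eIdx <- if (side == "compound") pairs$cIdx else pairs$pIdx
    for (ch in chans) {
      extra <- channelArgs[[ch]] %||% list()
      if (ch %in% names(feats)) {
        X <- feats[[ch]][eIdx, , drop = FALSE]
        if (normalize) {
          nz <- fitNormalizer(X, sp$train, fittedOn = "train")
          X <- normalizeFeatures(nz, X)
          normalizers[[paste(side, ch, sep = ".")]] <- nz
        }
        cfg <- do.call(channelConfig,
                       c(list(kind = "dense", inputDim = ncol(X)), extra))
      } else {
        tk <- .tokenChannel(dataset, side, ch, smilesVocab, aaVocab,
                            fixedLengths)
        X <- tk$ids[eIdx, , drop = FALSE]
        kind <- if (grepl("_blstm$", ch)) "blstm"
                else if (grepl("_lstm$", ch)) "lstm" else "dilated_cnn"
        cfg <- do.call(channelConfig,
                       c(list(kind = kind, fixedLength = ncol(X),
                              vocabSize = tk$V), extra))
      }
      inputs[[paste(side, ch, sep = ".")]] <- X
      configs[[side]][[ch]] <- cfg
    }
  }
  list(inputs = inputs, labels = pairs$label,
       trainIdx = sp$train, valIdx = sp$validation, testIdx = sp$test,
       compoundConfigs = configs$compound, proteinConfigs = configs$protein,
       normalizers = normalizers)
}

.tokenChannel <- function(dataset, side, ch, smilesVocab, aaVocab,
                          fixedLengths) {
  base <- sub("_b?lstm$", "", ch)
  if (side == "compound" && base == "smiles") {
    vocab <- smilesVocab %||% buildVocabulary(dataset@compounds$smiles)
    ids <- tokenIds(dataset@compounds$smiles, vocab, fixedLengths[["smiles"]])
  } else if (side == "protein" && base == "aa") {
    vocab <- aaVocab %||% buildVocabulary(dataset@proteins$sequence)
    ids <- tokenIds(dataset@proteins$sequence, vocab, fixedLengths[["aa"]])
  } else {
    stop(sprintf("unknown %s channel '%s' (no such feature view)", side, ch),
         call. = FALSE)
  }
  list(ids = ids, V = vocabularySize(vocab))
}
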