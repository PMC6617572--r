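#' Word-embedding tables with an out-of-vocabulary policy
#'
#' Maps words (protein N-grams or compound Morgan-substructure identifiers)
#' to d-dimensional real vectors.  Under the default `"zero"` policy a
#' missing word yields the all-zero vector -- the behaviour used for entities
#' with no sequence information; the `"error"` policy makes lookups strict.
#'
#' @slot vectors Numeric matrix, one row per word (rownames are the words).
#' @slot oovPolicy `"zero"` or `"error"`.
#' @name EmbeddingTable-class
#' @aliases EmbeddingTable
#' @exportClass EmbeddingTable
setClass("EmbeddingTable",
         representation(vectors = "matrix", oovPolicy = "character"))

setValidity("EmbeddingTable", function(object) {
  if (is.null(rownames(object@vectors))) return("vectors must have word rownames")
  if (!object@oovPolicy %in% c("zero", "error")) return("oovPolicy must be 'zero' or 'error'")
  TRUE
})

setMethod("show", "EmbeddingTable", function(object) {
  cat(sprintf("EmbeddingTable: %d words, dimension %d (oov policy: %s)\n",
              nrow(object@vectors), ncol(object@vectors), object@oovPolicy))
})

#' @param vectors Numeric matrix with word rownames.
#' @param oovPolicy `"zero"` (default) or `"error"`.
#' @rdname EmbeddingTable-class
#' @export
embeddingTable <- function(vectors, oovPolicy = c("zero", "error")) {
  new("EmbeddingTable", vectors = as.matrix(vectors),
      oovPolicy = match.arg(oovPolicy))
}

#' Embedding accessors
#'
#' `embeddingDim` returns d; `lookupWords` returns an `N x d` matrix of word
#' vectors honouring the table's out-of-vocabulary policy.
#'
#' @param table An [EmbeddingTable-class].
#' @param words Character vector.
#' @export
embeddingDim <- function(table) ncol(table@vectors)

#' @rdname embeddingDim
#' @export
lookupWords <- function(table, words) {
  idx <- match(words, rownames(table@vectors))
  if (anyNA(idx) && table@oovPolicy == "error") {
    stop(sprintf("word '%s' not in embedding table", words[which(is.na(idx))[1]]),
         call. = FALSE)
  }
  out <- matrix(0, nrow = length(words), ncol = ncol(table@vectors))
  hit <- !is.na(idx)
  out[hit, ] <- table@vectors[idx[hit], , drop = FALSE]
  out
}

#' Split a protein sequence into N-gram words
#'
#' Follows the ProtVec convention: the sentence is the concatenation of the
#' `n` shifted non-overlapping n-gram lists (shifts `0..n-1`), so every
#' residue context appears and the total word count is
#' `sum(floor((len - shift) / n))`.
#'
#' @param aaSequence A single amino-acid string.
#' @param n Word size (default 3).
#' @return Character vector of n-gram words.
#' @examples
#' proteinToWords("MKVLAG", 3)  # MKV LAG KVL VLA
#' @export
proteinToWords <- function(aaSequence, n = 3L) {
  stopifnot(is.character(aaSequence), length(aaSequence) == 1L)
  n <- as.integer(n)
  len <- nchar(aaSequence)
  if (len < n) stop("sequence shorter than word size", call. = FALSE)
  unlist(lapply(seq_len(n) - 1L, function(shift) {
    k <- (len - shift) %/% n
    if (k == 0L) return(character(0))
    starts <- shift + 1L + n * (seq_len(k) - 1L)
    substring(aaSequence, starts, starts + n - 1L)
  }), use.names = FALSE)
}

#' TF-IDF weighting model for sentence aggregation
#'
#' Smoothed inverse document frequencies fitted on a corpus of sentences:
#' `idf(w) = ln((1 + nDocs) / (1 + df(w))) + 1`, the variant with implicit
#' "+1 document" smoothing, so unseen words receive the maximal idf.  Raw
#' in-sentence term counts are used; no norm is applied to the weights
#' (switchable via [aggregateSentence()] arguments).
#'
#' @slot df Named numeric vector of document frequencies.
#' @slot nDocs Number of fitting documents.
#' @name TfIdfModel-class
#' @aliases TfIdfModel
#' @exportClass TfIdfModel
setClass("TfIdfModel", representation(df = "numeric", nDocs = "numeric"))

setMethod("show", "TfIdfModel", function(object) {
  cat(sprintf("TfIdfModel: %d words over %d documents\n",
              length(object@df), as.integer(object@nDocs)))
})

#' Fit a TF-IDF model on a corpus of sentences
#'
#' @param documents List of character vectors (one sentence of words each).
#' @return A [TfIdfModel-class].
#' @examples
#' m <- fitTfIdf(list(c("a", "b"), c("a"), c("c")))
#' idfWeight(m, c("a", "c", "zz"))
#' @export
fitTfIdf <- function(documents) {
  if (length(documents) == 0L || all(lengths(documents) == 0L)) {
    stop("empty corpus", call. = FALSE)
  }
  df <- table(unlist(lapply(documents, unique), use.names = FALSE))
  new("TfIdfModel", df = stats::setNames(as.numeric(df), names(df)),
      nDocs = length(documents))
}

#' @param model A [TfIdfModel-class].
#' @param words Character vector; words absent from the fitting corpus get
#'   `df = 0` (maximal smoothed idf).
#' @rdname fitTfIdf
#' @export
idfWeight <- function(model, words) {
  df <- model@df[words]
  df[is.na(df)] <- 0
  unname(log((1 + model@nDocs) / (1 + df)) + 1)
}

#' Serialize a TF-IDF model as delimited text
#'
#' Columns: word, document_frequency, idf.  A header line
#' `# n_documents <n>` records the corpus size.
#'
#' @param model A [TfIdfModel-class].
#' @param path File path.
#' @export
writeTfIdf <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_documents\t%d", as.integer(model@nDocs)), con)
  writeLines("word\tdocument_frequency\tidf", con)
  writeLines(sprintf("%s\t%d\t%.10g", names(model@df), as.integer(model@df),
                     idfWeight(model, names(model@df))), con)
  invisible(path)
}

#' @rdname writeTfIdf
#' @export
readTfIdf <- function(path) {
  lines <- readLines(path)
  nDocs <- as.numeric(strsplit(lines[1], "\t")[[1]][2])
  df <- read.delim(text = lines[-1], stringsAsFactors = FALSE)
  new("TfIdfModel", df = stats::setNames(as.numeric(df$document_frequency),
                                         df$word), nDocs = nDocs)
}

#' Aggregate a sentence of word vectors into one embedding
#'
#' The three reductions used for molecule/protein sentence embeddings:
#' \describe{
#'   \item{sum}{\eqn{S = \sum_i w_i} -- sensitive to sentence length.}
#'   \item{mean}{\eqn{S = (1/N) \sum_i w_i} -- length-invariant.}
#'   \item{tfidf}{\eqn{S = \sum_i t_{w_i} w_i} with per-occurrence weight
#'     `idf(w)`; summing over occurrences folds the raw term frequency into
#'     the weight, so iterating distinct words once with `tf * idf` gives the
#'     same vector.  The weighted *sum* is the reference behaviour; set
#'     `normalize = TRUE` to divide by the total weight (a weighted
#'     average), and `sublinearTf = TRUE` for `1 + log(tf)` counts.}
#' }
#'
#' @param sentence Character vector of words (N >= 1).
#' @param table An [EmbeddingTable-class].
#' @param scheme `"sum"`, `"mean"` or `"tfidf"`.
#' @param tfidf A fitted [TfIdfModel-class]; required for `scheme = "tfidf"`.
#' @param normalize Divide the tfidf-weighted sum by the summed weights.
#' @param sublinearTf Use `1 + log(tf)` instead of raw term counts.
#' @return Numeric vector of length `embeddingDim(table)`.
#' @export
aggregateSentence <- function(sentence, table,
                              scheme = c("sum", "mean", "tfidf"),
                              tfidf = NULL, normalize = FALSE,
                              sublinearTf = FALSE) {
  scheme <- match.arg(scheme)
  if (length(sentence) == 0L) stop("empty sentence", call. = FALSE)
  W <- lookupWords(table, sentence)
  if (scheme == "sum") return(colSums(W))
  if (scheme == "mean") return(colSums(W) / length(sentence))
  if (is.null(tfidf)) stop("scheme 'tfidf' requires a fitted TfIdfModel", call. = FALSE)
  w <- idfWeight(tfidf, sentence)
  if (sublinearTf) {
    tf <- table(sentence)
    adj <- (1 + log(as.numeric(tf[sentence]))) / as.numeric(tf[sentence])
    w <- w * adj
  }
  out <- colSums(W * w)
  if (normalize) out <- out / sum(w)
  out
}

#' Train skip-gram word embeddings on a sentence corpus
#'
#' A compact skip-gram-with-negative-sampling trainer for desk-scale corpora
#' (the scale at which the synthetic datasets operate); externally trained
#' tables in word2vec text format are loadable with [readWord2vec()] for
#' larger corpora.  Training is single-threaded and fully deterministic for
#' a fixed seed.  Words with corpus frequency below `minCount` are dropped
#' from the table; looking them up afterwards follows the table's
#' out-of-vocabulary policy.
#'
#' @param corpus List of character vectors (sentences of words).
#' @param d Embedding dimension.
#' @param window Symmetric context window size.
#' @param minCount Minimum corpus frequency for a word to be kept (default 2).
#' @param seed Integer seed.
#' @param epochs Training epochs (default 3).
#' @param negatives Negative samples per (center, context) pair (default 5).
#' @param learningRate Initial SGD step size, linearly decayed (default 0.05).
#' @return An [EmbeddingTable-class] with the zero out-of-vocabulary policy.
#' @export
trainWordEmbeddings <- function(corpus, d = 100L, window = 5L, minCount = 2L,
                                seed = 1L, epochs = 3L, negatives = 5L,
                                learningRate = 0.05) {
  if (length(corpus) == 0L || all(lengths(corpus) == 0L)) {
    stop("empty corpus", call. = FALSE)
  }
  .assertScalarNumber(d, "d", positive = TRUE)
  .assertScalarNumber(window, "window", positive = TRUE)
  freq <- table(unlist(corpus, use.names = FALSE))
  vocab <- names(freq)[freq >= minCount]
  if (length(vocab) == 0L) stop("no word reaches minCount", call. = FALSE)
  .withSeed(seed, {
    Ein <- matrix(runif(length(vocab) * d, -0.5, 0.5) / d, ncol = d)
    Eout <- matrix(0, nrow = length(vocab), ncol = d)
    # (center, context) pairs over kept words only, positions in kept order
    pairs <- do.call(rbind, lapply(corpus, function(s) {
      ids <- match(s, vocab)
      ids <- ids[!is.na(ids)]
      L <- length(ids)
      if (L < 2L) return(NULL)
      do.call(rbind, lapply(seq_len(L), function(i) {
        ctx <- setdiff(max(1L, i - window):min(L, i + window), i)
        if (length(ctx) == 0L) return(NULL)
        cbind(ids[i], ids[ctx])
      }))
    }))
    if (is.null(pairs)) stop("corpus yields no context pairs", call. = FALSE)
    negProb <- (as.numeric(freq[vocab]))^0.75
    negProb <- negProb / sum(negProb)
    nPairs <- nrow(pairs)
    totalSteps <- epochs * nPairs
    step <- 0L
    batch <- 2048L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nPairs)
      for (start in seq(1L, nPairs, by = batch)) {
        sel <- ord[start:min(start + batch - 1L, nPairs)]
        m <- length(sel)
        lr <- learningRate * max(1 - step / totalSteps, 1e-4)
        step <- step + m
        ctr <- pairs[sel, 1]; pos <- pairs[sel, 2]
        neg <- matrix(sample.int(length(vocab), m * negatives, replace = TRUE,
                                 prob = negProb), nrow = m)
        Vc <- Ein[ctr, , drop = FALSE]
        # positive examples
        Vp <- Eout[pos, , drop = FALSE]
        gp <- plogis(rowSums(Vc * Vp)) - 1      # sigmoid(score) - label
        dC <- Vp * gp
        dOutRows <- Vc * gp
        outIdx <- pos
        # negative examples
        for (k in seq_len(negatives)) {
          Vn <- Eout[neg[, k], , drop = FALSE]
          gn <- plogis(rowSums(Vc * Vn))
          dC <- dC + Vn * gn
          dOutRows <- rbind(dOutRows, Vc * gn)
          outIdx <- c(outIdx, neg[, k])
        }
        # per-word mean aggregation keeps the step size bounded when a
        # word recurs many times within one batch (small vocabularies)
        dIn <- rowsum(dC, group = ctr)
        dIn <- dIn / as.vector(table(ctr)[rownames(dIn)])
        Ein[as.integer(rownames(dIn)), ] <-
          Ein[as.integer(rownames(dIn)), , drop = FALSE] - lr * dIn
        dOut <- rowsum(dOutRows, group = outIdx)
        dOut <- dOut / as.vector(table(outIdx)[rownames(dOut)])
        Eout[as.integer(rownames(dOut)), ] <-
          Eout[as.integer(rownames(dOut)), , drop = FALSE] - lr * dOut
      }
    }
    rownames(Ein) <- vocab
    embeddingTable(Ein, "zero")
  })
}

#' Read and write embedding tables in word2vec text format
#'
#' Header line `n_words d`, then one word followed by d floats per line.
#'
#' @param table An [EmbeddingTable-class].
#' @param path File path.
#' @export
writeWord2vec <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  V <- table@vectors
  writeLines(sprintf("%d %d", nrow(V), ncol(V)), con)
  writeLines(paste(rownames(V), apply(V, 1, function(r)
    paste(sprintf("%.8g", r), collapse = " "))), con)
  invisible(path)
}

#' @param oovPolicy Out-of-vocabulary policy for the loaded table.
#' @rdname writeWord2vec
#' @export
readWord2vec <- function(path, oovPolicy = c("zero", "error")) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  words <- vapply(parts, `[[`, character(1), 1)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  rownames(vecs) <- words
  embeddingTable(vecs, match.arg(oovPolicy))
}
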