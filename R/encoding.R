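#' Token vocabularies for character-level sequence encoding
#'
#' A `TokenVocabulary` is a bijective map between the single characters of a
#' sequence alphabet and contiguous integer indices `0..V-1`.  SMILES strings
#' and amino-acid sequences are tokenized at single-character granularity
#' (aromatic `c` and aliphatic `C` are distinct tokens, so SMILES is
#' case-sensitive; amino-acid sequences are upper-cased before tokenization
#' by the reader functions).
#'
#' @slot tokens Character vector of single characters; position `i` holds the
#'   token with index `i - 1`.
#' @name TokenVocabulary-class
#' @aliases TokenVocabulary
#' @exportClass TokenVocabulary
setClass("TokenVocabulary", representation(tokens = "character"))

setValidity("TokenVocabulary", function(object) {
  tk <- object@tokens
  if (length(tk) == 0L) return("vocabulary has no tokens")
  if (any(nchar(tk) != 1L)) return("all tokens must be single characters")
  if (anyDuplicated(tk)) return("tokens must be unique")
  TRUE
})

setMethod("show", "TokenVocabulary", function(object) {
  cat(sprintf("TokenVocabulary of size %d: %s\n", length(object@tokens),
              paste(object@tokens, collapse = "")))
})

#' Build a character vocabulary from a corpus of sequences
#'
#' Extracts the set of distinct single characters occurring in `sequences`
#' and orders them lexicographically by character code, so the mapping is
#' reproducible regardless of input order.  The intended usage mirrors common
#' practice for end-to-end sequence models: the vocabulary is extracted from
#' the union of all corpora a model will see (train and test), which is
#' convenient but leaks the test alphabet; pass the training corpus only for
#' a leakage-free vocabulary (unseen characters then raise an encoding
#' error).
#'
#' @param sequences Character vector of sequences (SMILES or amino acids).
#' @return A [TokenVocabulary-class] object.
#' @examples
#' buildVocabulary(c("AB", "BA"))
#' @export
buildVocabulary <- function(sequences) {
  if (length(sequences) == 0L || all(nchar(sequences) == 0L)) {
    stop("empty corpus", call. = FALSE)
  }
  chars <- unique(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE))
  # Lexicographic by character code, independent of the session locale.
  chars <- chars[order(vapply(chars, utf8ToInt, integer(1)))]
  new("TokenVocabulary", tokens = chars)
}

#' Vocabulary accessors
#'
#' `vocabularySize` returns the number of tokens V; `tokenIndex` maps
#' characters to their zero-based indices (`NA` for unknown characters);
#' `vocabularyTokens` returns the ordered token vector.
#'
#' @param vocab A [TokenVocabulary-class].
#' @param chars Character vector of single characters.
#' @return An integer scalar, an integer vector of indices in `0..V-1`, or a
#'   character vector, respectively.
#' @export
vocabularySize <- function(vocab) {
  stopifnot(is(vocab, "TokenVocabulary"))
  length(vocab@tokens)
}

#' @rdname vocabularySize
#' @export
tokenIndex <- function(vocab, chars) {
  stopifnot(is(vocab, "TokenVocabulary"))
  match(chars, vocab@tokens) - 1L
}

#' @rdname vocabularySize
#' @export
vocabularyTokens <- function(vocab) {
  stopifnot(is(vocab, "TokenVocabulary"))
  vocab@tokens
}

#' Fixed-length one-hot encoding of a sequence
#'
#' Encodes a character sequence as an `L x V` binary matrix (`L` =
#' `fixedLength`, `V` = vocabulary size).  Row `i` is one-hot at the index of
#' the i-th character.  Sequences longer than `L` are truncated by removing
#' characters from the end; shorter sequences are zero-padded at the end
#' (all-zero rows -- there is no dedicated padding token).
#'
#' @slot mat The `L x V` binary matrix.
#' @slot sourceLength Pre-truncation character count of the input.
#' @name EncodedSequence-class
#' @aliases EncodedSequence
#' @exportClass EncodedSequence
setClass("EncodedSequence",
         representation(mat = "matrix", sourceLength = "integer"))

setMethod("show", "EncodedSequence", function(object) {
  cat(sprintf("EncodedSequence: %d x %d one-hot matrix (source length %d)\n",
              nrow(object@mat), ncol(object@mat), object@sourceLength))
})

#' @param sequence A single character string.
#' @param vocab A [TokenVocabulary-class] covering every character of the
#'   (possibly truncated) sequence.
#' @param fixedLength Number of rows L of the encoding.
#' @return An [EncodedSequence-class].
#' @examples
#' v <- buildVocabulary(c("ACDE"))
#' encodeSequence("ACD", v, 5)
#' @rdname EncodedSequence-class
#' @export
encodeSequence <- function(sequence, vocab, fixedLength) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            is(vocab, "TokenVocabulary"))
  .assertScalarNumber(fixedLength, "fixedLength", positive = TRUE)
  ids <- tokenIds(sequence, vocab, fixedLength)
  V <- vocabularySize(vocab)
  m <- matrix(0L, nrow = fixedLength, ncol = V,
              dimnames = list(NULL, vocab@tokens))
  keep <- which(ids > 0L)
  m[cbind(keep, ids[keep])] <- 1L
  new("EncodedSequence", mat = m, sourceLength = nchar(sequence))
}

#' Integer token-id matrix for a batch of sequences
#'
#' Internal-friendly companion of [encodeSequence()]: returns 1-based token
#' ids with 0 marking end-padding, the exact information content of the
#' one-hot encoding in `L`-column integer form.  Used as the input format of
#' the sequence channels.
#'
#' @param sequences Character vector.
#' @inheritParams encodeSequence
#' @return For a single sequence an integer vector of length `fixedLength`;
#'   for several, an `n x fixedLength` integer matrix.
#' @export
tokenIds <- function(sequences, vocab, fixedLength) {
  one <- function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    keep <- head(chars, fixedLength)
    idx <- match(keep, vocab@tokens)
    if (anyNA(idx)) {
      p <- which(is.na(idx))[1]
      stop(sprintf("character '%s' at position %d is not in the vocabulary",
                   keep[p], p - 1L), call. = FALSE)
    }
    c(idx, integer(fixedLength - length(idx)))
  }
  if (length(sequences) == 1L) return(one(sequences))
  t(vapply(sequences, one, integer(fixedLength), USE.NAMES = FALSE))
}

#' Decode a one-hot encoding back to characters
#'
#' Reconstructs the first `min(sourceLength, L)` characters from the non-zero
#' rows of an [EncodedSequence-class].
#'
#' @param encoded An [EncodedSequence-class].
#' @param vocab The [TokenVocabulary-class] used to encode it.
#' @return A character string.
#' @export
decodeSequence <- function(encoded, vocab) {
  stopifnot(is(encoded, "EncodedSequence"), is(vocab, "TokenVocabulary"))
  nz <- which(rowSums(encoded@mat) > 0)
  if (length(nz) == 0L) return("")
  idx <- max.col(encoded@mat[nz, , drop = FALSE])
  paste(vocab@tokens[idx], collapse = "")
}

#' Read and write vocabularies as plain text
#'
#' Serialization format: one character per line; the line number minus one is
#' the token index.
#'
#' @param vocab A [TokenVocabulary-class].
#' @param path File path.
#' @return `readVocabulary` returns a [TokenVocabulary-class];
#'   `writeVocabulary` returns `path` invisibly.
#' @export
writeVocabulary <- function(vocab, path) {
  stopifnot(is(vocab, "TokenVocabulary"))
  writeLines(vocab@tokens, path)
  invisible(path)
}

#' @rdname writeVocabulary
#' @export
readVocabulary <- function(path) {
  new("TokenVocabulary", tokens = readLines(path))
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning a data frame
#' with upper-cased sequences.
#'
#' @param path FASTA file path.
#' @return `data.frame` with columns `protein_id`, `sequence`.
#' @export
readProteinFasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  data.frame(protein_id = sub("\\s.*$", "", names(aa)),
             sequence = toupper(as.character(aa)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read delimited compound and pair tables
#'
#' `readCompoundTable` expects columns `compound_id` and `SMILES` (case
#' insensitive); `readPairTable` expects `compound_id`, `protein_id`,
#' `label` with labels in \{0, 1\}.  Tab- or comma-delimited, inferred from
#' the file extension (`.csv` means comma).
#'
#' @param path File path.
#' @return A `data.frame`.
#' @export
readCompoundTable <- function(path) {
  df <- .readDelim(path)
  names(df) <- tolower(names(df))
  if (!all(c("compound_id", "smiles") %in% names(df))) {
    stop("compound table needs columns 'compound_id' and 'SMILES'", call. = FALSE)
  }
  data.frame(compound_id = as.character(df$compound_id),
             smiles = as.character(df$smiles), stringsAsFactors = FALSE)
}

#' @rdname readCompoundTable
#' @export
readPairTable <- function(path) {
  df <- .readDelim(path)
  names(df) <- tolower(names(df))
  need <- c("compound_id", "protein_id", "label")
  if (!all(need %in% names(df))) {
    stop("pair table needs columns compound_id, protein_id, label", call. = FALSE)
  }
  lab <- as.integer(df$label)
  if (!all(lab %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  data.frame(compound_id = as.character(df$compound_id),
             protein_id = as.character(df$protein_id),
             label = lab, stringsAsFactors = FALSE)
}

.readDelim <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}
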