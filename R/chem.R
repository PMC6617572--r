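# Molecular graphs and circular (Morgan/ECFP-style) environment identifiers.
#
# SMILES parsing is delegated to OpenBabel through ChemmineOB/ChemmineR; this
# file only walks the resulting connection table.  Identifiers are computed
# with the classic Morgan relaxation: an initial per-atom invariant is
# iteratively re-hashed together with the sorted (bond order, neighbour
# invariant) multiset, once per radius step.  Identifier values are specific
# to this package's hashing (as ECFP values are specific to a toolkit), but
# symmetry-equivalent atoms always receive equal identifiers.

.ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "H")

#' Parse SMILES strings into molecular graphs
#'
#' Converts SMILES to V2000 connection tables with OpenBabel and returns one
#' graph per input: atoms (element, degree, bond-order sum) and a bond list
#' with orders (aromatic rings are kekulized by the converter).  Unparseable
#' SMILES raise an error that carries the offending string.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A list of graphs, each a list with elements `element` (character),
#'   `bonds` (integer matrix with columns `a`, `b`, `order`), `degree`,
#'   `bondOrderSum`.
#' @export
parseSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  ids <- sprintf("pinncpi_%d", seq_along(smiles))
  src <- paste0(paste(smiles, ids, collapse = "\n"), "\n")
  sdfTxt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", source = src),
    error = function(e) stop("SMILES conversion failed: ", conditionMessage(e),
                             call. = FALSE))
  blocks <- .splitSdfBlocks(sdfTxt)
  got <- vapply(blocks, function(b) sub("\\s.*$", "", b[1]), character(1))
  miss <- !(ids %in% got)
  if (any(miss)) {
    stop(sprintf("unparseable SMILES: '%s'", smiles[which(miss)[1]]),
         call. = FALSE)
  }
  graphs <- lapply(blocks, .sdfBlockToGraph)
  graphs[match(ids, got)]
}

.splitSdfBlocks <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  ends <- which(lines == "$$$$")
  starts <- c(1L, head(ends, -1L) + 1L)
  mapply(function(s, e) lines[s:(e - 1L)], starts, ends, SIMPLIFY = FALSE)
}

# One V2000 block -> graph.  The counts line is line 4; atom lines follow,
# then bond lines.  Fixed-width fields per the V2000 specification.
.sdfBlockToGraph <- function(lines) {
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1L) stop("empty molecule block", call. = FALSE)
  atomLines <- lines[5:(4 + na)]
  element <- trimws(substr(atomLines, 32, 34))
  if (nb > 0L) {
    bondLines <- lines[(5 + na):(4 + na + nb)]
    bonds <- cbind(a = as.integer(substr(bondLines, 1, 3)),
                   b = as.integer(substr(bondLines, 4, 6)),
                   order = as.integer(substr(bondLines, 7, 9)))
  } else {
    bonds <- matrix(integer(0), ncol = 3,
                    dimnames = list(NULL, c("a", "b", "order")))
  }
  degree <- tabulate(c(bonds[, "a"], bonds[, "b"]), nbins = na)
  bos <- integer(na)
  if (nb > 0L) {
    for (k in seq_len(nb)) {
      bos[bonds[k, "a"]] <- bos[bonds[k, "a"]] + bonds[k, "order"]
      bos[bonds[k, "b"]] <- bos[bonds[k, "b"]] + bonds[k, "order"]
    }
  }
  list(element = element, bonds = bonds, degree = degree, bondOrderSum = bos)
}

# Per-atom circular environment identifiers up to maxRadius.
# Returns an (nAtoms x (maxRadius+1)) matrix; column r+1 holds radius-r ids.
.morganIdentifiers <- function(graph, maxRadius) {
  na <- length(graph$element)
  elemIdx <- match(graph$element, .ELEMENTS)
  elemIdx[is.na(elemIdx)] <- length(.ELEMENTS) + 1L
  inv <- vapply(seq_len(na), function(i) {
    .hashIntVec(c(elemIdx[i], graph$degree[i], graph$bondOrderSum[i]))
  }, numeric(1))
  out <- matrix(0, nrow = na, ncol = maxRadius + 1L)
  out[, 1] <- inv
  if (maxRadius >= 1L && nrow(graph$bonds) > 0L) {
    nbrs <- vector("list", na)
    for (k in seq_len(nrow(graph$bonds))) {
      a <- graph$bonds[k, "a"]; b <- graph$bonds[k, "b"]
      o <- graph$bonds[k, "order"]
      nbrs[[a]] <- rbind(nbrs[[a]], c(b, o))
      nbrs[[b]] <- rbind(nbrs[[b]], c(a, o))
    }
    for (r in seq_len(maxRadius)) {
      inv2 <- numeric(na)
      for (i in seq_len(na)) {
        nb <- nbrs[[i]]
        if (is.null(nb)) {
          inv2[i] <- .hashIntVec(c(r, inv[i]))
        } else {
          pairs <- cbind(nb[, 2], inv[nb[, 1]])
          ord <- order(pairs[, 1], pairs[, 2])
          inv2[i] <- .hashIntVec(c(r, inv[i], as.vector(t(pairs[ord, , drop = FALSE]))))
        }
      }
      inv <- inv2
      out[, r + 1L] <- inv
    }
  } else if (maxRadius >= 1L) {
    for (r in seq_len(maxRadius)) out[, r + 1L] <- vapply(inv, function(x) .hashIntVec(c(r, x)), numeric(1))
  }
  out
}

#' Morgan substructure "words" of a compound
#'
#' Emits one word per heavy atom and per radius: the circular-environment
#' identifier of that atom at that radius, as a character string.  Atoms are
#' taken in connection-table order (which follows the SMILES atom order) and,
#' within an atom, radius 0 precedes radius 1, matching the sentence
#' convention of substructure-embedding featurizers.  Duplicate words are
#' retained: symmetric atoms contribute one occurrence each.
#'
#' @param smiles A single SMILES string, or a pre-parsed graph from
#'   [parseSmiles()].
#' @param radii Integer vector of radii (default `c(0, 1)`).
#' @return Character vector of words (the compound "sentence").
#' @examples
#' compoundToWords("CC", radii = 0)  # two identical words
#' @export
compoundToWords <- function(smiles, radii = c(0L, 1L)) {
  stopifnot(length(radii) >= 1L, all(radii >= 0L))
  graph <- if (is.character(smiles)) parseSmiles(smiles)[[1]] else smiles
  ids <- .morganIdentifiers(graph, max(radii))
  radii <- sort(unique(as.integer(radii)))
  words <- as.vector(t(ids[, radii + 1L, drop = FALSE]))  # per atom, radius asc
  sprintf("m%d", words)
}

#' ECFP-style circular fingerprints
#'
#' Binary fingerprints of diameter `2 * radius` (default diameter 4,
#' ECFP4-like): every atom environment identifier with radius `0..radius` is
#' folded into `nBits` positions by modulus.  Identifier values are specific
#' to this package's hashing, as they are to any fingerprint toolkit.
#'
#' @param smiles Character vector of SMILES strings (or a list of parsed
#'   graphs).
#' @param nBits Fingerprint width (default 1024).
#' @param radius Maximum environment radius (default 2).
#' @return A `length(smiles) x nBits` 0/1 integer matrix.
#' @export
ecfpFingerprint <- function(smiles, nBits = 1024L, radius = 2L) {
  graphs <- if (is.character(smiles)) parseSmiles(smiles) else smiles
  out <- matrix(0L, nrow = length(graphs), ncol = nBits)
  for (i in seq_along(graphs)) {
    ids <- .morganIdentifiers(graphs[[i]], radius)
    bits <- unique(as.vector(ids) %% nBits) + 1L
    out[i, bits] <- 1L
  }
  out
}
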