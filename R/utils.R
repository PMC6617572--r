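# Internal helpers shared across modules.

#' @import methods
#' @importFrom stats rnorm runif plogis sd var quantile rbinom t.test var.test
#' @importFrom utils read.delim write.table head tail
NULL

# Deterministic polynomial hash of an integer vector into [0, 2^31 - 2].
# Doubles stay below 2^53 throughout, so the arithmetic is exact.
.hashIntVec <- function(v) {
  m <- 2147483647  # 2^31 - 1, prime
  h <- 0
  for (x in v) {
    h <- (h * 1000003 + (x %% m)) %% m
  }
  h
}

# Seeded standard-normal vector keyed by an arbitrary string; used for
# word-keyed random projections that must agree across datasets.
.keyedGaussian <- function(key, n, seed) {
  h <- .hashIntVec(c(seed, utf8ToInt(key)))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(h %% .Machine$integer.max)
  rnorm(n)
}

# Run an expression with a local RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a base seed and a label, kept below 2^31.
.childSeed <- function(seed, label) {
  as.integer(.hashIntVec(c(seed, utf8ToInt(as.character(label)))) %% 2147483000L + 1L)
}

.assertScalarNumber <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  }
  if (positive && x <= 0) stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}

.sem <- function(x) stats::sd(x) / sqrt(length(x))
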