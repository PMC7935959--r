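# Internal helpers: deterministic seed streams, RNG isolation, tiny hashing.

#' Derive a child seed from a parent seed and integer tags
#'
#' Mixes a parent seed with one or more non-negative integer tags through a
#' multiplicative congruential step, giving reproducible, well-separated seed
#' streams for nested stochastic stages (ICA restarts, per-gene permutation
#' nulls, replicate simulations). The result is always in [1, 2^31 - 2] so it
#' is a valid R integer seed.
#'
#' @param seed integer parent seed.
#' @param ... integer tags (stage number, gene index, set size, ...).
#' @return a single integer seed.
#' @keywords internal
derive_seed <- function(seed, ...) {
  tags <- c(...)
  h <- as.double(seed) %% 2147483647
  for (tag in tags) {
    # 69069 is the classic VAX MCG multiplier; modulus 2^31 - 1 keeps the
    # state in integer range. All arithmetic in doubles stays exact here
    # because intermediate products are < 2^53.
    h <- (h * 69069 + (as.double(tag) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

# Deterministic integer tag for a gene identifier (polynomial string hash).
# Null seeds derive from this rather than from the row index, so prediction
# scores are invariant to gene-row permutation.
gene_tag <- function(id) {
  h <- 0
  for (x in utf8ToInt(id)) h <- (h * 131 + x) %% 16777213
  as.integer(h)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# FNV-1a 32-bit hash of a character vector, returned as 8 hex digits.
# Used to stamp pipeline artifacts with a configuration fingerprint.
# Arithmetic runs in doubles (exact below 2^53); the xor only touches the
# low byte, as the FNV-1a round requires.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

# Stop unless all values are finite numerics.
stopifnot_finite <- function(x, what = "values") {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop(sprintf("%s must be finite numeric values", what), call. = FALSE)
  invisible(TRUE)
}
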