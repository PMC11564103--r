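# Internal helpers shared across modules.

sigmoid <- function(x) plogis(x)

logit <- function(p) qlogis(p)

#' Derive a reproducible substream seed
#'
#' All generators take one user-facing seed and derive independent
#' per-entity substream seeds from it, so that simulated entities (wells,
#' ROIs, patients) can be generated in any order or in parallel without
#' changing the output.
#'
#' @param seed Integer master seed.
#' @param index Integer substream index (>= 0).
#' @return An integer seed below 2^31.
#' @keywords internal
substream_seed <- function(seed, index) {
  # Weyl-style mixing; keeps results in the positive 32-bit integer range.
  s <- (as.double(seed) %% 2147483647) + 1
  v <- (s * 48271 + as.double(index) * 2246822519) %% 2147483629
  as.integer(v)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]", name))
  }
  x
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number", name))
  }
  x
}

# Stable content hash of a character vector (feature order fingerprint).
feature_hash <- function(x) {
  rlang::hash(as.character(x))
}
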