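# Internal helpers shared across the pipeline.

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds, balancing fold sizes within each
#' stratum. Consumes the current RNG stream (wrap in [withr::with_seed()] for
#' reproducibility).
#'
#' @param strata vector defining the strata (class labels or stage strings).
#' @param k number of folds; `k = 1` puts every sample in fold 1.
#' @return integer vector of fold ids in `1:k`, same length as `strata`.
#' @keywords internal
make_folds <- function(strata, k) {
  n <- length(strata)
  if (k < 1L) stop("k must be >= 1")
  fold <- integer(n)
  if (k == 1L) return(fold + 1L)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Entropy of a count vector, natural log. Zero counts contribute zero.
entropy_nat <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) return(0)
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

# Entropy in bits (used by the MDL stopping criterion).
entropy_bits <- function(counts) entropy_nat(counts) / log(2)

# Coerce labels to a 0/1 integer vector, validating content.
as_binary_labels <- function(labels) {
  if (inherits(labels, "stage_labels")) labels <- labels$label
  y <- as.integer(labels)
  if (anyNA(y) || !all(y %in% c(0L, 1L))) {
    stop("labels must be binary 0 (early) / 1 (late)")
  }
  y
}

# Deterministic derived seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
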