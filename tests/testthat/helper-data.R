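# Programmatic fixtures.

# Random WOE-able count table (k bins x 2 classes). With zero_cells = FALSE
# every cell is >= 1 so the unsmoothed formulas are exact.
random_count_table <- function(k = sample(2:6, 1), zero_cells = FALSE) {
  lo <- if (zero_cells) 0L else 1L
  Ei <- sample(lo:30, k, replace = TRUE)
  Li <- sample(lo:30, k, replace = TRUE)
  if (sum(Ei) == 0) Ei[1L] <- 1L
  if (sum(Li) == 0) Li[1L] <- 1L
  list(Ei = Ei, Li = Li)
}

# Expand a count table into bin-index / label vectors.
table_to_vectors <- function(tab) {
  k <- length(tab$Ei)
  bins <- c(rep(seq_len(k), tab$Ei), rep(seq_len(k), tab$Li))
  labels <- rep(c(0L, 1L), c(sum(tab$Ei), sum(tab$Li)))
  list(bins = bins, labels = labels, k = k)
}

# Small random instance for discretization oracles: few distinct values,
# both classes guaranteed present.
random_small_instance <- function(n_max = 15L, v_max = 6L) {
  n <- sample(4:n_max, 1)
  values <- sample(seq_len(v_max), n, replace = TRUE) +
    round(stats::runif(1), 2)
  labels <- sample(0:1, n, replace = TRUE)
  if (length(unique(labels)) < 2L) labels[1:2] <- c(0L, 1L)
  list(values = values, labels = labels)
}

# Small discrete feature frame for FCBF oracles.
random_fcbf_instance <- function(n = 40L, p = sample(3:10, 1)) {
  y <- sample(0:1, n, replace = TRUE)
  if (length(unique(y)) < 2L) y[1:2] <- c(0L, 1L)
  x <- as.data.frame(lapply(seq_len(p), function(j) {
    k <- sample(2:4, 1)
    if (stats::runif(1) < 0.5) {
      sample(seq_len(k), n, replace = TRUE)          # noise
    } else {
      pmin(pmax(y + sample(0:(k - 1), n, replace = TRUE), 1), k)  # class-linked
    }
  }))
  names(x) <- sprintf("f%02d", seq_len(p))
  list(x = x, y = y)
}

# Tiny labeled cohort for fast end-to-end pipeline tests.
small_cohort <- function(seed = 42L) {
  generate_cohort(cohort_config(
    n_samples = 200L, n_noise = 60L, n_informative = 6L,
    n_redundant_per_informative = 1L, effect_shift = 1.5,
    seed = seed))
}

small_control <- function(seed = 7L, ...) {
  stage_control(
    seed = seed, fcbf_folds = 5L, cv_folds = 5L,
    classifiers = list(
      classifier_spec("svm_rbf", seed = seed, tune = FALSE, gamma = 0.1, cost = 1),
      classifier_spec("logistic", seed = seed),
      classifier_spec("naive_bayes", seed = seed)),
    ...)
}
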