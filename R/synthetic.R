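# Synthetic cohort generator: long-tailed non-negative expression with
# planted class-shifted genes, correlated redundant copies, and pure noise.

#' Synthetic cohort configuration
#'
#' Defines a cohort with the statistical structure the pipeline assumes:
#' log-normal (heavy right tail) abundance marginals; a minority of
#' informative genes whose log2 location shifts between early and late
#' samples; redundant genes that are correlated noisy copies of an
#' informative parent; and pure-noise genes. Defaults describe the reference
#' recovery scenario used throughout the package: 500 samples (40% late,
#' close to the 243/604 late share of a typical renal-carcinoma cohort),
#' 15 informative genes with a one-unit log2 shift, two redundant copies per
#' informative gene, and 2000 noise genes.
#'
#' @param n_samples total samples.
#' @param late_fraction fraction of late-stage samples, in (0, 1).
#' @param n_noise pure-noise genes.
#' @param n_informative planted class-shifted genes.
#' @param n_redundant_per_informative correlated copies per informative gene.
#' @param effect_shift class difference of the informative genes' log2 mean.
#' @param dispersion per-gene SD on the log2 scale (tail weight).
#' @param redundancy_correlation target Pearson r (log scale) between a
#'   redundant gene and its parent, in (0, 1).
#' @param baseline_log2_range range the per-gene baseline log2 means are
#'   drawn from.
#' @param seed integer seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 500L, late_fraction = 0.4,
                          n_noise = 2000L, n_informative = 15L,
                          n_redundant_per_informative = 2L,
                          effect_shift = 1.0, dispersion = 1.0,
                          redundancy_correlation = 0.8,
                          baseline_log2_range = c(2, 9), seed = 1L) {
  if (!(late_fraction > 0 && late_fraction < 1)) stop("late_fraction must be in (0, 1)")
  if (dispersion <= 0) stop("dispersion must be positive")
  if (!(redundancy_correlation > 0 && redundancy_correlation < 1)) {
    stop("redundancy_correlation must be in (0, 1)")
  }
  n_late <- round(late_fraction * n_samples)
  if (n_late < 2L || n_samples - n_late < 2L) {
    stop("both classes need at least 2 samples")
  }
  if (n_noise < 0L || n_informative < 0L || n_redundant_per_informative < 0L) {
    stop("gene counts must be non-negative")
  }
  structure(list(n_samples = as.integer(n_samples),
                 late_fraction = late_fraction,
                 n_noise = as.integer(n_noise),
                 n_informative = as.integer(n_informative),
                 n_redundant_per_informative = as.integer(n_redundant_per_informative),
                 effect_shift = effect_shift, dispersion = dispersion,
                 redundancy_correlation = redundancy_correlation,
                 baseline_log2_range = baseline_log2_range,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic expression cohort
#'
#' Values are built on the log2 scale and exponentiated, so they are
#' non-negative without truncation artifacts. Noise genes draw from a
#' class-independent normal on the log2 scale; informative genes shift their
#' log2 mean by `effect_shift` in late samples (alternating up/down
#' direction across genes); redundant genes mix their standardized parent
#' with fresh noise to hit the target log-scale correlation exactly in
#' expectation. Gene rows are shuffled (seeded), and each sample also gets a
#' four-level pathologic stage string so stratified splitting is exercised.
#'
#' @param config a [cohort_config()].
#' @return a `synthetic_cohort` list: `expression` (genes x samples raw
#'   abundance matrix), `labels` (a `stage_labels` data frame), and `truth`
#'   (data frame `gene_id`, `role` in noise/informative/redundant, `parent`,
#'   `shift`).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("config must come from cohort_config()")
  cf <- config
  n <- cf$n_samples
  n_late <- round(cf$late_fraction * n)
  p <- cf$n_noise + cf$n_informative * (1L + cf$n_redundant_per_informative)
  gene_ids <- sprintf("g%05d", seq_len(p))
  sample_ids <- sprintf("s%04d", seq_len(n))
  withr::with_seed(cf$seed, {
    y <- sample(rep(c(1L, 0L), c(n_late, n - n_late)))
    # stage strings: early mostly Stage I, late mostly Stage III
    stage <- ifelse(y == 0L,
                    ifelse(stats::runif(n) < 0.8, "Stage I", "Stage II"),
                    ifelse(stats::runif(n) < 0.57, "Stage III", "Stage IV"))
    logm <- matrix(0, nrow = p, ncol = n)
    role <- rep("noise", p)
    parent <- rep(NA_character_, p)
    shift <- rep(0, p)
    mu <- stats::runif(p, cf$baseline_log2_range[1L], cf$baseline_log2_range[2L])
    g <- 0L
    if (cf$n_informative > 0L) {
      for (i in seq_len(cf$n_informative)) {
        g <- g + 1L
        d <- if (i %% 2L == 0L) -cf$effect_shift else cf$effect_shift
        role[g] <- "informative"; shift[g] <- d
        logm[g, ] <- mu[g] + d * (y == 1L) + cf$dispersion * stats::rnorm(n)
        for (rcopy in seq_len(cf$n_redundant_per_informative)) {
          g <- g + 1L
          role[g] <- "redundant"; parent[g] <- gene_ids[g - rcopy]
          zp <- scale(logm[g - rcopy, ])[, 1L]
          r <- cf$redundancy_correlation
          logm[g, ] <- mu[g] + cf$dispersion *
            (r * zp + sqrt(1 - r^2) * stats::rnorm(n))
        }
      }
    }
    while (g < p) {
      g <- g + 1L
      logm[g, ] <- mu[g] + cf$dispersion * stats::rnorm(n)
    }
    perm <- sample(p)
  })
  expr <- 2^logm
  dimnames(expr) <- list(gene_ids, sample_ids)
  truth <- data.frame(gene_id = gene_ids, role = role, parent = parent,
                      shift = shift, stringsAsFactors = FALSE)
  expr <- expr[perm, , drop = FALSE]
  truth <- truth[perm, , drop = FALSE]
  rownames(truth) <- NULL
  labels <- data.frame(sample_id = sample_ids, stage = stage, label = y,
                       stringsAsFactors = FALSE)
  class(labels) <- c("stage_labels", "data.frame")
  attr(labels, "excluded") <- character(0)
  structure(list(expression = expr, labels = labels, truth = truth,
                 config = cf), class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits the same TSV dialect the readers consume: `expression.tsv`
#' (genes x samples), `clinical.tsv` (`sample_id`, `pathologic_stage`), and
#' `truth.tsv` (`gene_id`, `role`, `parent`, `shift`).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_expression_matrix(cohort$expression, paths["expression"])
  utils::write.table(
    data.frame(sample_id = cohort$labels$sample_id,
               pathologic_stage = cohort$labels$stage),
    paths["clinical"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
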