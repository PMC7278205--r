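# Chi-merge supervised discretization and the max-bin-share gene filter.

#' Pearson chi-square for two adjacent bins
#'
#' The merge statistic of Chi-merge: a Pearson chi-square on the 2 x 2 table
#' (two adjacent bins x two classes). Cells whose expected count is zero
#' (a class or a bin empty across the pair) contribute 0, so a pair in which
#' only one class occurs has chi-square 0 — merging it never loses class
#' discrimination.
#'
#' @param tab 2 x 2 non-negative integer matrix, rows = adjacent bins,
#'   columns = classes (early, late).
#' @return the chi-square statistic (>= 0).
#' @export
chi_square_adjacent <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("tab must be a 2 x 2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("tab must hold non-negative integer counts")
  n <- sum(tab)
  if (n == 0) stop("all-zero table: chi-square undefined")
  expected <- outer(rowSums(tab), colSums(tab)) / n
  ok <- expected > 0
  sum((tab[ok] - expected[ok])^2 / expected[ok])
}

# Equal-frequency prebinning with ties kept together: each distinct value is
# assigned a prebin index from its cumulative sample count, so equal values
# can never straddle a boundary. Returns at most `prebins` groups.
prebin_groups <- function(counts, prebins) {
  cum <- cumsum(counts)
  n <- cum[length(cum)]
  g <- ceiling(cum * prebins / n)
  # renumber consecutively (some target groups may be skipped by heavy ties)
  cumsum(c(TRUE, diff(g) > 0))
}

#' Fit a Chi-merge binning scheme for one gene
#'
#' Bottom-up supervised discretization: values start in equal-frequency
#' prebins (ties kept together) and the adjacent pair of bins whose 2 x 2
#' class table has the smallest chi-square is merged repeatedly, so the final
#' bins differ as much as possible in their early/late composition. Merging
#' stops only when all three conditions hold: every adjacent chi-square
#' exceeds `chi2_stop`, the number of bins is at most `max_bins`, and every
#' bin holds at least `min_bin_fraction` of the training samples. Ties on the
#' merge statistic are broken by the leftmost pair, making the fit
#' deterministic.
#'
#' @param values numeric vector of training values for one gene.
#' @param labels binary labels (0 early / 1 late), same length.
#' @param initial_prebins number of equal-frequency prebins to start from.
#' @param chi2_stop chi-square stopping threshold; the default 3.841 is the
#'   0.95 quantile of chi-square with 1 df.
#' @param max_bins maximum number of final bins.
#' @param min_bin_fraction minimum fraction of training samples per bin.
#' @param gene_id optional gene identifier carried in the scheme.
#' @return a `binning_scheme` list: `gene_id`, `cuts` (strictly increasing
#'   interior cut points; `k - 1` cuts define `k` bins over the whole real
#'   line), `n_bins`, and the training class counts per bin.
#' @export
chimerge_fit <- function(values, labels, initial_prebins = 20L,
                         chi2_stop = 3.841, max_bins = 6L,
                         min_bin_fraction = 0.05, gene_id = NA_character_) {
  y <- as_binary_labels(labels)
  if (length(values) != length(y)) stop("values and labels differ in length")
  if (any(!is.finite(values))) stop("values must be finite")
  n <- length(values)
  ux <- sort(unique(values))
  if (length(ux) < 2L) {
    warning("all values identical: single-bin scheme for gene ", gene_id)
    cnt <- matrix(c(sum(y == 0L), sum(y == 1L)), nrow = 1L)
    return(structure(list(gene_id = gene_id, cuts = numeric(0), n_bins = 1L,
                          counts = cnt, n = n), class = "binning_scheme"))
  }
  if (length(unique(y)) < 2L) stop("both classes must be present to fit a binning scheme")

  code <- match(values, ux)
  per_val <- matrix(0, nrow = length(ux), ncol = 2L)
  for (i in seq_len(n)) per_val[code[i], y[i] + 1L] <- per_val[code[i], y[i] + 1L] + 1
  grp <- if (length(ux) <= initial_prebins) seq_along(ux) else
    prebin_groups(rowSums(per_val), initial_prebins)
  k <- max(grp)
  counts <- rowsum(per_val, grp)                 # k x 2 class counts per prebin
  upper <- c(which(diff(grp) > 0), length(ux))   # last distinct-value index per bin

  adj_chi <- function(i) chi_square_adjacent(counts[c(i, i + 1L), , drop = FALSE])
  chi <- if (k > 1L) vapply(seq_len(k - 1L), adj_chi, numeric(1)) else numeric(0)

  while (k > 1L) {
    need <- min(chi) <= chi2_stop || k > max_bins ||
      min(rowSums(counts)) / n < min_bin_fraction
    if (!need) break
    j <- which.min(chi)                          # leftmost minimal pair
    counts[j, ] <- counts[j, ] + counts[j + 1L, ]
    counts <- counts[-(j + 1L), , drop = FALSE]
    upper <- upper[-j]
    k <- k - 1L
    chi <- chi[-j]
    if (j > 1L) chi[j - 1L] <- adj_chi(j - 1L)
    if (j <= length(chi)) chi[j] <- adj_chi(j)
  }
  cuts <- if (k > 1L) (ux[upper[-k]] + ux[upper[-k] + 1L]) / 2 else numeric(0)
  structure(list(gene_id = gene_id, cuts = cuts, n_bins = k,
                 counts = counts, n = n), class = "binning_scheme")
}

#' Map values to bin indices under a fitted scheme
#'
#' Bins are half-open on the left, `(c_{j-1}, c_j]`, with the outer bins
#' unbounded, so every real value maps to exactly one bin; a value exactly
#' equal to a cut point falls in the left bin. Indices are 1-based.
#'
#' @param values numeric vector.
#' @param scheme a `binning_scheme` from [chimerge_fit()].
#' @return integer vector of bin indices in `1:scheme$n_bins`.
#' @export
assign_bins <- function(values, scheme) {
  if (!inherits(scheme, "binning_scheme")) stop("scheme must come from chimerge_fit()")
  if (length(scheme$cuts) == 0L) return(rep(1L, length(values)))
  findInterval(values, scheme$cuts, left.open = TRUE) + 1L
}

#' Dominant-bin gene filter
#'
#' A gene whose largest training bin holds more than `threshold` of the
#' training samples is nearly constant after discretization and is dropped
#' (strict inequality: a share exactly at the threshold is kept).
#'
#' @param bin_counts per-bin training totals (vector), or a `binning_scheme`
#'   whose stored counts are used.
#' @param threshold maximal allowed share of the largest bin (default 0.90).
#' @return `TRUE` to keep the gene, `FALSE` to drop it.
#' @export
max_bin_filter <- function(bin_counts, threshold = 0.90) {
  if (inherits(bin_counts, "binning_scheme")) bin_counts <- rowSums(bin_counts$counts)
  share <- max(bin_counts) / sum(bin_counts)
  share <= threshold
}
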