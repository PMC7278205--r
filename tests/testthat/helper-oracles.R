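# Independent reference implementations used to cross-check the package's
# formulas and algorithms. Deliberately written with different machinery
# (chisq.test, table(), lm, naive recursion) than the implementations they
# verify.

# Pearson chi-square with the zero-expected-cell convention, via chisq.test
# after dropping empty margins (a cell with zero expected count contributes
# zero, which is equivalent to dropping its empty row/column).
oracle_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  t2 <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(t2) < 2L || ncol(t2) < 2L) return(0)
  unname(suppressWarnings(stats::chisq.test(t2, correct = FALSE)$statistic))
}

# Symmetric uncertainty by direct summation of the mutual-information series.
oracle_su <- function(x, y) {
  jt <- table(x, y)
  n <- sum(jt)
  pxy <- jt / n
  px <- rowSums(pxy); py <- colSums(pxy)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx + hy == 0) return(0)
  mi <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      if (pxy[i, j] > 0) mi <- mi + pxy[i, j] * log(pxy[i, j] / (px[i] * py[j]))
    }
  }
  unname(2 * mi / (hx + hy))
}

# WOE vector straight from the definition (same smoothing convention).
oracle_woe <- function(Ei, Li, s = 0.5) {
  E <- sum(Ei); L <- sum(Li)
  if (any(Ei == 0 | Li == 0)) {
    log((Ei + s) / E) - log((Li + s) / L)
  } else {
    log(Ei / E) - log(Li / L)
  }
}

# Information value straight from the definition.
oracle_iv <- function(Ei, Li, s = 0.5) {
  E <- sum(Ei); L <- sum(Li)
  if (any(Ei == 0 | Li == 0)) { a <- (Ei + s) / E; b <- (Li + s) / L }
  else { a <- Ei / E; b <- Li / L }
  sum((a - b) * log(a / b))
}

# Per-feature VIF through lm().
oracle_vif <- function(x) {
  x <- as.matrix(x)
  vapply(seq_len(ncol(x)), function(i) {
    d <- data.frame(yv = x[, i], x[, -i, drop = FALSE])
    r2 <- summary(stats::lm(yv ~ ., data = d))$r.squared
    1 / (1 - r2)
  }, numeric(1))
}

# Chi-merge by naive greedy search: every adjacent pair's statistic is
# recomputed from scratch through oracle_chi2 at every step, enumerating all
# candidate merges.
oracle_chimerge_cuts <- function(values, labels, initial_prebins = 20,
                                 chi2_stop = 3.841, max_bins = 6,
                                 min_bin_fraction = 0.05) {
  n <- length(values)
  ux <- sort(unique(values))
  if (length(ux) < 2L) return(numeric(0))
  cnt <- vapply(ux, function(u) sum(values == u), numeric(1))
  if (length(ux) <= initial_prebins) {
    g <- seq_along(ux)
  } else {
    gg <- ceiling(cumsum(cnt) * initial_prebins / n)
    g <- cumsum(c(TRUE, diff(gg) > 0))
  }
  bins <- unname(split(seq_along(ux), g))
  bin_counts <- function(ix) {
    inb <- values %in% ux[ix]
    c(sum(labels[inb] == 0), sum(labels[inb] == 1))
  }
  counts <- t(vapply(bins, bin_counts, numeric(2)))
  repeat {
    k <- length(bins)
    if (k == 1L) break
    chis <- vapply(seq_len(k - 1L), function(j)
      oracle_chi2(counts[j:(j + 1L), , drop = FALSE]), numeric(1))
    if (min(chis) > chi2_stop && k <= max_bins &&
        min(rowSums(counts)) / n >= min_bin_fraction) break
    j <- which.min(chis)
    bins[[j]] <- c(bins[[j]], bins[[j + 1L]])
    bins[[j + 1L]] <- NULL
    counts[j, ] <- counts[j, ] + counts[j + 1L, ]
    counts <- counts[-(j + 1L), , drop = FALSE]
  }
  if (length(bins) == 1L) return(numeric(0))
  vapply(seq_len(length(bins) - 1L), function(j) {
    hi <- max(bins[[j]])
    (ux[hi] + ux[hi + 1L]) / 2
  }, numeric(1))
}

# Entropy/MDL discretization by naive recursion over every midpoint between
# adjacent distinct sorted values.
oracle_mdlp_cuts <- function(values, labels) {
  rec <- function(v, y) {
    o <- order(v); v <- v[o]; y <- y[o]
    N <- length(v)
    if (N < 2L) return(numeric(0))
    ent <- function(yy) {
      p <- table(yy) / length(yy)
      -sum(p * log2(p))
    }
    cands <- which(v[-N] < v[-1L])
    if (!length(cands)) return(numeric(0))
    infos <- vapply(cands, function(i)
      (i * ent(y[1:i]) + (N - i) * ent(y[(i + 1):N])) / N, numeric(1))
    pick <- which.min(infos)
    j <- cands[pick]
    entS <- ent(y)
    gain <- entS - infos[pick]
    k <- length(unique(y))
    k1 <- length(unique(y[1:j])); k2 <- length(unique(y[(j + 1):N]))
    delta <- log2(3^k - 2) -
      (k * entS - k1 * ent(y[1:j]) - k2 * ent(y[(j + 1):N]))
    if (gain <= (log2(N - 1) + delta) / N) return(numeric(0))
    sort(c((v[j] + v[j + 1L]) / 2,
           rec(v[1:j], y[1:j]), rec(v[(j + 1):N], y[(j + 1):N])))
  }
  rec(values, labels)
}

# FCBF by literal transcription of the predominant-correlation definition,
# with all symmetric uncertainties from oracle_su.
oracle_fcbf <- function(df, y, delta = 0) {
  nm <- names(df)
  su_c <- vapply(df, function(col) oracle_su(col, y), numeric(1))
  names(su_c) <- nm
  sel <- nm[su_c > delta]
  sel <- sel[order(-su_c[sel], sel)]
  keep <- character(0)
  while (length(sel)) {
    f <- sel[1L]
    keep <- c(keep, f)
    sel <- sel[-1L]
    if (length(sel)) {
      red <- vapply(sel, function(g2) oracle_su(df[[f]], df[[g2]]) >= su_c[g2],
                    logical(1))
      sel <- sel[!red]
    }
  }
  keep
}
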