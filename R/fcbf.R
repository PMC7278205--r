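# Fast correlation-based filtering: symmetric uncertainty, the internal
# entropy/MDL discretizer it needs, the FCBF search itself, and stability
# aggregation over repeated cross-validation resampling.

# Symmetric uncertainty from integer codes in 1:kx / 1:ky.
su_codes <- function(cx, kx, cy, ky) {
  n <- length(cx)
  joint <- tabulate((cy - 1L) * kx + cx, nbins = kx * ky)
  hx <- entropy_nat(tabulate(cx, nbins = kx))
  hy <- entropy_nat(tabulate(cy, nbins = ky))
  if (hx + hy == 0) return(0)
  hxy <- entropy_nat(joint)
  su <- 2 * (hx + hy - hxy) / (hx + hy)
  min(max(su, 0), 1)
}

#' Symmetric uncertainty between two discrete vectors
#'
#' `SU(X, Y) = 2 I(X; Y) / (H(X) + H(Y))`, the mutual information normalized
#' by the marginal entropies (natural log; the ratio is base-invariant).
#' Ranges over \[0, 1\]: 0 for independence, 1 for a deterministic one-to-one
#' relation. Defined as 0 when both variables are constant.
#'
#' @param x,y discrete vectors (factor, character, or integer codes) of equal
#'   length.
#' @return symmetric uncertainty in \[0, 1\].
#' @export
symmetric_uncertainty <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (!length(x)) stop("need at least one sample")
  cx <- as.integer(factor(x)); cy <- as.integer(factor(y))
  su_codes(cx, max(cx), cy, max(cy))
}

# Recursive entropy-minimization cuts with the MDL stopping criterion,
# operating on presorted values. Returns the accepted cut values.
mdlp_cuts_sorted <- function(x, y) {
  cuts <- numeric(0)
  ent2 <- function(a, b) {
    n <- a + b
    h <- numeric(length(n))
    pos <- a > 0; h[pos] <- h[pos] - (a / n * log2(a / n))[pos]
    pos <- b > 0; h[pos] <- h[pos] - (b / n * log2(b / n))[pos]
    h
  }
  recurse <- function(lo, hi) {
    N <- hi - lo + 1L
    if (N < 2L) return(invisible())
    xs <- x[lo:hi]; ys <- y[lo:hi]
    c1 <- cumsum(ys); c0 <- seq_len(N) - c1
    tot1 <- c1[N]; tot0 <- c0[N]
    cand <- which(xs[-N] < xs[-1L])
    if (!length(cand)) return(invisible())
    l0 <- c0[cand]; l1 <- c1[cand]
    r0 <- tot0 - l0; r1 <- tot1 - l1
    entL <- ent2(l0, l1); entR <- ent2(r0, r1)
    info <- (cand * entL + (N - cand) * entR) / N
    j <- which.min(info)                       # leftmost minimal cut
    entS <- ent2(tot0, tot1)
    gain <- entS - info[j]
    k  <- (tot0 > 0) + (tot1 > 0)
    kL <- (l0[j] > 0) + (l1[j] > 0)
    kR <- (r0[j] > 0) + (r1[j] > 0)
    delta <- log2(3^k - 2) - (k * entS - kL * entL[j] - kR * entR[j])
    if (gain <= (log2(N - 1) + delta) / N) return(invisible())
    cuts <<- c(cuts, (xs[cand[j]] + xs[cand[j] + 1L]) / 2)
    recurse(lo, lo + cand[j] - 1L)
    recurse(lo + cand[j], hi)
    invisible()
  }
  recurse(1L, length(x))
  sort(cuts)
}

#' Entropy/MDL supervised discretization of one continuous feature
#'
#' The internal discretizer feeding symmetric-uncertainty computations on
#' continuous expression values: cut points are chosen recursively to
#' minimize the class-information entropy, and each cut is accepted only if
#' it passes the minimum-description-length criterion. Features for which no
#' cut is accepted become single-valued (and thus carry zero relevance).
#' Because cuts are order statistics, the result is invariant under strictly
#' monotone transforms of `values`.
#'
#' @param values numeric vector.
#' @param labels binary class labels (0/1), same length.
#' @return integer vector of bin codes (1-based), with the accepted cut
#'   values in attribute `"cuts"`.
#' @export
mdl_discretize <- function(values, labels) {
  y <- as_binary_labels(labels)
  if (length(values) != length(y)) stop("values and labels differ in length")
  ord <- order(values)
  cuts <- mdlp_cuts_sorted(values[ord], y[ord])
  codes <- findInterval(values, cuts, left.open = TRUE) + 1L
  attr(codes, "cuts") <- cuts
  codes
}

#' Fast correlation-based filter on discrete features
#'
#' Classic two-phase FCBF: features are ranked by their symmetric uncertainty
#' with the class (relevance, kept when strictly above `delta`), then the
#' ranked list is walked keeping each remaining feature as predominant and
#' removing every later feature `f_j` whose redundancy `SU(f_i, f_j)` with a
#' kept feature is at least its own relevance `SU(f_j, class)`. Ties in
#' relevance are broken lexicographically on the feature name, so the result
#' does not depend on input column order.
#'
#' @param x samples x features matrix or data frame of discrete values, with
#'   column names.
#' @param y binary class labels (0/1).
#' @param delta relevance threshold; features with `SU <= delta` are never
#'   considered (default 0).
#' @return character vector of selected feature names, in selection
#'   (decreasing-relevance) order; full relevance scores in attribute
#'   `"su_relevance"`.
#' @export
fcbf <- function(x, y, delta = 0) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.null(names(x)) || any(names(x) == "")) stop("features must be named")
  yv <- as_binary_labels(y)
  nm <- names(x)
  codes <- lapply(x, function(col) as.integer(factor(col)))
  kk <- vapply(codes, max, integer(1))
  cy <- yv + 1L
  su_rel <- vapply(seq_along(codes), function(i)
    su_codes(codes[[i]], kk[i], cy, 2L), numeric(1))
  names(su_rel) <- nm
  cand <- which(su_rel > delta)
  ordc <- cand[order(-su_rel[cand], nm[cand])]
  alive <- rep(TRUE, length(ordc))
  keep <- integer(0)
  for (i in seq_along(ordc)) {
    if (!alive[i]) next
    gi <- ordc[i]
    keep <- c(keep, gi)
    if (i < length(ordc)) {
      for (j in seq(i + 1L, length(ordc))) {
        if (!alive[j]) next
        gj <- ordc[j]
        if (su_codes(codes[[gi]], kk[gi], codes[[gj]], kk[gj]) >= su_rel[gj]) {
          alive[j] <- FALSE
        }
      }
    }
  }
  structure(nm[keep], su_relevance = su_rel)
}

# One FCBF run on the raw training values of a fold: per gene, MDL-discretize
# using a precomputed sort order, then run fcbf on genes with >= 1 cut.
fold_fcbf_raw <- function(mat, y, ord_mat, keep_mask, delta) {
  p <- nrow(mat)
  sub <- which(keep_mask)
  ys <- y[sub]
  cy <- ys + 1L
  codes_list <- vector("list", p)
  kk <- integer(p)
  su_rel <- numeric(p)
  for (g in seq_len(p)) {
    xg <- mat[g, ]
    ord <- ord_mat[g, ]
    ord_sub <- ord[keep_mask[ord]]
    cuts <- mdlp_cuts_sorted(xg[ord_sub], y[ord_sub])
    if (!length(cuts)) next
    codes_list[[g]] <- findInterval(xg[sub], cuts, left.open = TRUE) + 1L
    kk[g] <- length(cuts) + 1L
    su_rel[g] <- su_codes(codes_list[[g]], kk[g], cy, 2L)
  }
  nm <- rownames(mat)
  cand <- which(su_rel > delta)
  ordc <- cand[order(-su_rel[cand], nm[cand])]
  alive <- rep(TRUE, length(ordc))
  keep <- integer(0)
  for (i in seq_along(ordc)) {
    if (!alive[i]) next
    gi <- ordc[i]
    keep <- c(keep, gi)
    if (i < length(ordc)) {
      for (j in seq(i + 1L, length(ordc))) {
        if (!alive[j]) next
        gj <- ordc[j]
        if (su_codes(codes_list[[gi]], kk[gi], codes_list[[gj]], kk[gj]) >= su_rel[gj]) {
          alive[j] <- FALSE
        }
      }
    }
  }
  keep
}

#' Stability-aggregated FCBF gene selection
#'
#' Runs FCBF on raw (untransformed) training expression values under repeated
#' resampling: in each of `repeats` rounds the training samples are split
#' into `folds` stratified cross-validation folds (reshuffled each round,
#' seeded), FCBF is run on every fold-training split, and the round's subset
#' is formed by `within_repeat_rule` (default: genes selected in at least
#' half the folds). Genes selected in at least `min_count` of the `repeats`
#' rounds form the kept set. Discretization inside each run uses
#' [mdl_discretize()], so the raw abundance scale is irrelevant (the cuts are
#' order statistics).
#'
#' @param mat genes x samples matrix of raw training values.
#' @param labels binary labels (0/1) for the training samples.
#' @param repeats number of resampling rounds (default 10).
#' @param folds folds per round (default 10); `folds = 1` degenerates to one
#'   FCBF run on the full data per round.
#' @param within_repeat_rule how a round's 10 fold-level selections collapse
#'   to one subset: `"majority"` (>= ceiling(folds/2) folds), `"union"`, or
#'   `"intersection"`.
#' @param min_count minimal number of rounds a gene must be selected in
#'   (default 8).
#' @param delta FCBF relevance threshold.
#' @param seed integer seed; results are bit-for-bit reproducible given
#'   `(seed, repeats, folds)`.
#' @return a `selection_frequency` data frame with columns `gene_id`,
#'   `count` (rounds selected, in `0:repeats`) and `kept`; attributes
#'   `repeats`, `min_count`, and `kept` (character vector of kept genes).
#' @export
stability_select <- function(mat, labels, repeats = 10L, folds = 10L,
                             within_repeat_rule = c("majority", "union", "intersection"),
                             min_count = 8L, delta = 0, seed = 1L) {
  validate_expression_matrix(mat)
  y <- as_binary_labels(labels)
  if (length(y) != ncol(mat)) stop("labels and matrix columns differ in length")
  if (repeats < 1L) stop("repeats must be >= 1")
  if (min_count > repeats) stop("min_count cannot exceed repeats")
  rule <- match.arg(within_repeat_rule)
  p <- nrow(mat); n <- ncol(mat)
  ord_mat <- t(apply(mat, 1L, order))           # per-gene sample sort order
  thr <- switch(rule, majority = ceiling(folds / 2), union = 1L,
                intersection = folds)
  count <- integer(p)
  withr::with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold <- make_folds(y, folds)
      nsel <- integer(p)
      for (f in seq_len(folds)) {
        keep_mask <- if (folds == 1L) rep(TRUE, n) else fold != f
        sel <- fold_fcbf_raw(mat, y, ord_mat, keep_mask, delta)
        nsel[sel] <- nsel[sel] + 1L
      }
      count[nsel >= thr] <- count[nsel >= thr] + 1L
    }
  })
  out <- data.frame(gene_id = rownames(mat), count = count,
                    kept = count >= min_count & count > 0L,
                    stringsAsFactors = FALSE)
  class(out) <- c("selection_frequency", "data.frame")
  attr(out, "repeats") <- repeats
  attr(out, "min_count") <- min_count
  attr(out, "kept") <- out$gene_id[out$kept]
  out
}

#' Export a selection-frequency table as TSV
#'
#' @param freq a `selection_frequency` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_selection_frequency <- function(freq, path) {
  utils::write.table(as.data.frame(freq), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
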