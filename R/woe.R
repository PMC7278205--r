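# Weight-of-evidence encoding of discretized genes, and (de)serialization of
# fitted binning + WOE models.

#' Fit a weight-of-evidence table on training bins
#'
#' For each bin `i` with `E_i` early and `L_i` late training samples (totals
#' `E`, `L`):
#' \deqn{WOE_i = \ln\frac{E_i/E}{L_i/L}}
#' Positive WOE marks an early-enriched bin. If any bin has a zero cell the
#' log is undefined, so `smoothing` (default 0.5) is added to every bin cell
#' (totals stay unsmoothed): `WOE_i = ln((E_i + s)/(L_i + s)) - ln(E/L)`.
#' On tables without zero cells the formula is exact.
#'
#' @param bins integer bin indices (from [assign_bins()]), training samples.
#' @param labels binary labels (0 early / 1 late), same length.
#' @param smoothing additive smoothing applied only when a zero cell exists.
#' @param n_bins total number of bins in the scheme (defaults to `max(bins)`).
#' @return a `woe_table` data frame with columns `bin`, `n_early`, `n_late`,
#'   `woe`, and attributes `E`, `L` (class totals) and `smoothed`.
#' @export
woe_fit <- function(bins, labels, smoothing = 0.5, n_bins = max(bins)) {
  y <- as_binary_labels(labels)
  if (length(bins) != length(y)) stop("bins and labels differ in length")
  E <- sum(y == 0L); L <- sum(y == 1L)
  if (E == 0L || L == 0L) stop("both classes must be present to fit WOE")
  Ei <- tabulate(bins[y == 0L], nbins = n_bins)
  Li <- tabulate(bins[y == 1L], nbins = n_bins)
  smoothed <- any(Ei == 0L | Li == 0L)
  s <- if (smoothed) smoothing else 0
  woe <- log((Ei + s) / (Li + s)) - log(E / L)
  out <- data.frame(bin = seq_len(n_bins), n_early = Ei, n_late = Li, woe = woe)
  class(out) <- c("woe_table", "data.frame")
  attr(out, "E") <- E
  attr(out, "L") <- L
  attr(out, "smoothed") <- smoothed
  attr(out, "smoothing") <- if (smoothed) smoothing else 0
  out
}

#' Encode values by their bin's weight of evidence
#'
#' A deterministic step function: each value is assigned to its training bin
#' and replaced by that bin's WOE. On realistic cohorts the encoded values
#' fall roughly in \[-3, 3\]; no hard clipping is applied.
#'
#' @param values numeric vector (any sample set).
#' @param scheme `binning_scheme` fitted on training data.
#' @param table matching `woe_table` fitted on training data.
#' @return numeric vector of WOE-encoded values.
#' @export
woe_transform <- function(values, scheme, table) {
  if (!inherits(table, "woe_table")) stop("table must come from woe_fit()")
  table$woe[assign_bins(values, scheme)]
}

#' Fit Chi-merge + WOE for a set of genes
#'
#' Convenience wrapper fitting, per gene, a Chi-merge scheme and its WOE
#' table on training data.
#'
#' @param train_mat genes x samples matrix (training samples only).
#' @param labels binary labels for the training samples.
#' @param genes gene IDs to fit (default: all rows).
#' @param ... passed to [chimerge_fit()] (`initial_prebins`, `chi2_stop`,
#'   `max_bins`, `min_bin_fraction`).
#' @param smoothing passed to [woe_fit()].
#' @return a `woe_model`: named list (per gene) of `list(scheme, table)`.
#' @export
woe_model_fit <- function(train_mat, labels, genes = rownames(train_mat),
                          smoothing = 0.5, ...) {
  y <- as_binary_labels(labels)
  out <- lapply(genes, function(g) {
    scheme <- chimerge_fit(train_mat[g, ], y, gene_id = g, ...)
    bins <- assign_bins(train_mat[g, ], scheme)
    list(scheme = scheme,
         table = woe_fit(bins, y, smoothing = smoothing, n_bins = scheme$n_bins))
  })
  names(out) <- genes
  structure(out, class = "woe_model")
}

#' Apply a fitted WOE model to an expression matrix
#'
#' @param mat genes x samples matrix (any sample set) containing every gene
#'   in the model.
#' @param model a `woe_model` from [woe_model_fit()].
#' @param genes subset of model genes to encode (default all).
#' @return samples x genes matrix of WOE-encoded values.
#' @export
woe_model_transform <- function(mat, model, genes = names(model)) {
  missing <- setdiff(genes, rownames(mat))
  if (length(missing)) stop("gene(s) absent from matrix: ",
                            paste(utils::head(missing, 5L), collapse = ", "))
  enc <- vapply(genes, function(g)
    woe_transform(mat[g, ], model[[g]]$scheme, model[[g]]$table),
    numeric(ncol(mat)))
  if (is.null(dim(enc))) enc <- matrix(enc, nrow = 1L, dimnames = list(NULL, genes))
  rownames(enc) <- colnames(mat)
  enc
}

#' Serialize / restore fitted binning + WOE tables as JSON
#'
#' The audit format stores, per gene, the cut points, per-bin early/late
#' counts and WOE values, and the class totals, so an encoding can be
#' re-applied or inspected without the training data.
#'
#' @param model a `woe_model`.
#' @param path JSON path.
#' @return `write_woe_model`: `path` invisibly; `read_woe_model`: a
#'   `woe_model`.
#' @export
write_woe_model <- function(model, path) {
  doc <- lapply(model, function(m) list(
    gene_id = m$scheme$gene_id,
    cuts = m$scheme$cuts,
    n_bins = m$scheme$n_bins,
    n_early = m$table$n_early,
    n_late = m$table$n_late,
    woe = m$table$woe,
    E = attr(m$table, "E"),
    L = attr(m$table, "L"),
    smoothed = attr(m$table, "smoothed"),
    smoothing = attr(m$table, "smoothing")))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_woe_model
#' @export
read_woe_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(doc), function(g) {
    d <- doc[[g]]
    scheme <- structure(list(gene_id = d$gene_id, cuts = as.numeric(d$cuts),
                             n_bins = as.integer(d$n_bins),
                             counts = cbind(d$n_early, d$n_late),
                             n = sum(d$n_early) + sum(d$n_late)),
                        class = "binning_scheme")
    tab <- data.frame(bin = seq_len(scheme$n_bins), n_early = d$n_early,
                      n_late = d$n_late, woe = d$woe)
    class(tab) <- c("woe_table", "data.frame")
    attr(tab, "E") <- d$E; attr(tab, "L") <- d$L
    attr(tab, "smoothed") <- d$smoothed; attr(tab, "smoothing") <- d$smoothing
    list(scheme = scheme, table = tab)
  })
  names(out) <- names(doc)
  structure(out, class = "woe_model")
}
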