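# Joint statistical measures on WOE-encoded training features: information
# value, pairwise-correlation redundancy elimination, and VIF collinearity
# screening.

#' Information value of a discretized gene
#'
#' Summarizes a fitted WOE table into a single predictive-power score:
#' \deqn{IV = \sum_i \left(\frac{E_i}{E} - \frac{L_i}{L}\right)
#'       \ln\frac{E_i/E}{L_i/L}}
#' Every term is of the form `(a - b) ln(a/b) >= 0`, so IV is non-negative
#' and invariant under bin relabeling. When the table was fitted with
#' smoothing (a zero cell), the same smoothed numerators enter both factors,
#' keeping each contribution finite and non-negative. Conventional strength
#' categories: `< 0.02` unpredictive, `0.02-0.10` weak, `0.10-0.30`
#' moderate, `> 0.30` strong.
#'
#' @param woe_table a `woe_table` from [woe_fit()].
#' @param gene_id optional identifier carried in the record.
#' @return an `iv_record` list: `gene_id`, `iv`, per-bin `contributions`,
#'   and `category`.
#' @export
information_value <- function(woe_table, gene_id = NA_character_) {
  if (!inherits(woe_table, "woe_table")) stop("woe_table must come from woe_fit()")
  E <- attr(woe_table, "E"); L <- attr(woe_table, "L")
  s <- attr(woe_table, "smoothing") %||% 0
  if (nrow(woe_table) == 1L) {
    warning("single-bin table: IV = 0 for gene ", gene_id)
    contrib <- 0
  } else {
    a <- (woe_table$n_early + s) / E
    b <- (woe_table$n_late + s) / L
    contrib <- (a - b) * woe_table$woe
  }
  iv <- sum(contrib)
  category <- if (iv < 0.02) "unpredictive" else if (iv < 0.10) "weak" else
    if (iv <= 0.30) "moderate" else "strong"
  structure(list(gene_id = gene_id, iv = iv, contributions = contrib,
                 category = category), class = "iv_record")
}

#' Information values for every gene of a WOE model
#'
#' @param model a `woe_model` from [woe_model_fit()].
#' @return data frame with columns `gene_id`, `iv`, `category`, sorted by
#'   decreasing IV.
#' @export
iv_table <- function(model) {
  recs <- lapply(names(model), function(g)
    information_value(model[[g]]$table, gene_id = g))
  df <- data.frame(gene_id = vapply(recs, `[[`, character(1), "gene_id"),
                   iv = vapply(recs, `[[`, numeric(1), "iv"),
                   category = vapply(recs, `[[`, character(1), "category"),
                   stringsAsFactors = FALSE)
  df[order(-df$iv, df$gene_id), , drop = FALSE]
}

#' Filter genes by information value
#'
#' Rejects genes whose IV falls below `threshold`; a gene exactly at the
#' threshold is kept ("lower than" is the rejection rule).
#'
#' @param iv data frame with columns `gene_id`, `iv` (e.g. from
#'   [iv_table()]), or a named numeric vector of IVs.
#' @param threshold minimal IV (default 0.1).
#' @return data frame of kept genes sorted by decreasing IV.
#' @export
iv_filter <- function(iv, threshold = 0.1) {
  if (!is.data.frame(iv)) {
    iv <- data.frame(gene_id = names(iv), iv = as.numeric(iv),
                     stringsAsFactors = FALSE)
  }
  out <- iv[iv$iv >= threshold, , drop = FALSE]
  out[order(-out$iv, out$gene_id), , drop = FALSE]
}

#' Pairwise-correlation redundancy filter
#'
#' Computes Pearson correlations between all pairs of encoded genes.
#' Violating pairs (`|r| > threshold`) are processed in decreasing `|r|`; in
#' each still-live pair the gene with the lower IV is dropped (ties broken
#' lexicographically: the alphabetically later gene is dropped) and its
#' remaining pairs are discarded. A gene in no violating pair is never
#' dropped. Constant encoded genes have undefined correlations and are
#' dropped up front with a warning.
#'
#' @param x samples x genes matrix of WOE-encoded training values.
#' @param iv named numeric vector of IV scores covering every column of `x`.
#' @param threshold maximal allowed `|r|` (default 0.7).
#' @return list with `kept` (character vector) and `log` (data frame of
#'   decisions: `gene_a`, `gene_b`, `r`, `dropped`).
#' @export
correlation_filter <- function(x, iv, threshold = 0.7) {
  x <- as.matrix(x)
  nm <- colnames(x)
  if (is.null(nm)) stop("encoded matrix must have gene column names")
  if (nrow(x) < 2L) stop("need at least two samples")
  log <- data.frame(gene_a = character(0), gene_b = character(0),
                    r = numeric(0), dropped = character(0),
                    stringsAsFactors = FALSE)
  const <- apply(x, 2L, stats::sd) == 0
  if (any(const)) {
    warning("constant encoded gene(s) dropped: ",
            paste(nm[const], collapse = ", "))
    log <- rbind(log, data.frame(gene_a = nm[const], gene_b = NA_character_,
                                 r = NA_real_, dropped = nm[const],
                                 stringsAsFactors = FALSE))
    x <- x[, !const, drop = FALSE]
    nm <- colnames(x)
  }
  if (ncol(x) >= 2L) {
    cm <- stats::cor(x)
    pairs <- which(upper.tri(cm) & abs(cm) > threshold, arr.ind = TRUE)
    if (nrow(pairs)) {
      pr <- data.frame(a = nm[pairs[, 1L]], b = nm[pairs[, 2L]],
                       r = cm[pairs], stringsAsFactors = FALSE)
      swap <- pr$a > pr$b
      tmp <- pr$a[swap]; pr$a[swap] <- pr$b[swap]; pr$b[swap] <- tmp
      pr <- pr[order(-abs(pr$r), pr$a, pr$b), , drop = FALSE]
      dropped <- character(0)
      for (i in seq_len(nrow(pr))) {
        a <- pr$a[i]; b <- pr$b[i]
        if (a %in% dropped || b %in% dropped) next
        iva <- iv[[a]]; ivb <- iv[[b]]
        drop <- if (iva < ivb) a else if (ivb < iva) b else max(a, b)
        dropped <- c(dropped, drop)
        log <- rbind(log, data.frame(gene_a = a, gene_b = b, r = pr$r[i],
                                     dropped = drop, stringsAsFactors = FALSE))
      }
      nm <- setdiff(nm, dropped)
    }
  }
  list(kept = nm, log = log)
}

#' Variance inflation factors
#'
#' `VIF_i = 1 / (1 - R_i^2)` where `R_i^2` is the coefficient of
#' determination from the ordinary least-squares regression (with intercept)
#' of encoded gene `i` on all other encoded genes. Computed via QR
#' projections. Exact linear dependence (`R_i^2 = 1` to machine precision)
#' is reported as infinite VIF; a single-gene input has `VIF = 1` by
#' convention.
#'
#' @param x samples x genes matrix of encoded training values, `n >= p + 1`.
#' @return data frame with columns `gene_id`, `r_squared`, `vif`.
#' @export
compute_vif <- function(x) {
  x <- as.matrix(x)
  nm <- colnames(x)
  n <- nrow(x); p <- ncol(x)
  if (n < p + 1L) stop("need at least p + 1 samples for p features")
  if (p == 1L) {
    return(data.frame(gene_id = nm, r_squared = 0, vif = 1,
                      stringsAsFactors = FALSE))
  }
  r2 <- vapply(seq_len(p), function(i) {
    yi <- x[, i]
    tss <- sum((yi - mean(yi))^2)
    if (tss == 0) return(1)               # constant: flagged infinite below
    qr_o <- qr(cbind(1, x[, -i, drop = FALSE]))
    rss <- sum(qr.resid(qr_o, yi)^2)
    max(0, 1 - rss / tss)
  }, numeric(1))
  vif <- ifelse(r2 >= 1 - 1e-10, Inf, 1 / (1 - r2))
  data.frame(gene_id = nm, r_squared = r2, vif = vif, stringsAsFactors = FALSE)
}

#' Iterative VIF collinearity filter
#'
#' While any VIF reaches `threshold`, the gene with the largest VIF is
#' removed (exactly collinear genes, infinite VIF, go first; ties broken
#' lexicographically) and VIFs are recomputed.
#'
#' @param x samples x genes matrix of encoded training values.
#' @param threshold removal threshold (default 10).
#' @return list with `kept`, `records` (final [compute_vif()] table) and
#'   `log` (data frame `gene_id`, `vif` of removals in order).
#' @export
vif_filter <- function(x, threshold = 10) {
  x <- as.matrix(x)
  log <- data.frame(gene_id = character(0), vif = numeric(0),
                    stringsAsFactors = FALSE)
  repeat {
    if (ncol(x) == 0L) break
    rec <- compute_vif(x)
    worst <- max(rec$vif)
    if (worst < threshold) break
    cand <- rec$gene_id[rec$vif == worst]
    victim <- min(cand)
    if (is.infinite(worst)) {
      warning("exact linear dependence: removing gene ", victim)
    }
    log <- rbind(log, data.frame(gene_id = victim, vif = worst,
                                 stringsAsFactors = FALSE))
    x <- x[, setdiff(colnames(x), victim), drop = FALSE]
  }
  list(kept = colnames(x),
       records = if (ncol(x)) compute_vif(x) else
         data.frame(gene_id = character(0), r_squared = numeric(0),
                    vif = numeric(0), stringsAsFactors = FALSE),
       log = log)
}
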