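# Unpenalized logistic regression with Wald statistics, and backward
# stepwise elimination enforcing significance and coefficient sign.

separation_error <- function(feature) {
  stop(structure(class = c("stagesel_separation", "error", "condition"),
                 list(message = paste0(
                   "perfect separation detected (diverging coefficient); ",
                   "remove the separating feature '", feature, "'"),
                   call = NULL, feature = feature)))
}

#' Fit an unpenalized logistic regression with Wald statistics
#'
#' Maximum-likelihood logistic fit with intercept; the positive class is
#' late stage (label 1). Standard errors come from the observed information
#' (the inverse of the weighted cross-product, as in `summary.glm`), Wald
#' `z = beta / se`, and two-sided p-values from the normal reference.
#'
#' @param x samples x features numeric matrix (0 columns allowed for an
#'   intercept-only fit).
#' @param y binary labels (0 early / 1 late).
#' @param check_separation if `TRUE` (default), a perfectly separated fit
#'   (residual deviance numerically zero, diverging coefficients) raises an
#'   error naming the separating feature; the classifier wrapper disables
#'   this to allow saturated fits on resampled folds.
#' @return an `lr_summary` data frame with columns `term`, `estimate`,
#'   `std_error`, `z`, `p_value` (first row the intercept); attributes
#'   `converged` and `n`.
#' @export
fit_logistic <- function(x, y, check_separation = TRUE) {
  y <- as_binary_labels(y)
  x <- as.matrix(x)
  if (nrow(x) == 0L) x <- matrix(numeric(0), nrow = length(y), ncol = 0L)
  if (nrow(x) != length(y)) stop("x and y differ in length")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (ncol(x) >= length(y)) stop("need n > p for an unpenalized fit")
  X <- cbind("(Intercept)" = 1, x)
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  beta <- fit$coefficients
  if (anyNA(beta)) {
    stop("aliased coefficient(s): ", paste(names(beta)[is.na(beta)], collapse = ", "),
         " (exactly collinear features)")
  }
  if (check_separation && ncol(x) > 0L && fit$deviance < 1e-6) {
    scl <- apply(x, 2L, stats::sd)
    scl[scl == 0] <- 1
    separation_error(names(which.max(abs(beta[-1L]) * scl)))
  }
  pcol <- ncol(X)
  covmat <- chol2inv(fit$qr$qr[seq_len(pcol), seq_len(pcol), drop = FALSE])
  se <- sqrt(diag(covmat))
  z <- beta / se
  out <- data.frame(term = colnames(X), estimate = unname(beta),
                    std_error = unname(se), z = unname(z),
                    p_value = unname(2 * stats::pnorm(-abs(z))),
                    stringsAsFactors = FALSE)
  class(out) <- c("lr_summary", "data.frame")
  attr(out, "converged") <- fit$converged
  attr(out, "n") <- length(y)
  out
}

#' Backward stepwise logistic elimination
#'
#' Repeatedly fits the logistic model and removes the single worst offending
#' feature until every remaining feature satisfies both constraints:
#' coefficient `beta < 0` and Wald `p <= p_threshold`. With WOE-oriented
#' features (positive values mark early-enriched bins) and the late stage as
#' the positive class, every informative coefficient should be negative, so
#' a non-negative sign outranks a p-value violation in the removal order;
#' within the same violation class the largest p-value goes first (ties
#' broken lexicographically). Removing `k` features takes exactly `k`
#' refits. If a fit detects perfect separation, the separating feature is
#' removed with reason `"separation"`.
#'
#' @param x samples x features numeric matrix of WOE-encoded training values.
#' @param y binary labels (0 early / 1 late).
#' @param p_threshold maximal Wald p-value retained (default 0.1).
#' @return a `stepwise_fit` list: `selected` (character vector), `summary`
#'   (final [fit_logistic()] table), `trace` (data frame `step`, `gene_id`,
#'   `reason`, `p_value`, `estimate`), and `n_refits`.
#' @export
stepwise_eliminate <- function(x, y, p_threshold = 0.1) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("features must be named")
  trace <- data.frame(step = integer(0), gene_id = character(0),
                      reason = character(0), p_value = numeric(0),
                      estimate = numeric(0), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (ncol(x) == 0L) {
      stop("stepwise elimination removed every feature; trace:\n",
           paste(utils::capture.output(print(trace)), collapse = "\n"))
    }
    s <- tryCatch(fit_logistic(x, y), stagesel_separation = function(e) e)
    if (inherits(s, "stagesel_separation")) {
      victim <- s$feature
      step <- step + 1L
      trace <- rbind(trace, data.frame(step = step, gene_id = victim,
                                       reason = "separation",
                                       p_value = NA_real_,
                                       estimate = NA_real_,
                                       stringsAsFactors = FALSE))
      x <- x[, setdiff(colnames(x), victim), drop = FALSE]
      next
    }
    feats <- s[s$term != "(Intercept)", , drop = FALSE]
    sign_viol <- feats$estimate >= 0
    p_viol <- feats$p_value > p_threshold
    if (!any(sign_viol) && !any(p_viol)) {
      return(structure(list(selected = feats$term, summary = s, trace = trace,
                            n_refits = step), class = "stepwise_fit"))
    }
    pool <- if (any(sign_viol)) feats[sign_viol, , drop = FALSE] else
      feats[p_viol, , drop = FALSE]
    pool <- pool[order(-pool$p_value, pool$term), , drop = FALSE]
    victim <- pool$term[1L]
    step <- step + 1L
    trace <- rbind(trace, data.frame(
      step = step, gene_id = victim,
      reason = if (any(sign_viol)) "sign" else "pvalue",
      p_value = pool$p_value[1L], estimate = pool$estimate[1L],
      stringsAsFactors = FALSE))
    x <- x[, setdiff(colnames(x), victim), drop = FALSE]
  }
}

#' Export a stepwise elimination trace as TSV
#'
#' @param fit a `stepwise_fit`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_elimination_trace <- function(fit, path) {
  utils::write.table(fit$trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
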