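# End-to-end pipeline: split -> FCBF stability selection (raw train) ->
# Chi-merge/WOE fit -> max-bin filter -> IV -> correlation -> VIF ->
# stepwise logistic elimination -> classifier training and evaluation.
# All feature decisions use training data only.

#' Pipeline control parameters
#'
#' Collects every tunable threshold of the selection chain with its default
#' operating value: 80/20 stratified split; FCBF stability selection with 10
#' repeats of 10-fold resampling keeping genes selected in >= 8 repeats;
#' Chi-merge stopped at chi-square 3.841 (0.95 quantile, 1 df) with at most
#' 6 bins of >= 5% of training samples each, from 20 equal-frequency
#' prebins; dominant-bin elimination above a 90% share; IV threshold 0.1;
#' pairwise |r| threshold 0.7; VIF threshold 10; stepwise Wald p threshold
#' 0.1.
#'
#' @param train_fraction training share of the split.
#' @param seed master seed; stage-level seeds are derived from it
#'   deterministically.
#' @param initial_prebins,chi2_stop,max_bins,min_bin_fraction Chi-merge
#'   settings (see [chimerge_fit()]).
#' @param max_bin_share dominant-bin elimination threshold.
#' @param smoothing WOE zero-cell smoothing.
#' @param fcbf_repeats,fcbf_folds,fcbf_min_count,fcbf_rule,fcbf_delta
#'   stability-selection settings (see [stability_select()]).
#' @param iv_threshold,cor_threshold,vif_threshold,p_threshold joint-filter
#'   and stepwise thresholds.
#' @param preprocessing classifier feature scale: `"woe"` (encoded) or
#'   `"log2_zscore"` (per-gene standardized `log2(v + 1)` values of the
#'   selected genes).
#' @param classifiers list of [classifier_spec()]s; default: tuned RBF-SVM,
#'   logistic, MLP, random forest, naive Bayes.
#' @param cv_folds folds for cross-validated metrics and SVM tuning.
#' @return a `stage_control` list.
#' @export
stage_control <- function(train_fraction = 0.8, seed = 1L,
                          initial_prebins = 20L, chi2_stop = 3.841,
                          max_bins = 6L, min_bin_fraction = 0.05,
                          max_bin_share = 0.9, smoothing = 0.5,
                          fcbf_repeats = 10L, fcbf_folds = 10L,
                          fcbf_min_count = 8L,
                          fcbf_rule = c("majority", "union", "intersection"),
                          fcbf_delta = 0,
                          iv_threshold = 0.1, cor_threshold = 0.7,
                          vif_threshold = 10, p_threshold = 0.1,
                          preprocessing = c("woe", "log2_zscore"),
                          classifiers = NULL, cv_folds = 10L) {
  fcbf_rule <- match.arg(fcbf_rule)
  preprocessing <- match.arg(preprocessing)
  stopifnot(train_fraction > 0, train_fraction < 1,
            initial_prebins >= 2, chi2_stop >= 0, max_bins >= 1,
            min_bin_fraction >= 0, min_bin_fraction < 1,
            max_bin_share > 0, max_bin_share <= 1,
            fcbf_repeats >= 1, fcbf_folds >= 1,
            fcbf_min_count <= fcbf_repeats,
            iv_threshold >= 0, cor_threshold > 0, cor_threshold <= 1,
            vif_threshold > 1, p_threshold > 0, p_threshold <= 1,
            cv_folds >= 2)
  if (is.null(classifiers)) {
    classifiers <- lapply(
      c("svm_rbf", "logistic", "mlp", "random_forest", "naive_bayes"),
      classifier_spec, seed = seed)
  }
  structure(as.list(environment()), class = "stage_control")
}

# Shared train/test evaluation harness: tunes (if asked), cross-validates on
# the training features, trains on all training samples, scores the test
# set. Used by stage_fit() and stage_baselines() so a gene-list arm fed the
# pipeline's own output reproduces the main report exactly.
evaluate_arm <- function(x_train, y_train, x_test, y_test, classifiers,
                         cv_folds, seed) {
  rows <- list(); models <- list(); scores <- list(); tuning <- list()
  for (spec in classifiers) {
    alg <- spec$algorithm
    if (alg == "svm_rbf" && isTRUE(spec$tune)) {
      gs <- svm_grid_search(x_train, y_train, spec, k = cv_folds,
                            seed = derive_seed(seed, 11L))
      spec$gamma <- gs$gamma; spec$cost <- gs$cost; spec$tune <- FALSE
      tuning[[alg]] <- gs
    }
    cv <- cross_validate(spec, x_train, y_train, k = cv_folds,
                         seed = derive_seed(seed, 13L))
    model <- train_classifier(spec, x_train, y_train)
    sc <- predict(model, x_test)
    te <- evaluate_scores(sc, y_test, score_type = model$score_type)
    rows[[length(rows) + 1L]] <- data.frame(
      algorithm = alg, method = c("10-fold", "testing"),
      sensitivity = c(cv$mean[["sensitivity"]], te$sensitivity),
      specificity = c(cv$mean[["specificity"]], te$specificity),
      accuracy = c(cv$mean[["accuracy"]], te$accuracy),
      mcc = c(cv$mean[["mcc"]], te$mcc),
      auc = c(cv$mean[["auc"]], te$auc),
      stringsAsFactors = FALSE)
    models[[alg]] <- model
    scores[[alg]] <- sc
  }
  list(metrics = do.call(rbind, rows), models = models,
       test_scores = do.call(cbind, scores), tuning = tuning)
}

#' Fit the stage-prediction pipeline
#'
#' The main entry point: splits the cohort, runs the full training-only
#' selection chain (FCBF stability selection on raw values, Chi-merge/WOE
#' discretization, dominant-bin elimination, information-value screening,
#' pairwise-correlation and VIF redundancy removal, backward stepwise
#' logistic elimination), then trains the configured classifiers on the
#' selected encoded genes and evaluates them by stratified cross-validation
#' on the training set and once on the held-out test set. Every eliminated
#' gene appears exactly once in the provenance table with its eliminating
#' stage; reruns with the same data and control are byte-identical.
#'
#' @param expr genes x samples matrix of raw non-negative abundances.
#' @param labels `stage_labels` (see [derive_stage_labels()]).
#' @param control a [stage_control()].
#' @return a `stage_fit` object; see [print.stage_fit()],
#'   [summary.stage_fit()], [coef.stage_fit()], [predict.stage_fit()],
#'   [plot.stage_fit()], [write_run_report()].
#' @export
stage_fit <- function(expr, labels, control = stage_control()) {
  validate_expression_matrix(expr)
  if (!inherits(labels, "stage_labels")) labels <- derive_stage_labels(labels)
  if (!inherits(control, "stage_control")) stop("control must come from stage_control()")
  seed <- control$seed
  split <- split_train_test(expr, labels, control$train_fraction, seed = seed)
  lab <- stats::setNames(labels$label, labels$sample_id)
  tr_mat <- expr[, split$train, drop = FALSE]
  te_mat <- expr[, split$test, drop = FALSE]
  y_tr <- lab[split$train]; y_te <- lab[split$test]

  genes <- rownames(expr)
  prov <- stats::setNames(rep("kept", length(genes)), genes)
  counts <- c(input = length(genes))
  die <- function(stage, last) {
    stop("stage '", stage, "' removed every gene; last surviving set: ",
         paste(last, collapse = ", "))
  }

  freq <- stability_select(tr_mat, y_tr, repeats = control$fcbf_repeats,
                           folds = control$fcbf_folds,
                           within_repeat_rule = control$fcbf_rule,
                           min_count = control$fcbf_min_count,
                           delta = control$fcbf_delta,
                           seed = derive_seed(seed, 1L))
  kept <- attr(freq, "kept")
  if (!length(kept)) die("fcbf", genes)
  prov[setdiff(genes, kept)] <- "fcbf"
  counts["fcbf"] <- length(kept)

  model <- woe_model_fit(tr_mat, y_tr, genes = kept,
                         smoothing = control$smoothing,
                         initial_prebins = control$initial_prebins,
                         chi2_stop = control$chi2_stop,
                         max_bins = control$max_bins,
                         min_bin_fraction = control$min_bin_fraction)
  ok <- vapply(kept, function(g)
    max_bin_filter(model[[g]]$scheme, control$max_bin_share), logical(1))
  prov[kept[!ok]] <- "max_bin"
  kept2 <- kept[ok]
  if (!length(kept2)) die("max_bin", kept)
  counts["max_bin"] <- length(kept2)

  ivt <- iv_table(model[kept2])
  kept3 <- iv_filter(ivt, control$iv_threshold)$gene_id
  prov[setdiff(kept2, kept3)] <- "iv"
  if (!length(kept3)) die("iv", kept2)
  counts["iv"] <- length(kept3)

  enc_tr <- woe_model_transform(tr_mat, model, kept3)
  iv_vec <- stats::setNames(ivt$iv, ivt$gene_id)
  cf <- correlation_filter(enc_tr, iv_vec, control$cor_threshold)
  kept4 <- intersect(kept3, cf$kept)
  prov[setdiff(kept3, kept4)] <- "correlation"
  if (!length(kept4)) die("correlation", kept3)
  counts["correlation"] <- length(kept4)

  vf <- vif_filter(enc_tr[, kept4, drop = FALSE], control$vif_threshold)
  kept5 <- intersect(kept4, vf$kept)
  prov[setdiff(kept4, kept5)] <- "vif"
  if (!length(kept5)) die("vif", kept4)
  counts["vif"] <- length(kept5)

  sw <- stepwise_eliminate(enc_tr[, kept5, drop = FALSE], y_tr,
                           p_threshold = control$p_threshold)
  final <- sw$selected
  prov[setdiff(kept5, final)] <- "stepwise"
  if (!length(final)) die("stepwise", kept5)
  counts["final"] <- length(final)

  standardization <- NULL
  if (control$preprocessing == "woe") {
    x_train <- enc_tr[, final, drop = FALSE]
    x_test <- woe_model_transform(te_mat, model, final)
  } else {
    standardization <- fit_standardization(tr_mat[final, , drop = FALSE])
    x_train <- t(apply_standardization(tr_mat, standardization))
    x_test <- t(apply_standardization(te_mat, standardization))
  }
  arm <- evaluate_arm(x_train, y_tr, x_test, y_te, control$classifiers,
                      control$cv_folds, seed)

  structure(list(
    selected_genes = final,
    provenance = data.frame(gene_id = genes, stage = unname(prov[genes]),
                            stringsAsFactors = FALSE),
    counts = counts,
    frequency = freq,
    woe_model = model,
    iv = ivt,
    correlation_log = cf$log,
    vif = vf,
    stepwise = sw,
    standardization = standardization,
    classifiers = arm$models,
    tuning = arm$tuning,
    metrics = arm$metrics,
    test_scores = arm$test_scores,
    test_labels = y_te,
    split = split,
    control = control),
    class = "stage_fit")
}

#' @export
print.stage_fit <- function(x, ...) {
  cat("Stage-prediction pipeline fit\n")
  cat("  gene counts along the chain: ",
      paste(names(x$counts), x$counts, sep = "=", collapse = " -> "), "\n")
  cat("  selected genes (", length(x$selected_genes), "): ",
      paste(utils::head(x$selected_genes, 10L), collapse = ", "),
      if (length(x$selected_genes) > 10L) ", ..." else "", "\n", sep = "")
  te <- x$metrics[x$metrics$method == "testing", , drop = FALSE]
  best <- te[which.max(te$auc), ]
  cat(sprintf("  best test AUC: %.3f (%s), accuracy %.2f%%, MCC %.3f\n",
              best$auc, best$algorithm, best$accuracy, best$mcc))
  invisible(x)
}

#' Summarize a fitted pipeline
#'
#' @param object a `stage_fit`.
#' @param ... unused.
#' @return `object`, invisibly; prints the stage chain, the final logistic
#'   model, and the full metrics table.
#' @export
summary.stage_fit <- function(object, ...) {
  print(object)
  cat("\nFinal logistic model (WOE-encoded features):\n")
  print(object$stepwise$summary, digits = 4)
  cat("\nMetrics (10-fold CV on training set / held-out testing):\n")
  print(object$metrics, digits = 3, row.names = FALSE)
  invisible(object)
}

#' Final logistic coefficients of the selection chain
#'
#' @param object a `stage_fit`.
#' @param ... unused.
#' @return named numeric vector (intercept first); all gene coefficients
#'   are negative by construction of the stepwise constraint.
#' @export
coef.stage_fit <- function(object, ...) {
  s <- object$stepwise$summary
  stats::setNames(s$estimate, s$term)
}

#' Score new samples with a fitted pipeline
#'
#' Encodes the selected genes of `newdata` with the training-fitted WOE
#' model (or standardization) and applies a trained classifier.
#'
#' @param object a `stage_fit`.
#' @param newdata genes x samples matrix containing the selected genes.
#' @param classifier which trained classifier to use (default `"svm_rbf"`).
#' @param type `"score"` (continuous) or `"class"` (0/1 at the default
#'   operating point).
#' @param ... unused.
#' @return numeric scores or integer class labels, named by sample.
#' @export
predict.stage_fit <- function(object, newdata, classifier = "svm_rbf",
                              type = c("score", "class"), ...) {
  type <- match.arg(type)
  if (!classifier %in% names(object$classifiers)) {
    stop("no trained classifier '", classifier, "'")
  }
  if (object$control$preprocessing == "woe") {
    x <- woe_model_transform(newdata, object$woe_model, object$selected_genes)
  } else {
    x <- t(apply_standardization(newdata, object$standardization))
  }
  model <- object$classifiers[[classifier]]
  sc <- predict(model, x)
  names(sc) <- colnames(newdata)
  if (type == "score") return(sc)
  thr <- if (model$score_type == "probability") 0.5 else 0
  as.integer(sc >= thr)
}

#' ROC curves of the fitted classifiers on the held-out test set
#'
#' @param x a `stage_fit`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, a list of per-classifier ROC point data frames.
#' @export
plot.stage_fit <- function(x, ...) {
  algs <- colnames(x$test_scores)
  cols <- seq_along(algs) + 1L
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = "Held-out test ROC", ...)
  out <- list()
  for (i in seq_along(algs)) {
    rp <- roc_points(x$test_scores[, i], x$test_labels)
    graphics::lines(rp$fpr, rp$tpr, col = cols[i])
    out[[algs[i]]] <- rp
  }
  auc <- vapply(algs, function(a)
    rank_auc(x$test_scores[, a], x$test_labels), numeric(1))
  graphics::legend("bottomright", bty = "n", col = cols, lty = 1,
                   legend = sprintf("%s (AUC %.3f)", algs, auc))
  invisible(out)
}

#' Baseline comparison arms
#'
#' Applies the same evaluation harness as [stage_fit()] to alternative
#' feature sets: the no-selection arm uses all genes with the log2/z-score
#' standardization path; the gene-list arm evaluates a user-supplied gene
#' set (for instance the pipeline's own output, which then reproduces the
#' main report's metrics exactly) with the preprocessing mode of `control`.
#'
#' @param expr genes x samples raw abundance matrix.
#' @param labels `stage_labels`.
#' @param control a [stage_control()]; the split and seeds are shared with
#'   [stage_fit()] so arms are comparable.
#' @param gene_list optional character vector of gene IDs for the gene-list
#'   arm; must be non-empty and present in `expr` when given.
#' @param classifiers classifier specs for the arms; defaults to an untuned
#'   RBF-SVM (unpenalized logistic cannot be fitted when genes outnumber
#'   samples).
#' @param arms which arms to run; the gene-list arm needs `gene_list`.
#' @return list of per-arm results, each with `metrics`, `models`,
#'   `test_scores`.
#' @export
stage_baselines <- function(expr, labels, control = stage_control(),
                            gene_list = NULL,
                            classifiers = list(classifier_spec("svm_rbf",
                                                               seed = control$seed,
                                                               tune = FALSE)),
                            arms = c("no_selection", "gene_list")) {
  arms <- match.arg(arms, several.ok = TRUE)
  validate_expression_matrix(expr)
  if (!inherits(labels, "stage_labels")) labels <- derive_stage_labels(labels)
  split <- split_train_test(expr, labels, control$train_fraction,
                            seed = control$seed)
  lab <- stats::setNames(labels$label, labels$sample_id)
  tr_mat <- expr[, split$train, drop = FALSE]
  te_mat <- expr[, split$test, drop = FALSE]
  y_tr <- lab[split$train]; y_te <- lab[split$test]
  out <- list()

  if ("no_selection" %in% arms) {
    sp <- fit_standardization(tr_mat)
    out$no_selection <- evaluate_arm(t(apply_standardization(tr_mat, sp)), y_tr,
                                     t(apply_standardization(te_mat, sp)), y_te,
                                     classifiers, control$cv_folds, control$seed)
  }

  if (!is.null(gene_list) && "gene_list" %in% arms) {
    if (!length(gene_list)) stop("gene_list is empty")
    missing <- setdiff(gene_list, rownames(expr))
    if (length(missing)) {
      stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
    }
    if (control$preprocessing == "woe") {
      model <- woe_model_fit(tr_mat, y_tr, genes = gene_list,
                             smoothing = control$smoothing,
                             initial_prebins = control$initial_prebins,
                             chi2_stop = control$chi2_stop,
                             max_bins = control$max_bins,
                             min_bin_fraction = control$min_bin_fraction)
      x_tr <- woe_model_transform(tr_mat, model, gene_list)
      x_te <- woe_model_transform(te_mat, model, gene_list)
    } else {
      sp2 <- fit_standardization(tr_mat[gene_list, , drop = FALSE])
      x_tr <- t(apply_standardization(tr_mat, sp2))
      x_te <- t(apply_standardization(te_mat, sp2))
    }
    out$gene_list <- evaluate_arm(x_tr, y_tr, x_te, y_te, classifiers,
                                  control$cv_folds, control$seed)
  }
  out
}

# Serializable run report (resolved config, seeds, chain counts, selections,
# metrics). Stable across reruns with identical inputs.
report_json <- function(fit) {
  ctl <- fit$control
  ctl$classifiers <- lapply(ctl$classifiers, function(s) {
    s[c("algorithm", "seed", "gamma", "cost", "tune", "size", "decay",
        "maxit", "ntree")]
  })
  doc <- list(
    control = ctl[setdiff(names(ctl), "fcbf_rule_choices")],
    counts = as.list(fit$counts),
    selected_genes = fit$selected_genes,
    provenance = fit$provenance,
    final_model = fit$stepwise$summary,
    metrics = fit$metrics)
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, dataframe = "columns",
                   null = "null", pretty = TRUE)
}

#' Write the run report and audit files
#'
#' Emits, under `dir`: `report.json` (resolved configuration, seeds,
#' per-stage gene counts, selections, final model, metrics),
#' `selection_frequency.tsv`, `filter_report.tsv` (IV, category and the
#' eliminating stage per gene with correlation partners),
#' `elimination_trace.tsv`, `metrics.tsv`, `woe_model.json`, `split.tsv`,
#' and `roc_test.tsv` (test-set ROC points per classifier).
#'
#' @param fit a `stage_fit`.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_run_report <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(report = file.path(dir, "report.json"),
             freq = file.path(dir, "selection_frequency.tsv"),
             filter = file.path(dir, "filter_report.tsv"),
             trace = file.path(dir, "elimination_trace.tsv"),
             metrics = file.path(dir, "metrics.tsv"),
             woe = file.path(dir, "woe_model.json"),
             split = file.path(dir, "split.tsv"),
             roc = file.path(dir, "roc_test.tsv"))
  writeLines(report_json(fit), paths["report"])
  write_selection_frequency(fit$frequency, paths["freq"])

  fr <- merge(fit$provenance, fit$iv, by = "gene_id", all.x = TRUE)
  fr$dropped_by <- ifelse(fr$stage == "kept", "none", fr$stage)
  cl <- fit$correlation_log
  fr$partner <- NA_character_; fr$abs_r <- NA_real_
  if (nrow(cl)) {
    for (i in seq_len(nrow(cl))) {
      d <- cl$dropped[i]
      other <- setdiff(c(cl$gene_a[i], cl$gene_b[i]), d)
      fr$partner[fr$gene_id == d] <- if (length(other)) other else NA_character_
      fr$abs_r[fr$gene_id == d] <- abs(cl$r[i])
    }
  }
  utils::write.table(fr[order(fr$gene_id), ], paths["filter"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_elimination_trace(fit$stepwise, paths["trace"])
  utils::write.table(fit$metrics, paths["metrics"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_woe_model(fit$woe_model, paths["woe"])
  write_split(fit$split, paths["split"])
  rocs <- do.call(rbind, lapply(colnames(fit$test_scores), function(a) {
    rp <- roc_points(fit$test_scores[, a], fit$test_labels)
    cbind(algorithm = a, rp)
  }))
  utils::write.table(rocs, paths["roc"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
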