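# Classifier training, SVM grid search, evaluation metrics, and stratified
# cross-validation. Positive class throughout: late stage (label 1).

#' Classifier specification
#'
#' Describes one of the five supported algorithms plus its hyperparameters.
#' For `svm_rbf` the default tuning grids follow libsvm practice: gamma over
#' `10^{-9, -7, -5, -3, -1, 1, 3}` (literal powers of ten) and cost over
#' `2^{-5, -3, ..., 13, 15}`. MLP, random-forest and naive-Bayes
#' hyperparameters default to the library values recorded here, with a fixed
#' seed for the stochastic trainers.
#'
#' @param algorithm one of `"svm_rbf"`, `"logistic"`, `"mlp"`,
#'   `"random_forest"`, `"naive_bayes"`.
#' @param seed integer seed used by stochastic trainers.
#' @param gamma,cost fixed SVM hyperparameters (used when `tune = FALSE` or
#'   after grid search); `gamma = NULL` means `1/p`.
#' @param gamma_grid,cost_grid SVM tuning grids.
#' @param tune if `TRUE` (default for `svm_rbf`), [svm_grid_search()] picks
#'   `(gamma, cost)` before training.
#' @param size,decay,maxit MLP (single-hidden-layer) settings.
#' @param ntree random-forest tree count.
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(algorithm = c("svm_rbf", "logistic", "mlp",
                                          "random_forest", "naive_bayes"),
                            seed = 1L, gamma = NULL, cost = 1,
                            gamma_grid = 10^seq(-9, 3, by = 2),
                            cost_grid = 2^seq(-5, 15, by = 2),
                            tune = NULL, size = 5L, decay = 0.1,
                            maxit = 500L, ntree = 500L) {
  algorithm <- match.arg(algorithm)
  if (!length(gamma_grid) || !length(cost_grid)) stop("tuning grids must be non-empty")
  if (is.null(tune)) tune <- algorithm == "svm_rbf"
  structure(list(algorithm = algorithm, seed = as.integer(seed),
                 gamma = gamma, cost = cost, gamma_grid = gamma_grid,
                 cost_grid = cost_grid, tune = tune, size = size,
                 decay = decay, maxit = maxit, ntree = ntree),
            class = "classifier_spec")
}

#' Train one classifier
#'
#' Trains the algorithm named by `spec` on the feature matrix. Every model
#' exposes a continuous score for ranking: posterior probability of the late
#' class for `logistic`, `mlp`, `random_forest`, `naive_bayes`
#' (`score_type = "probability"`, operating threshold 0.5), and the signed
#' decision value, oriented so larger means late, for `svm_rbf`
#' (`score_type = "decision"`, threshold 0). Training is deterministic given
#' `spec$seed`.
#'
#' @param spec a [classifier_spec()].
#' @param x samples x features numeric matrix.
#' @param y binary labels (0 early / 1 late), at least 2 samples per class.
#' @return a `stage_classifier`; use [predict.stage_classifier()] for
#'   scores.
#' @export
train_classifier <- function(spec, x, y) {
  if (!inherits(spec, "classifier_spec")) stop("spec must come from classifier_spec()")
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  if (min(table(y)) < 2L || length(unique(y)) < 2L) {
    stop("need at least 2 samples per class")
  }
  yf <- factor(y, levels = c(0L, 1L))
  flip <- 1
  fit <- switch(spec$algorithm,
    svm_rbf = {
      g <- spec$gamma %||% (1 / ncol(x))
      m <- withr::with_seed(spec$seed,
        e1071::svm(x, yf, kernel = "radial", gamma = g, cost = spec$cost,
                   scale = FALSE))
      dv <- attr(stats::predict(m, x, decision.values = TRUE),
                 "decision.values")[, 1L]
      if (mean(dv[y == 1L]) < mean(dv[y == 0L])) flip <- -1
      m
    },
    logistic = fit_logistic(x, y, check_separation = FALSE),
    mlp = withr::with_seed(spec$seed,
      nnet::nnet(x, y, size = spec$size, decay = spec$decay,
                 maxit = spec$maxit, entropy = TRUE, trace = FALSE)),
    random_forest = withr::with_seed(spec$seed,
      randomForest::randomForest(x, yf, ntree = spec$ntree)),
    naive_bayes = e1071::naiveBayes(x, yf))
  structure(list(spec = spec, fit = fit, flip = flip,
                 features = colnames(x),
                 score_type = if (spec$algorithm == "svm_rbf") "decision"
                              else "probability"),
            class = "stage_classifier")
}

#' Score new samples with a trained classifier
#'
#' @param object a `stage_classifier`.
#' @param newdata samples x features matrix with the training feature
#'   columns.
#' @param ... unused.
#' @return numeric score per sample (probability of late, or oriented SVM
#'   decision value).
#' @export
predict.stage_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata)[, object$features, drop = FALSE]
  spec <- object$spec
  switch(spec$algorithm,
    svm_rbf = object$flip *
      attr(stats::predict(object$fit, x, decision.values = TRUE),
           "decision.values")[, 1L],
    logistic = {
      s <- object$fit
      eta <- drop(cbind(1, x) %*% s$estimate)
      stats::plogis(eta)
    },
    mlp = drop(stats::predict(object$fit, x)),
    random_forest = stats::predict(object$fit, x, type = "prob")[, "1"],
    naive_bayes = stats::predict(object$fit, x, type = "raw")[, "1"])
}

#' Grid search for the RBF-SVM hyperparameters
#'
#' Evaluates every `(gamma, cost)` pair of the spec's grids by stratified
#' k-fold cross-validated accuracy (the same seeded folds for every
#' candidate) and returns the pair with the highest mean accuracy; ties are
#' broken toward the smaller cost, then the smaller gamma.
#'
#' @param x samples x features matrix.
#' @param y binary labels.
#' @param spec a [classifier_spec()] for `svm_rbf`.
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed.
#' @return list with `gamma`, `cost`, and `cv_table` (data frame `gamma`,
#'   `cost`, `accuracy` for all candidates).
#' @export
svm_grid_search <- function(x, y, spec = classifier_spec("svm_rbf"),
                            k = 10L, seed = 1L) {
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  fold <- withr::with_seed(seed, make_folds(y, k))
  grid <- expand.grid(gamma = spec$gamma_grid, cost = spec$cost_grid,
                      KEEP.OUT.ATTRS = FALSE)
  yf <- factor(y, levels = c(0L, 1L))
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    correct <- 0L
    for (f in sort(unique(fold))) {
      tr <- fold != f
      m <- e1071::svm(x[tr, , drop = FALSE], yf[tr], kernel = "radial",
                      gamma = grid$gamma[i], cost = grid$cost[i],
                      scale = FALSE)
      pred <- stats::predict(m, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == yf[!tr])
    }
    correct / length(y)
  }, numeric(1))
  grid$accuracy <- acc
  best <- grid[order(-grid$accuracy, grid$cost, grid$gamma), ][1L, ]
  list(gamma = best$gamma, cost = best$cost, cv_table = grid)
}

#' Confusion-matrix metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy (percent)
#' `100 (TP+TN)/N`, and the Matthews correlation coefficient
#' \deqn{MCC = \frac{TP\,TN - FP\,FN}
#'  {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' (0 when the denominator vanishes, i.e. a constant predictor).
#'
#' @param tp,fp,tn,fn non-negative integer confusion-matrix cells; positive
#'   class = late stage.
#' @return list with `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `accuracy` (percent), `mcc`.
#' @export
metrics_from_confusion <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       accuracy = 100 * (tp + tn) / n, mcc = mcc)
}

# Rank (Mann-Whitney) AUC; ties get average ranks, equivalent to the
# trapezoidal area under the ROC curve over all score thresholds.
rank_auc <- function(scores, y) {
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate classifier scores on one sample set
#'
#' Thresholds the scores into a confusion matrix (probability scale: predict
#' late when `score >= 0.5`; decision scale: `score >= 0`) and computes the
#' five headline metrics; AUC is the rank statistic over all thresholds and
#' needs both classes present.
#'
#' @param scores numeric scores, larger = more late-like.
#' @param labels binary labels (0 early / 1 late).
#' @param threshold operating point; default 0.5 for probabilities, 0 for
#'   decision values.
#' @param score_type `"probability"` or `"decision"`.
#' @return an `eval_metrics` list: confusion cells plus `sensitivity`,
#'   `specificity`, `accuracy` (percent), `mcc`, `auc`.
#' @export
evaluate_scores <- function(scores, labels, threshold = NULL,
                            score_type = c("probability", "decision")) {
  score_type <- match.arg(score_type)
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  if (length(unique(y)) < 2L) stop("AUC undefined: only one class present")
  if (is.null(threshold)) threshold <- if (score_type == "probability") 0.5 else 0
  pred <- as.integer(scores >= threshold)
  m <- metrics_from_confusion(tp = sum(pred == 1L & y == 1L),
                              fp = sum(pred == 1L & y == 0L),
                              tn = sum(pred == 0L & y == 0L),
                              fn = sum(pred == 0L & y == 1L))
  m$auc <- rank_auc(scores, y)
  class(m) <- "eval_metrics"
  m
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("confusion (late positive): TP %d  FP %d  TN %d  FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("sensitivity %.3f  specificity %.3f  accuracy %.2f%%  MCC %.3f%s\n",
              x$sensitivity, x$specificity, x$accuracy, x$mcc,
              if (!is.null(x$auc)) sprintf("  AUC %.3f", x$auc) else ""))
  invisible(x)
}

#' Stratified k-fold cross-validation of one classifier
#'
#' Splits the samples into `k` stratified folds (seeded), trains a fresh
#' model on each fold's complement, evaluates on the fold, and averages the
#' metrics arithmetically across folds.
#'
#' @param spec a [classifier_spec()] with fixed hyperparameters.
#' @param x samples x features matrix.
#' @param y binary labels.
#' @param k folds (default 10); every fold must contain both classes.
#' @param seed fold-assignment seed.
#' @return list with `mean` (named numeric vector of averaged metrics) and
#'   `folds` (per-fold data frame).
#' @export
cross_validate <- function(spec, x, y, k = 10L, seed = 1L) {
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  fold <- withr::with_seed(seed, make_folds(y, k))
  rows <- lapply(sort(unique(fold)), function(f) {
    tr <- fold != f
    if (length(unique(y[!tr])) < 2L) {
      stop("fold ", f, " contains a single class; use a smaller k")
    }
    model <- train_classifier(spec, x[tr, , drop = FALSE], y[tr])
    sc <- predict(model, x[!tr, , drop = FALSE])
    m <- evaluate_scores(sc, y[!tr], score_type = model$score_type)
    data.frame(fold = f, sensitivity = m$sensitivity,
               specificity = m$specificity, accuracy = m$accuracy,
               mcc = m$mcc, auc = m$auc)
  })
  tab <- do.call(rbind, rows)
  list(mean = colMeans(tab[, -1L]), folds = tab)
}

#' ROC curve points
#'
#' False/true positive rates over all score thresholds, for plotting or
#' export.
#'
#' @param scores numeric scores (larger = more late-like).
#' @param labels binary labels.
#' @return data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  y <- as_binary_labels(labels)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  tpr <- cumsum(ys == 1L) / sum(y == 1L)
  fpr <- cumsum(ys == 0L) / sum(y == 0L)
  keep <- !duplicated(ss, fromLast = TRUE)    # collapse tied scores
  data.frame(threshold = c(Inf, ss[keep]),
             fpr = c(0, fpr[keep]),
             tpr = c(0, tpr[keep]))
}
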