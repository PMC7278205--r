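# Classifier training, grid search, metrics, cross-validation.

toy_separable <- function() {
  x <- cbind(f1 = c(0, 0.5, 10, 10.5, 0.2, 10.2),
             f2 = c(0, 0.4, 10, 10.4, 0.3, 10.1))
  y <- c(0L, 0L, 1L, 1L, 0L, 1L)
  list(x = x, y = y)
}

test_that("every algorithm separates a trivially separable toy", {
  toy <- toy_separable()
  for (alg in c("svm_rbf", "logistic", "mlp", "random_forest", "naive_bayes")) {
    spec <- classifier_spec(alg, seed = 3L, tune = FALSE, gamma = 0.5,
                            cost = 10)
    m <- train_classifier(spec, toy$x, toy$y)
    sc <- predict(m, toy$x)
    em <- evaluate_scores(sc, toy$y, score_type = m$score_type)
    expect_equal(em$accuracy, 100, info = alg)
  }
  expect_error(classifier_spec("boosted_stump"))
  expect_error(train_classifier(classifier_spec("logistic"),
                                toy$x, rep(1L, 6)), "class")
})

test_that("training is deterministic for a fixed seed", {
  set.seed(71)
  x <- matrix(rnorm(600), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(200, 1, plogis(x[, 1]))
  for (alg in c("mlp", "random_forest", "svm_rbf")) {
    spec <- classifier_spec(alg, seed = 17L, tune = FALSE)
    s1 <- predict(train_classifier(spec, x, y), x)
    s2 <- predict(train_classifier(spec, x, y), x)
    expect_identical(s1, s2, info = alg)
  }
})

test_that("the logistic classifier reproduces fit_logistic coefficients", {
  set.seed(72)
  x <- matrix(rnorm(400), ncol = 2, dimnames = list(NULL, c("gA", "gB")))
  y <- rbinom(200, 1, plogis(-x[, 1] + 0.5 * x[, 2]))
  m <- train_classifier(classifier_spec("logistic"), x, y)
  expect_equal(m$fit$estimate, fit_logistic(x, y)$estimate, tolerance = 1e-10)
  # predicted probabilities follow the fitted linear predictor
  sc <- predict(m, x)
  eta <- cbind(1, x) %*% m$fit$estimate
  expect_equal(unname(sc), unname(plogis(drop(eta))), tolerance = 1e-12)
})

test_that("SVM grid search enumerates the full grid and honours the argmax contract", {
  spec <- classifier_spec("svm_rbf")
  expect_equal(length(spec$gamma_grid) * length(spec$cost_grid), 77L)

  set.seed(73)
  x <- matrix(rnorm(300), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(150, 1, plogis(2 * x[, 1]))
  small <- classifier_spec("svm_rbf", gamma_grid = c(0.01, 0.5),
                           cost_grid = c(0.5, 1, 8))
  gs <- svm_grid_search(x, y, small, k = 4, seed = 2)
  expect_equal(nrow(gs$cv_table), 6L)
  best_acc <- gs$cv_table$accuracy[gs$cv_table$gamma == gs$gamma &
                                     gs$cv_table$cost == gs$cost]
  expect_true(all(gs$cv_table$accuracy <= best_acc))
  # single-candidate grid returns that candidate
  one <- classifier_spec("svm_rbf", gamma_grid = 0.2, cost_grid = 4)
  gs1 <- svm_grid_search(x, y, one, k = 3, seed = 2)
  expect_equal(c(gs1$gamma, gs1$cost), c(0.2, 4))
})

test_that("evaluation metrics are exact on canonical cases", {
  # perfect scores
  y <- rep(0:1, each = 10)
  em <- evaluate_scores(c(rep(0.1, 10), rep(0.9, 10)), y)
  expect_equal(em$mcc, 1); expect_equal(em$auc, 1)
  expect_equal(em$accuracy, 100)
  # constant predictor has MCC 0
  expect_equal(evaluate_scores(rep(0.7, 20), y)$mcc, 0)
  # random scores approach AUC 0.5
  set.seed(74)
  yr <- rbinom(10000, 1, 0.4)
  expect_equal(evaluate_scores(runif(10000), yr)$auc, 0.5, tolerance = 0.02)
  # stored cells always reproduce the stored rates
  em2 <- evaluate_scores(runif(200), rbinom(200, 1, 0.5))
  re <- metrics_from_confusion(em2$tp, em2$fp, em2$tn, em2$fn)
  expect_identical(re$accuracy, em2$accuracy)
  expect_identical(re$mcc, em2$mcc)
  expect_error(evaluate_scores(runif(5), rep(1, 5)), "one class")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(75)
  y <- rbinom(300, 1, 0.4)
  sc <- rnorm(300) + y
  a0 <- evaluate_scores(sc, y, score_type = "decision")$auc
  expect_equal(evaluate_scores(exp(sc), y, threshold = 0)$auc, a0)
  expect_equal(evaluate_scores(plogis(3 * sc), y)$auc, a0)
  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(a0, ref, tolerance = 1e-12)
  }
})

test_that("cross-validation partitions exactly once and averages per-fold metrics", {
  set.seed(76)
  x <- matrix(rnorm(600), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(200, 1, plogis(1.5 * x[, 1]))
  cv <- cross_validate(classifier_spec("logistic"), x, y, k = 5, seed = 4)
  expect_equal(nrow(cv$folds), 5L)
  expect_equal(cv$mean[["accuracy"]], mean(cv$folds$accuracy))
  expect_equal(cv$mean[["auc"]], mean(cv$folds$auc))
  cv2 <- cross_validate(classifier_spec("logistic"), x, y, k = 5, seed = 4)
  expect_identical(cv, cv2)
  # a fold holding a whole class is rejected
  y_rare <- c(rep(0L, 196), rep(1L, 4))
  expect_error(cross_validate(classifier_spec("logistic"), x, y_rare,
                              k = 8, seed = 1), "class")
})

test_that("ROC points trace the empirical curve", {
  y <- c(0, 0, 1, 1)
  rp <- roc_points(c(0.1, 0.4, 0.35, 0.8), y)
  expect_equal(rp$fpr[1], 0); expect_equal(rp$tpr[1], 0)
  expect_equal(rp$fpr[nrow(rp)], 1); expect_equal(rp$tpr[nrow(rp)], 1)
  expect_true(all(diff(rp$fpr) >= 0) && all(diff(rp$tpr) >= 0))
})
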