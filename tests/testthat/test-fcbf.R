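# Symmetric uncertainty, MDL discretization, FCBF, stability selection.

test_that("symmetric uncertainty matches entropy arithmetic and its bounds", {
  x <- c(1, 1, 2, 2, 1, 2)
  expect_equal(symmetric_uncertainty(x, x), 1)
  # exactly independent by construction (full product design)
  xi <- rep(1:2, each = 2); yi <- rep(1:2, 2)
  expect_equal(symmetric_uncertainty(xi, yi), 0)
  # 2x2 joint counts [[2,1],[1,2]] against direct entropy arithmetic
  xj <- c(1, 1, 1, 2, 2, 2); yj <- c(1, 1, 2, 1, 2, 2)
  expect_equal(symmetric_uncertainty(xj, yj), oracle_su(xj, yj),
               tolerance = 1e-9)
  expect_error(symmetric_uncertainty(1:3, 1:4), "length")
  # symmetry and [0,1] bounds on random vectors
  set.seed(41)
  for (i in 1:50) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    su <- symmetric_uncertainty(a, b)
    expect_equal(su, symmetric_uncertainty(b, a), tolerance = 1e-12)
    expect_gte(su, 0); expect_lte(su, 1)
    expect_equal(su, oracle_su(a, b), tolerance = 1e-9)
  }
  # both constant -> defined as 0
  expect_equal(symmetric_uncertainty(rep(1, 5), rep(2, 5)), 0)
})

test_that("MDL discretization accepts a clean boundary and rejects noise", {
  # perfectly separating threshold -> exactly one cut at the boundary
  d <- mdl_discretize(1:10, rep(0:1, each = 5))
  expect_equal(attr(d, "cuts"), 5.5)
  expect_equal(as.integer(d), rep(1:2, each = 5))
  # labels independent of values -> no accepted cut
  set.seed(42)
  d0 <- mdl_discretize(rnorm(60), sample(0:1, 60, replace = TRUE))
  expect_length(attr(d0, "cuts"), 0)
})

test_that("MDL discretization equals the naive recursive-split oracle", {
  set.seed(43)
  for (i in 1:60) {
    inst <- random_small_instance(n_max = 30L, v_max = 10L)
    mine <- attr(mdl_discretize(inst$values, inst$labels), "cuts")
    ref <- oracle_mdlp_cuts(inst$values, inst$labels)
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("FCBF keeps predominant features and removes redundant copies", {
  set.seed(44)
  y <- sample(0:1, 60, replace = TRUE)
  x <- data.frame(f1 = y, f2 = y, f3 = sample(1:3, 60, replace = TRUE))
  sel <- fcbf(x, y)
  expect_identical(as.character(sel), "f1")   # copy removed, noise irrelevant

  # constant features carry zero relevance; strict > delta gives empty set
  x0 <- data.frame(a = rep(1, 20), b = rep(2, 20))
  expect_length(fcbf(x0, rep(0:1, 10)), 0)
})

test_that("mutually independent relevant features are all kept", {
  set.seed(45)
  n <- 400
  f1 <- sample(1:2, n, replace = TRUE)
  f2 <- sample(1:2, n, replace = TRUE)
  # class depends on both features; f1 and f2 stay marginally independent
  y <- as.integer(runif(n) < plogis(1.5 * (f1 - 1.5) + 1.5 * (f2 - 1.5)))
  x <- data.frame(f1 = f1, f2 = f2)
  su_c <- c(oracle_su(f1, y), oracle_su(f2, y))
  su_ff <- oracle_su(f1, f2)
  expect_true(all(su_ff < su_c))      # precondition of the example
  expect_setequal(as.character(fcbf(x, y)), c("f1", "f2"))
})

test_that("FCBF equals the brute-force predominance oracle and ignores column order", {
  set.seed(46)
  for (i in 1:40) {
    inst <- random_fcbf_instance()
    mine <- as.character(fcbf(inst$x, inst$y))
    ref <- oracle_fcbf(inst$x, inst$y)
    expect_identical(mine, ref)
    # column order must not matter
    perm <- sample(ncol(inst$x))
    expect_identical(as.character(fcbf(inst$x[, perm, drop = FALSE], inst$y)),
                     mine)
    # no kept feature is predominated by another kept feature
    if (length(mine) > 1) {
      su_c <- vapply(inst$x[mine], function(col) oracle_su(col, inst$y),
                     numeric(1))
      for (a in mine) for (b in setdiff(mine, a)) {
        expect_lt(oracle_su(inst$x[[a]], inst$x[[b]]), su_c[[b]])
      }
    }
  }
})

test_that("stability selection recovers a planted gene and is reproducible", {
  co <- generate_cohort(cohort_config(
    n_samples = 300L, n_noise = 50L, n_informative = 1L,
    n_redundant_per_informative = 0L, effect_shift = 2.0, seed = 9L))
  y <- co$labels$label
  planted <- co$truth$gene_id[co$truth$role == "informative"]
  fr <- stability_select(co$expression, y, repeats = 10L, folds = 10L,
                         min_count = 8L, seed = 12L)
  expect_equal(fr$count[fr$gene_id == planted], 10L)
  expect_true(planted %in% attr(fr, "kept"))
  expect_lte(max(fr$count), attr(fr, "repeats"))
  # bit-for-bit reproducible
  fr2 <- stability_select(co$expression, y, repeats = 10L, folds = 10L,
                          min_count = 8L, seed = 12L)
  expect_identical(fr, fr2)
  # min_count = 0 keeps exactly the genes ever selected
  fr0 <- stability_select(co$expression, y, repeats = 3L, folds = 2L,
                          min_count = 0L, seed = 12L)
  expect_setequal(attr(fr0, "kept"), fr0$gene_id[fr0$count > 0])
  expect_error(stability_select(co$expression, y, repeats = 3L,
                                min_count = 5L), "min_count")
})

test_that("one repeat with one fold degenerates to a single FCBF run", {
  co <- generate_cohort(cohort_config(
    n_samples = 120L, n_noise = 20L, n_informative = 2L,
    n_redundant_per_informative = 0L, effect_shift = 2.0, seed = 13L))
  y <- co$labels$label
  fr <- stability_select(co$expression, y, repeats = 1L, folds = 1L,
                         min_count = 1L, seed = 5L)
  # reference: discretize every gene on the full data, then one fcbf pass
  disc <- as.data.frame(lapply(rownames(co$expression), function(g)
    as.integer(mdl_discretize(co$expression[g, ], y))))
  names(disc) <- rownames(co$expression)
  ref <- as.character(fcbf(disc, y))
  expect_setequal(attr(fr, "kept"), ref)
})
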