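# Information value, correlation redundancy filter, VIF screening.

test_that("information value matches hand arithmetic and categorizes correctly", {
  # single bin: no discrimination possible
  tab <- table_to_vectors(list(Ei = 30, Li = 20))
  wt <- woe_fit(tab$bins, tab$labels, n_bins = 1L)
  expect_warning(r <- information_value(wt), "single-bin")
  expect_equal(r$iv, 0)
  expect_equal(r$category, "unpredictive")

  # early (30,20) of 50, late (10,40) of 50 -> 0.4 ln3 + 0.4 ln2
  tab <- table_to_vectors(list(Ei = c(30, 20), Li = c(10, 40)))
  wt <- woe_fit(tab$bins, tab$labels)
  r <- information_value(wt)
  expect_equal(r$iv, 0.4 * log(3) + 0.4 * log(2), tolerance = 1e-12)
  expect_equal(r$category, "strong")
  expect_equal(r$iv, sum(r$contributions))
})

test_that("IV is non-negative, permutation-invariant, and matches the definition", {
  set.seed(51)
  for (i in 1:100) {
    tab <- random_count_table(zero_cells = i %% 3 == 0)
    v <- table_to_vectors(tab)
    wt <- woe_fit(v$bins, v$labels, n_bins = v$k)
    r <- information_value(wt)
    expect_equal(r$iv, oracle_iv(tab$Ei, tab$Li), tolerance = 1e-9)
    expect_gte(r$iv, -1e-12)
    expect_true(all(r$contributions >= -1e-12))
    # invariant under bin relabeling
    perm <- sample(v$k)
    vp <- list(bins = perm[v$bins], labels = v$labels)
    rp <- information_value(woe_fit(vp$bins, vp$labels, n_bins = v$k))
    expect_equal(rp$iv, r$iv, tolerance = 1e-12)
  }
})

test_that("IV filter keeps scores at or above threshold, sorted descending", {
  df <- data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                   iv = c(0.455, 0.09, 0.1, 0.02))
  out <- iv_filter(df, threshold = 0.1)
  expect_identical(out$gene_id, c("gA", "gC"))   # 0.455 kept, exact 0.1 kept
  expect_false("gB" %in% out$gene_id)            # 0.09 rejected
  empty <- iv_filter(df[0, ], threshold = 0.1)
  expect_equal(nrow(empty), 0)
})

test_that("category boundaries follow the 0.02 / 0.10 / 0.30 convention", {
  categorize <- function(iv_target) {
    # build a two-bin table and scale the mix until IV ~ target
    f <- function(d) {
      Ei <- c(50 + d, 50 - d); Li <- c(50 - d, 50 + d)
      oracle_iv(Ei, Li) - iv_target
    }
    d <- stats::uniroot(f, c(0.1, 49))$root
    tab <- table_to_vectors(list(Ei = round(c(50 + d, 50 - d)),
                                 Li = round(c(50 - d, 50 + d))))
    information_value(woe_fit(tab$bins, tab$labels))$category
  }
  expect_equal(categorize(0.05), "weak")
  expect_equal(categorize(0.2), "moderate")
  expect_equal(categorize(0.5), "strong")
})

test_that("correlation filter drops the lower-IV member of violating pairs", {
  set.seed(52)
  n <- 300
  z <- rnorm(n); w <- rnorm(n); u <- rnorm(n)
  g2 <- z
  g1 <- 0.95 * z + sqrt(1 - 0.95^2) * w            # r(g1,g2) ~ 0.95
  g3 <- 0.8 * z - 0.36 * w + 0.48 * u              # r(g2,g3) ~ 0.8, r(g1,g3) ~ 0.65
  g4 <- rnorm(n)                                   # uninvolved
  x <- cbind(g1 = g1, g2 = g2, g3 = g3, g4 = g4)
  cm <- abs(stats::cor(x))
  # preconditions of the worked trace
  expect_gt(cm["g1", "g2"], 0.9); expect_gt(cm["g2", "g3"], 0.7)
  expect_lt(cm["g1", "g3"], 0.7); expect_true(all(cm["g4", 1:3] < 0.7))
  iv <- c(g1 = 0.5, g2 = 0.4, g3 = 0.3, g4 = 0.15)
  out <- correlation_filter(x, iv, threshold = 0.7)
  # g1~g2 resolved first (larger |r|): g2 dropped and its g3 pair discarded
  expect_setequal(out$kept, c("g1", "g3", "g4"))
  expect_identical(out$log$dropped, "g2")

  # a pair below threshold keeps both members
  out2 <- correlation_filter(x[, c("g1", "g4")], iv, threshold = 0.7)
  expect_setequal(out2$kept, c("g1", "g4"))

  # constant encoded gene is dropped with a warning
  xc <- cbind(x[, 1:2], gK = rep(1, n))
  expect_warning(out3 <- correlation_filter(xc, c(iv, gK = 0.2)), "constant")
  expect_false("gK" %in% out3$kept)
})

test_that("VIF matches closed forms and the lm oracle", {
  # orthogonal features -> all VIF = 1
  x <- cbind(a = c(1, 1, -1, -1, 1, 1, -1, -1),
             b = c(1, -1, 1, -1, 1, -1, 1, -1),
             c = c(1, 1, 1, 1, -1, -1, -1, -1))
  expect_equal(compute_vif(x)$vif, rep(1, 3), tolerance = 1e-12)

  # two features: VIF = 1 / (1 - r^2)
  set.seed(53)
  for (r_target in c(-0.9, -0.4, 0.3, 0.7)) {
    n <- 400
    a <- rnorm(n)
    b <- r_target * a + sqrt(1 - r_target^2) * rnorm(n)
    x2 <- cbind(g1 = a, g2 = b)
    r_emp <- stats::cor(a, b)
    expect_equal(compute_vif(x2)$vif, rep(1 / (1 - r_emp^2), 2),
                 tolerance = 1e-9)
  }

  # random matrices against lm-based R^2
  for (i in 1:20) {
    n <- 60; p <- sample(3:6, 1)
    xr <- matrix(rnorm(n * p), n, p,
                 dimnames = list(NULL, sprintf("v%d", 1:p)))
    xr[, 2] <- xr[, 1] * 0.6 + rnorm(n) * 0.5
    expect_equal(compute_vif(xr)$vif, oracle_vif(xr), tolerance = 1e-9)
  }
})

test_that("exactly collinear features get infinite VIF and one is removed", {
  set.seed(54)
  a <- rnorm(50); b <- rnorm(50)
  x <- cbind(g1 = a, g2 = a, g3 = b)
  v <- compute_vif(x)
  expect_true(all(is.infinite(v$vif[1:2])))
  expect_warning(out <- vif_filter(x, threshold = 10), "linear dependence")
  expect_setequal(out$kept, c("g2", "g3"))   # lexicographically first removed
  expect_true(all(out$records$vif < 10))
  # independent features pass untouched
  x2 <- cbind(g1 = a, g3 = b)
  out2 <- vif_filter(x2, threshold = 10)
  expect_setequal(out2$kept, c("g1", "g3"))
  expect_equal(nrow(out2$log), 0)
})
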