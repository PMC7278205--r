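# Expression I/O, stage labeling, splitting, standardization.

test_that("expression TSV round-trips and decodes log2 storage", {
  m <- matrix(c(0, 1.5, 7, 1234.5678, 0.001, 42), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, f)
  m2 <- read_expression_matrix(f)
  expect_identical(dimnames(m2), dimnames(m))
  expect_equal(m2, m, tolerance = 1e-12)

  # stored log2(raw + 1) values are inverted on read: 3.0 -> 2^3 - 1 = 7
  mlog <- matrix(c(3, 0), nrow = 1, dimnames = list("gA", c("s1", "s2")))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(gene_id = "gA", s1 = 3, s2 = 0),
                     f2, sep = "\t", quote = FALSE, row.names = FALSE)
  m3 <- read_expression_matrix(f2, already_log2 = TRUE)
  expect_equal(unname(m3[1, ]), c(7, 0))
})

test_that("malformed and invalid expression input is rejected by name", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\t2", "gB\t3"), f)
  expect_error(read_expression_matrix(f), "line 3")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "gDup\t1", "gDup\t2"), f2)
  expect_error(read_expression_matrix(f2), "gDup")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "gA\t-3"), f3)
  expect_error(read_expression_matrix(f3), "negative")
})

test_that("stage strings map to the binary early/late target", {
  clin <- data.frame(
    sample_id = c("a", "b", "c", "d", "e"),
    pathologic_stage = c("Stage II", "Stage IV", "stage iii",
                         "  Stage I ", "[Discrepancy]"))
  lab <- derive_stage_labels(clin)
  expect_equal(lab$label[match(c("a", "b", "c", "d"), lab$sample_id)],
               c(0L, 1L, 1L, 0L))
  expect_identical(attr(lab, "excluded"), "e")
  expect_error(derive_stage_labels(
    data.frame(sample_id = "x", pathologic_stage = "unknown")), "no sample")
})

test_that("stratified split reproduces per-stage 80/20 counts", {
  # stratum sizes of a 604-sample cohort: 293/68/139/104 across stages I-IV
  sizes <- c("Stage I" = 293, "Stage II" = 68, "Stage III" = 139,
             "Stage IV" = 104)
  clin <- data.frame(
    sample_id = sprintf("s%03d", seq_len(sum(sizes))),
    pathologic_stage = rep(names(sizes), sizes))
  lab <- derive_stage_labels(clin)
  m <- matrix(1, nrow = 2, ncol = sum(sizes),
              dimnames = list(c("g1", "g2"), clin$sample_id))
  sp <- split_train_test(m, lab, train_fraction = 0.8, seed = 5)
  expect_length(sp$train, 482)
  expect_length(sp$test, 122)
  stage_of <- stats::setNames(lab$stage, lab$sample_id)
  expect_equal(unname(table(stage_of[sp$train])[names(sizes)]),
               c(234L, 54L, 111L, 83L), ignore_attr = TRUE)
  # disjoint and exhaustive
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), clin$sample_id)
  # deterministic given seed
  sp2 <- split_train_test(m, lab, train_fraction = 0.8, seed = 5)
  expect_identical(sp[c("train", "test")], sp2[c("train", "test")])
})

test_that("balanced half-split preserves classes and round-trips to disk", {
  clin <- data.frame(sample_id = letters[1:10],
                     pathologic_stage = rep(c("Stage I", "Stage III"), 5))
  lab <- derive_stage_labels(clin)
  m <- matrix(1, 1, 10, dimnames = list("g", letters[1:10]))
  sp <- split_train_test(m, lab, train_fraction = 0.5, seed = 3)
  expect_length(sp$train, 5)
  y <- stats::setNames(lab$label, lab$sample_id)
  expect_setequal(unique(y[sp$train]), 0:1)
  expect_setequal(unique(y[sp$test]), 0:1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_split(sp, f)
  sp2 <- read_split(f)
  expect_setequal(sp2$train, sp$train)
  expect_setequal(sp2$test, sp$test)
})

test_that("log2/z-score standardization is fitted on training data only", {
  set.seed(9)
  tr <- matrix(rexp(300, 1 / 50), nrow = 10,
               dimnames = list(sprintf("g%02d", 1:10), sprintf("t%02d", 1:30)))
  tr[3, ] <- 5  # constant gene
  params <- fit_standardization(tr)
  expect_true(params$constant[3])
  z <- apply_standardization(tr, params)
  expect_equal(unname(rowMeans(z)), rep(0, 10), tolerance = 1e-9)
  expect_equal(unname(apply(z[-3, ], 1, sd)), rep(1, 9), tolerance = 1e-9)
  expect_equal(unname(z[3, ]), rep(0, 30))

  # raw 0 maps to log2(1) = 0; raw 7 maps to log2(8) = 3
  expect_equal(log2(0 + 1), 0)
  one <- matrix(7, 1, 1, dimnames = list("g01", "x1"))
  p1 <- list(gene_ids = "g01", mean = c(g01 = 3), sd = c(g01 = 1),
             constant = FALSE)
  class(p1) <- "standardization_params"
  expect_equal(unname(apply_standardization(one, p1)[1, 1]), 0)

  # mutating held-out values never changes the fitted parameters
  te <- matrix(rexp(50, 1 / 50), nrow = 10,
               dimnames = list(rownames(tr), sprintf("h%02d", 1:5)))
  z1 <- apply_standardization(te, params)
  params2 <- fit_standardization(tr)   # refit after "seeing" mutated test data
  expect_identical(params, params2)
  expect_equal(apply_standardization(te, params2), z1)
})
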