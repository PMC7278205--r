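# Expression-matrix I/O, stage labeling, train/test splitting, and the
# log2 / z-score standardization path.

#' Read a gene-expression matrix from TSV
#'
#' Reads a genes-in-rows tab-separated table (UCSC Xena dialect: first column
#' gene IDs, header row sample IDs) into a numeric matrix with gene IDs as row
#' names and sample IDs as column names. The canonical internal scale is raw
#' abundance (RSEM/FPKM-like, non-negative); matrices distributed as
#' `log2(x + 1)` are inverted on read via `already_log2 = TRUE`.
#'
#' @param path path to the TSV file.
#' @param already_log2 if `TRUE`, stored values `v` are interpreted as
#'   `log2(raw + 1)` and converted back to raw abundance `2^v - 1`.
#' @param genes_in_rows if `FALSE`, the file is samples-in-rows (first column
#'   sample IDs, header gene IDs) and is transposed on read.
#' @return numeric matrix, genes x samples, all values finite and `>= 0`.
#' @export
read_expression_matrix <- function(path, already_log2 = FALSE,
                                   genes_in_rows = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("malformed TSV '%s': line %d has %d fields, expected %d",
                 path, bad, nf[bad], nf[1L]))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs an ID column plus >= 1 value column")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!genes_in_rows) m <- t(m)
  if (already_log2) m <- 2^m - 1
  validate_expression_matrix(m)
  m
}

#' Write a gene-expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; values are written with full double
#' precision so that a read/write round trip reproduces the matrix to 1e-12.
#'
#' @param mat genes x samples numeric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  validate_expression_matrix(mat)
  df <- data.frame(gene_id = rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate expression-matrix invariants
#'
#' Checks that `mat` is a numeric genes x samples matrix with unique gene and
#' sample IDs and finite, non-negative values. Called by every consumer of an
#' expression matrix; errors name the offending ID.
#'
#' @param mat candidate matrix.
#' @return `mat`, invisibly.
#' @export
validate_expression_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop("expression data must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("expression matrix needs gene IDs as row names and sample IDs as column names")
  }
  dup <- unique(rownames(mat)[duplicated(rownames(mat))])
  if (length(dup)) stop("duplicated gene ID(s): ", paste(dup, collapse = ", "))
  dup <- unique(colnames(mat)[duplicated(colnames(mat))])
  if (length(dup)) stop("duplicated sample ID(s): ", paste(dup, collapse = ", "))
  if (any(!is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value for gene '%s', sample '%s'",
                 rownames(mat)[bad[1L]], colnames(mat)[bad[2L]]))
  }
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative expression value for gene '%s', sample '%s'",
                 rownames(mat)[bad[1L]], colnames(mat)[bad[2L]]))
  }
  invisible(mat)
}

#' Derive binary early/late stage labels from clinical stage strings
#'
#' Pathologic stage strings are whitespace- and case-normalized and mapped to
#' the binary target: Stage I and II are early (label 0), Stage III and IV
#' late (label 1). Any other string (missing, "[Discrepancy]", stage X, ...)
#' is treated as missing and the sample is excluded; excluded IDs are kept in
#' the `"excluded"` attribute.
#'
#' @param clinical either a data frame whose first two columns are sample ID
#'   and stage string (column names `sample_id` / `pathologic_stage` are
#'   honoured when present), or a named character vector of stage strings.
#' @return a `stage_labels` data frame with columns `sample_id`, `stage`
#'   (normalized string) and `label` (0 early / 1 late), plus attribute
#'   `excluded` (character vector of dropped sample IDs).
#' @export
derive_stage_labels <- function(clinical) {
  if (is.data.frame(clinical)) {
    sid_col <- if ("sample_id" %in% names(clinical)) "sample_id" else names(clinical)[1L]
    stg_col <- if ("pathologic_stage" %in% names(clinical)) "pathologic_stage" else names(clinical)[2L]
    ids <- as.character(clinical[[sid_col]])
    stg <- as.character(clinical[[stg_col]])
  } else {
    if (is.null(names(clinical))) stop("clinical vector must be named by sample ID")
    ids <- names(clinical)
    stg <- as.character(clinical)
  }
  norm <- toupper(trimws(gsub("\\s+", " ", stg)))
  map <- c("STAGE I" = 0L, "STAGE II" = 0L, "STAGE III" = 1L, "STAGE IV" = 1L)
  lab <- unname(map[norm])
  keep <- !is.na(lab)
  if (!any(keep)) stop("no sample has a recognizable pathologic stage (Stage I-IV)")
  excluded <- ids[!keep]
  pretty <- c("STAGE I" = "Stage I", "STAGE II" = "Stage II",
              "STAGE III" = "Stage III", "STAGE IV" = "Stage IV")
  out <- data.frame(sample_id = ids[keep],
                    stage = unname(pretty[norm[keep]]),
                    label = lab[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("stage_labels", "data.frame")
  attr(out, "excluded") <- excluded
  out
}

#' Stratified train/test split
#'
#' Randomly partitions samples into a training and a held-out test set,
#' stratified by the four pathologic stage groups when stage strings are
#' available (else by the binary label), so that each stratum contributes
#' `round(train_fraction * n_stratum)` training samples. Reproducible for a
#' given seed.
#'
#' @param mat genes x samples expression matrix.
#' @param labels `stage_labels` object (see [derive_stage_labels()]).
#' @param train_fraction fraction of samples assigned to training, in (0, 1).
#' @param seed integer seed controlling the permutation.
#' @return a `stage_split` list with `train` and `test` character vectors of
#'   sample IDs (disjoint, exhaustive over labeled samples present in `mat`).
#' @export
split_train_test <- function(mat, labels, train_fraction = 0.8, seed = 1L) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must be strictly between 0 and 1")
  }
  if (!inherits(labels, "stage_labels")) stop("labels must come from derive_stage_labels()")
  missing <- setdiff(labels$sample_id, colnames(mat))
  if (length(missing)) {
    stop("labeled sample(s) absent from expression matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  strata <- if (all(!is.na(labels$stage))) labels$stage else as.character(labels$label)
  ids <- labels$sample_id
  train <- character(0)
  tie_up <- TRUE
  withr::with_seed(seed, {
    for (s in unique(strata)) {
      sid <- ids[strata == s]
      x <- train_fraction * length(sid)
      if (isTRUE(all.equal(x - floor(x), 0.5))) {
        # exact half: alternate up/down so tied strata balance overall
        n_tr <- floor(x) + as.integer(tie_up)
        tie_up <- !tie_up
      } else {
        n_tr <- round(x)
      }
      n_tr <- max(min(n_tr, length(sid)), 0L)
      train <- c(train, sample(sid)[seq_len(n_tr)])
    }
  })
  test <- setdiff(ids, train)
  lab <- stats::setNames(labels$label, labels$sample_id)
  if (length(unique(lab[train])) < 2L || length(unique(lab[test])) < 2L) {
    stop("a class is absent from one side of the split; ",
         "try a different train_fraction or seed")
  }
  out <- list(train = train, test = test,
              train_fraction = train_fraction, seed = seed)
  class(out) <- "stage_split"
  out
}

#' Persist / load a train-test partition
#'
#' Two-column TSV (`sample_id`, `split`) so a partition can be audited and
#' reused across runs.
#'
#' @param split a `stage_split` object.
#' @param path TSV path.
#' @return `write_split`: `path` invisibly; `read_split`: a `stage_split`.
#' @export
write_split <- function(split, path) {
  df <- data.frame(
    sample_id = c(split$train, split$test),
    split = rep(c("train", "test"), c(length(split$train), length(split$test))),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- list(train = df$sample_id[df$split == "train"],
              test = df$sample_id[df$split == "test"],
              train_fraction = NA_real_, seed = NA_integer_)
  class(out) <- "stage_split"
  out
}

#' Fit the log2 / z-score standardization on training samples
#'
#' The comparison preprocessing path: raw abundances are transformed with
#' `x = log2(v + 1)` and then z-scored per gene, `z = (x - xbar) / s`, where
#' the per-gene mean `xbar` and standard deviation `s` are estimated on
#' training samples only. Genes constant in training (`s = 0`) are flagged
#' and map to 0.
#'
#' @param train_mat genes x samples matrix of raw abundances (training only).
#' @return a `standardization_params` list with per-gene `mean`, `sd`
#'   (training sample SD of the log2 values) and logical `constant` flags.
#' @export
fit_standardization <- function(train_mat) {
  validate_expression_matrix(train_mat)
  x <- log2(train_mat + 1)
  mu <- rowMeans(x)
  s <- apply(x, 1L, stats::sd)
  const <- s == 0
  out <- list(gene_ids = rownames(train_mat), mean = mu, sd = s, constant = const)
  class(out) <- "standardization_params"
  out
}

#' Apply fitted standardization parameters
#'
#' @param mat genes x samples matrix of raw abundances; must contain every
#'   gene the parameters were fitted for.
#' @param params a `standardization_params` object fitted on training data.
#' @return genes x samples matrix of z-scores (rows ordered as in `params`);
#'   constant training genes are all-zero rows.
#' @export
apply_standardization <- function(mat, params) {
  if (!inherits(params, "standardization_params")) stop("params must come from fit_standardization()")
  missing <- setdiff(params$gene_ids, rownames(mat))
  if (length(missing)) {
    stop("gene(s) absent from matrix: ", paste(utils::head(missing, 5L), collapse = ", "))
  }
  x <- log2(mat[params$gene_ids, , drop = FALSE] + 1)
  s <- ifelse(params$constant, 1, params$sd)
  z <- (x - params$mean) / s
  z[params$constant, ] <- 0
  z
}
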