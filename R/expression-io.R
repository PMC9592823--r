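#' Read a gene x sample expression matrix from a tab-delimited file
#'
#' The expected dialect is a single header row of sample identifiers, gene
#' identifiers in the first column, and tab-separated numeric values
#' (log-scale expression). Missing or non-numeric cells and duplicated gene
#' rows are rejected rather than silently imputed.
#'
#' @param path Path to a TSV file.
#' @return An expression table: tibble with `gene_id` plus one numeric
#'   column per sample.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) {
    abort(sprintf("malformed header in %s: empty first line", path))
  }
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (nrow(x) == 0L) abort(sprintf("no data rows in %s", path))
  names(x)[1L] <- "gene_id"
  dup <- unique(x$gene_id[duplicated(x$gene_id)])
  if (length(dup) > 0L) {
    abort(sprintf("duplicated gene ids in %s: %s", path,
                  paste(utils::head(dup, 5L), collapse = ", ")))
  }
  for (s in names(x)[-1L]) {
    v <- suppressWarnings(as.numeric(x[[s]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0L) {
      abort(sprintf("non-numeric or missing value in %s, column '%s', data line %d",
                    path, s, bad[[1L]]))
    }
    x[[s]] <- v
  }
  validate_expression(x, "file")
}

#' Write an expression table as a tab-delimited matrix
#'
#' @param x An expression table.
#' @param path Output file path.
#' @return `x`, invisibly (for piping).
#' @export
write_expression_matrix <- function(x, path) {
  x <- validate_expression(x)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

#' Read a phenotype table
#'
#' Comma-separated table with a `sample_id` column and any of: `condition`
#' (control/treated), `ki67_pre`, `ki67_post` (percentages in \[0, 100\]),
#' `response` (responder/non_responder), `group`.
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per sample.
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  if (!"sample_id" %in% names(x)) abort("phenotype table must have a sample_id column")
  if (anyDuplicated(x$sample_id)) abort("phenotype table has duplicated sample ids")
  for (k in c("ki67_pre", "ki67_post")) {
    if (k %in% names(x)) {
      v <- x[[k]]
      if (any(v[!is.na(v)] < 0 | v[!is.na(v)] > 100)) {
        abort(sprintf("%s values must lie in [0, 100]", k))
      }
    }
  }
  x
}

#' Aggregate probe-level expression to genes and replicates to subjects
#'
#' Mirrors the microarray preprocessing convention for bead-array trial
#' data: expression is first averaged over the probes mapping to each gene,
#' and the resulting gene-level values are then averaged over replicate
#' arrays of the same subject. The order is fixed: probes first, then
#' replicates.
#'
#' @param x An expression table whose `gene_id` column holds probe ids.
#' @param probe_map Data frame with columns `probe_id`, `gene_id`. Probes
#'   absent from the map are dropped (count reported via a message).
#' @param replicate_map Optional data frame with columns `sample_id`,
#'   `subject_id`; when `NULL`, each sample is its own subject.
#' @return An expression table with one row per gene and one column per
#'   subject.
#' @export
aggregate_probes <- function(x, probe_map, replicate_map = NULL) {
  m <- as_expr_matrix(x)
  if (!is.data.frame(probe_map) || !all(c("probe_id", "gene_id") %in% names(probe_map))) {
    abort("`probe_map` must be a data frame with columns probe_id and gene_id.")
  }
  if (nrow(probe_map) == 0L) abort("`probe_map` is empty.")
  pm <- stats::setNames(as.character(probe_map$gene_id), probe_map$probe_id)
  mapped <- rownames(m) %in% names(pm)
  n_drop <- sum(!mapped)
  if (n_drop > 0L) {
    inform(sprintf("dropping %d probe(s) absent from probe_map", n_drop))
  }
  m <- m[mapped, , drop = FALSE]
  if (nrow(m) == 0L) abort("no probes left after mapping.")
  gene <- pm[rownames(m)]
  gm <- rowsum(m, group = gene, reorder = FALSE) / as.vector(table(gene)[unique(gene)])
  # rowsum()/count gives the per-gene arithmetic mean of its probes
  if (is.null(replicate_map)) {
    out <- gm
  } else {
    if (!all(c("sample_id", "subject_id") %in% names(replicate_map))) {
      abort("`replicate_map` must have columns sample_id and subject_id.")
    }
    rm_ <- stats::setNames(as.character(replicate_map$subject_id),
                           replicate_map$sample_id)
    missing <- setdiff(colnames(gm), names(rm_))
    if (length(missing) > 0L) {
      abort(sprintf("samples absent from replicate_map: %s",
                    paste(utils::head(missing, 5L), collapse = ", ")))
    }
    subj <- rm_[colnames(gm)]
    out <- t(rowsum(t(gm), group = subj, reorder = FALSE)) /
      rep(as.vector(table(subj)[unique(subj)]), each = nrow(gm))
    colnames(out) <- unique(subj)
  }
  expr_as_tibble(out)
}

#' Remove low-variance and low-expression genes
#'
#' Drops genes whose across-sample variance lies at or below the
#' `var_percentile` of all gene variances, or whose mean expression lies at
#' or below the `expr_percentile` of all gene means (union of the two
#' removal sets). Percentiles use the linear-interpolation convention and
#' the boundary is inclusive, so the 0th percentile removes exactly the
#' minimal gene(s). Surviving genes keep their input order.
#'
#' @param x An expression table.
#' @param var_percentile Variance percentile cutoff, in \[0, 100). Default 25.
#' @param expr_percentile Mean-expression percentile cutoff, in \[0, 100).
#'   Default 30.
#' @return The filtered expression table.
#' @export
filter_low_info <- function(x, var_percentile = 25, expr_percentile = 30) {
  m <- as_expr_matrix(x)
  for (p in c(var_percentile, expr_percentile)) {
    if (!is.numeric(p) || length(p) != 1L || p < 0 || p >= 100) {
      abort("percentiles must be single numbers in [0, 100).")
    }
  }
  vars <- apply(m, 1L, stats::var)
  means <- rowMeans(m)
  v_cut <- stats::quantile(vars, var_percentile / 100, type = 7, names = FALSE)
  e_cut <- stats::quantile(means, expr_percentile / 100, type = 7, names = FALSE)
  keep <- !(vars <= v_cut | means <= e_cut)
  if (!any(keep)) abort("all genes filtered")
  validate_expression(x)[keep, , drop = FALSE]
}

#' Quantile-normalize an expression matrix
#'
#' Without a reference, performs standard quantile normalization: the
#' reference distribution is the per-rank mean of the column-sorted values,
#' and each column's values are replaced by the reference values at their
#' within-column ranks (ties receive the mean of the tied reference
#' positions). With a reference — typically saved from a training run — each
#' column is mapped onto that distribution instead, which is how held-out
#' samples are projected onto a training normalization.
#'
#' @param x An expression table with at least one sample.
#' @param reference Optional numeric vector (non-decreasing after sorting)
#'   of length equal to the gene count, e.g. from a previous call.
#' @return The normalized expression table, with the reference used stored
#'   in attribute `"quantile_reference"` (retrieve with
#'   [quantile_reference()]).
#' @export
quantile_normalize <- function(x, reference = NULL) {
  m <- as_expr_matrix(x)
  if (is.null(reference)) {
    reference <- rowMeans(apply(m, 2L, sort, method = "quick"))
  } else {
    reference <- sort(as.numeric(reference))
    if (length(reference) != nrow(m)) {
      abort(sprintf("reference length %d does not match gene count %d.",
                    length(reference), nrow(m)))
    }
  }
  out <- apply(m, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    if (length(reference) == 1L) rep(reference, length(col))
    else stats::approx(seq_along(reference), reference, xout = r)$y
  })
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(m))
  dimnames(out) <- dimnames(m)
  res <- expr_as_tibble(out)
  attr(res, "quantile_reference") <- as.numeric(reference)
  res
}

#' Extract the quantile reference stored by [quantile_normalize()]
#'
#' @param x A result of [quantile_normalize()].
#' @return Numeric non-decreasing vector, one value per gene rank.
#' @export
quantile_reference <- function(x) {
  ref <- attr(x, "quantile_reference", exact = TRUE)
  if (is.null(ref)) abort("`x` carries no quantile reference; run quantile_normalize() first.")
  ref
}

#' Standardize each gene to mean 0 and unit standard deviation
#'
#' Per gene, subtracts the across-sample mean and divides by the sample
#' standard deviation (n - 1 denominator). Genes with zero variance cannot
#' be standardized and are dropped with a warning, so downstream
#' correlation and symmetrical-uncertainty computations never see a
#' zero-variance predictor.
#'
#' @param x An expression table with at least two samples.
#' @return The standardized expression table.
#' @export
standardize_genes <- function(x) {
  m <- as_expr_matrix(x)
  if (ncol(m) < 2L) abort("standardization needs at least 2 samples.")
  sds <- apply(m, 1L, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warn(sprintf("dropping %d constant gene(s) that cannot be standardized", sum(const)))
    m <- m[!const, , drop = FALSE]
    sds <- sds[!const]
    if (nrow(m) == 0L) abort("all genes constant; nothing to standardize.")
  }
  out <- (m - rowMeans(m)) / sds
  expr_as_tibble(out)
}
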