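#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# An expression table is a tibble whose first column ("gene_id") holds unique
# gene identifiers and whose remaining columns are numeric, one per sample.
# All user-facing functions take and return this shape so calls chain with
# the pipe; internally we convert to a genes x samples base matrix.

#' Validate an expression table
#'
#' Checks the tibble contract used throughout the package: a `gene_id`
#' first column with unique, non-missing identifiers, at least one sample
#' column, all sample columns numeric and finite.
#'
#' @param x A data frame: `gene_id` plus one numeric column per sample.
#' @param arg Name used in error messages.
#' @return `x` as a tibble.
#' @export
validate_expression <- function(x, arg = "x") {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame with a gene_id column.", arg))
  }
  x <- as_tibble(x)
  if (ncol(x) < 2L) {
    abort(sprintf("`%s` must have a gene_id column and at least one sample column.", arg))
  }
  if (names(x)[1L] != "gene_id") {
    abort(sprintf("first column of `%s` must be named 'gene_id' (found '%s').",
                  arg, names(x)[1L]))
  }
  ids <- x$gene_id
  if (anyNA(ids)) abort(sprintf("`%s` has missing gene ids.", arg))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(sprintf("`%s` has duplicated gene ids: %s.", arg,
                  paste(utils::head(dup, 5L), collapse = ", ")))
  }
  sn <- names(x)[-1L]
  if (anyDuplicated(sn)) abort(sprintf("`%s` has duplicated sample ids.", arg))
  for (s in sn) {
    v <- x[[s]]
    if (!is.numeric(v)) {
      abort(sprintf("sample column '%s' of `%s` is not numeric.", s, arg))
    }
    if (any(!is.finite(v))) {
      abort(sprintf("sample column '%s' of `%s` contains non-finite values.", s, arg))
    }
  }
  x
}

# tibble -> genes x samples numeric matrix with dimnames
as_expr_matrix <- function(x, arg = "x") {
  x <- validate_expression(x, arg)
  m <- as.matrix(x[, -1L, drop = FALSE])
  rownames(m) <- x$gene_id
  m
}

# genes x samples matrix -> expression tibble
expr_as_tibble <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(gene_id = rownames(m)), out)
}

#' Sample identifiers of an expression table
#'
#' @param x An expression table (`gene_id` + sample columns).
#' @return Character vector of sample column names.
#' @export
sample_ids <- function(x) {
  names(validate_expression(x))[-1L]
}

# Deterministic per-fold seed keyed by (global seed, sample id) so LOOCV fold
# results do not depend on column order. Kept below 2^31 - 1.
derive_seed <- function(seed, id) {
  stopifnot(length(id) == 1L)
  u <- utf8ToInt(as.character(id))
  h <- sum(u * seq_along(u)) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 1) %% 2147483629)
}

# Run code under a local seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# match a labels argument (tibble sample_id/label column, or named vector)
# against the sample columns of an expression table; returns a character
# vector aligned to sample order.
align_labels <- function(labels, samples, col = NULL, arg = "labels") {
  if (is.data.frame(labels)) {
    if (is.null(col)) {
      cand <- intersect(c("condition", "response", "label", "group"), names(labels))
      if (length(cand) == 0L) {
        abort(sprintf("`%s` must have a condition/response/label/group column.", arg))
      }
      col <- cand[[1L]]
    }
    if (!all(c("sample_id", col) %in% names(labels))) {
      abort(sprintf("`%s` must have columns sample_id and %s.", arg, col))
    }
    v <- stats::setNames(as.character(labels[[col]]), labels$sample_id)
  } else {
    v <- stats::setNames(as.character(labels), names(labels))
    if (is.null(names(v))) {
      if (length(v) != length(samples)) {
        abort(sprintf("unnamed `%s` must have one entry per sample.", arg))
      }
      names(v) <- samples
    }
  }
  missing <- setdiff(samples, names(v))
  if (length(missing) > 0L) {
    abort(sprintf("`%s` missing entries for samples: %s.", arg,
                  paste(utils::head(missing, 5L), collapse = ", ")))
  }
  out <- v[samples]
  if (anyNA(out)) abort(sprintf("`%s` contains missing values.", arg))
  unname(out)
}
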