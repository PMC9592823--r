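# fixtures are built in code; heavyweight default-scale runs are computed
# once per test session and memoized here.

expr_tbl <- function(m) {
  stopifnot(is.matrix(m))
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

as_matrix_expr <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$gene_id
  m
}

random_expr <- function(n_genes, n_samples, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
  })
  expr_tbl(m)
}

# wrap a features x samples 0/1 integer matrix as a discretized_matrix
disc_from_codes <- function(codes) {
  storage.mode(codes) <- "integer"
  if (is.null(colnames(codes))) colnames(codes) <- sprintf("s%02d", seq_len(ncol(codes)))
  if (is.null(rownames(codes))) rownames(codes) <- sprintf("f%02d", seq_len(nrow(codes)))
  structure(
    list(
      codes = dplyr::bind_cols(tibble::tibble(feature_id = rownames(codes)),
                               tibble::as_tibble(codes, .name_repair = "minimal")),
      split_rule = tibble::tibble(feature_id = rownames(codes),
                                  threshold = 0.5, degenerate = FALSE)
    ),
    class = "discretized_matrix"
  )
}

.cache <- new.env(parent = emptyenv())

memo <- function(key, code) {
  if (!exists(key, envir = .cache)) assign(key, force(code), envir = .cache)
  get(key, envir = .cache)
}

# default-scale synthetic cell-line experiment and fitted signature
default_cells <- function() memo("cells", simulate_cell_lines(seed = 1))

default_filtered <- function() memo("filtered", filter_low_info(default_cells()$expr))

default_signature <- function() {
  memo("sigmodel",
       fit_signature_model(default_filtered(), default_cells()$pheno, seed = 17))
}

# default-scale patient cohort (strong signal, d = 2) and its LOOCV
default_patients <- function() {
  memo("patients",
       simulate_patient_cohort(signature = default_signature()$gene_set, seed = 1))
}

default_patient_loocv <- function() {
  memo("pat_loocv", {
    pat <- default_patients()
    labels <- label_response(pat$pheno)
    std <- standardize_genes(pat$expr)
    loocv_patients(std, labels, default_signature()$gene_set, seed = 17)
  })
}

# matched null cohort (effect size 0) for the anti-leakage check
null_patient_loocv <- function() {
  memo("pat_loocv_null", {
    pat <- simulate_patient_cohort(effect_size = 0,
                                   signature = default_signature()$gene_set,
                                   seed = 1)
    labels <- label_response(pat$pheno)
    std <- standardize_genes(pat$expr)
    loocv_patients(std, labels, default_signature()$gene_set, seed = 17)
  })
}

default_cell_loocv <- function() {
  memo("cell_loocv",
       loocv_cell_lines(default_filtered(), default_cells()$pheno, seed = 17))
}
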