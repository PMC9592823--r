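#' Assemble a full pipeline configuration
#'
#' Collects every tunable parameter of the pipeline in one named list with
#' the package defaults: filter percentiles 25/30, signature size 100, two
#' metagenes, 10% relative Ki67 decrease, FCBF delta 0.25, mtry grid
#' `2..min(15, p)` (`NULL` here), 0.75 high-response cutoff, and the
#' synthetic-data defaults. The config is snapshotted into every run
#' directory so all constants of a run are explicit.
#'
#' @param seed Global seed. Default 17.
#' @param ... Overrides of any default, e.g. `n_genes = 1000`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 17, ...) {
  cfg <- list(
    seed = seed,
    var_percentile = 25, expr_percentile = 30,
    n_signature_genes = 100, k_metagenes = 2,
    n_iter = 5000, n_burn = 1000, prior_variance = 100,
    ki67_threshold_pct = 10,
    delta = 0.25, n_trees = 500, mtry_grid = NULL,
    inner_folds = 5, inner_repeats = 5,
    high_response_cutoff = 0.75,
    sim = list(
      n_lines = 9, n_genes = 5000, n_true_genes = 200, cell_effect_size = 1.5,
      line_sd = 0.5, noise_sd_cell = 0.3,
      n_patients = 23, n_informative = 10, n_redundant_per_informative = 1,
      patient_effect_size = 2, overlap_with_invitro = 0.3,
      response_rate = 0.5, noise_sd_patient = 0.5,
      external_n_per_group = 50,
      external_group_means = c(low = 0, medium = 0.5, high = 1)
    )
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% names(cfg)) cfg[[nm]] <- dots[[nm]]
    else if (nm %in% names(cfg$sim)) cfg$sim[[nm]] <- dots[[nm]]
    else abort(sprintf("unknown config parameter '%s'.", nm))
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full biomarker pipeline on simulated data
#'
#' Executes every stage end to end: simulate the cell-line experiment,
#' filter low-information genes, fit and cross-validate the in vitro
#' signature, simulate the patient cohort (with signature overlap), label
#' response from Ki67, standardize, run patient LOOCV, fit the final
#' integrative model, and — optionally — score a simulated external cohort
#' and compare its groups. All artifacts (TSV matrices, CSV phenotypes,
#' JSON models and reports, the config snapshot) are written to `outdir`;
#' re-running with the same config reproduces every numeric output.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if absent); `NULL` skips
#'   writing.
#' @param external Also run the external-cohort stage. Default `TRUE`.
#' @return A list with `signature_model`, `cellline_loocv`,
#'   `patient_loocv`, `final_model`, `labels`, and (when `external`)
#'   `external_scores` and `group_comparison`.
#' @export
run_full_pipeline <- function(config = pipeline_config(), outdir = NULL,
                              external = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  cells <- simulate_cell_lines(
    n_lines = sim$n_lines, n_genes = sim$n_genes,
    n_true_genes = sim$n_true_genes, effect_size = sim$cell_effect_size,
    line_sd = sim$line_sd, noise_sd = sim$noise_sd_cell,
    seed = derive_seed(config$seed, "cell-lines"))
  filtered <- filter_low_info(cells$expr, config$var_percentile,
                              config$expr_percentile)
  sig_model <- fit_signature_model(
    filtered, cells$pheno, n_genes = config$n_signature_genes,
    k = config$k_metagenes, n_iter = config$n_iter, n_burn = config$n_burn,
    prior_variance = config$prior_variance,
    seed = derive_seed(config$seed, "signature"))
  cell_loocv <- loocv_cell_lines(
    filtered, cells$pheno, n_genes = config$n_signature_genes,
    k = config$k_metagenes, n_iter = config$n_iter, n_burn = config$n_burn,
    prior_variance = config$prior_variance,
    seed = derive_seed(config$seed, "cell-loocv"))
  patients <- simulate_patient_cohort(
    n_patients = sim$n_patients, n_genes = sim$n_genes,
    n_informative = sim$n_informative,
    n_redundant_per_informative = sim$n_redundant_per_informative,
    effect_size = sim$patient_effect_size,
    overlap_with_invitro = sim$overlap_with_invitro,
    response_rate = sim$response_rate, noise_sd = sim$noise_sd_patient,
    signature = sig_model$gene_set,
    seed = derive_seed(config$seed, "patients"))
  labels <- label_response(patients$pheno, threshold_pct = config$ki67_threshold_pct)
  std <- standardize_genes(patients$expr)
  pat_loocv <- loocv_patients(
    std, labels, sig_model$gene_set, delta = config$delta,
    n_trees = config$n_trees, mtry_grid = config$mtry_grid,
    inner_folds = config$inner_folds, inner_repeats = config$inner_repeats,
    seed = derive_seed(config$seed, "patient-loocv"))
  final <- fit_final_model(
    std, labels, sig_model$gene_set, delta = config$delta,
    n_trees = config$n_trees, mtry_grid = config$mtry_grid,
    inner_folds = config$inner_folds, inner_repeats = config$inner_repeats,
    seed = derive_seed(config$seed, "final"))
  res <- list(signature_model = sig_model, cellline_loocv = cell_loocv,
              patient_loocv = pat_loocv, final_model = final, labels = labels,
              config = config)
  if (external) {
    ext <- simulate_external_cohort(
      patients$truth, n_per_group = sim$external_n_per_group,
      group_means = sim$external_group_means, n_genes = sim$n_genes,
      effect_size = sim$patient_effect_size, noise_sd = sim$noise_sd_patient,
      seed = derive_seed(config$seed, "external"))
    scores <- suppressWarnings(
      score_external_cohort(final, ext$expr,
                            cutoff = config$high_response_cutoff))
    res$external_scores <- dplyr::left_join(scores, ext$groups, by = "sample_id")
    attr(res$external_scores, "cutoff") <- config$high_response_cutoff
    class(res$external_scores) <- class(scores)
    res$group_comparison <- compare_groups(res$external_scores)
  }
  if (!is.null(outdir)) write_pipeline_artifacts(res, outdir)
  res
}

write_pipeline_artifacts <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  cfg_doc <- unclass(cfg)
  jsonlite::write_json(cfg_doc, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_signature_model(res$signature_model,
                        file.path(outdir, "signature_model.json"))
  readr::write_tsv(res$cellline_loocv, file.path(outdir, "cellline_loocv.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$patient_loocv, file.path(outdir, "patient_loocv.tsv"),
                   progress = FALSE)
  readr::write_csv(res$labels, file.path(outdir, "response_labels.csv"),
                   progress = FALSE)
  write_final_model(res$final_model, file.path(outdir, "final_model.json"))
  if (!is.null(res$external_scores)) {
    readr::write_tsv(res$external_scores, file.path(outdir, "external_scores.tsv"),
                     progress = FALSE)
    gc_ <- res$group_comparison
    jsonlite::write_json(
      list(anova = as.list(gc_$anova), tukey = as.list(gc_$tukey),
           group_summary = as.list(gc_$group_summary), cutoff = gc_$cutoff),
      file.path(outdir, "group_comparison.json"),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(outdir)
}
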