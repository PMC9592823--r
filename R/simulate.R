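#' Simulate a paired cell-line treatment experiment
#'
#' Emulates the design of an in vitro drug-response experiment: `n_lines`
#' cell lines each profiled under a vehicle control and a treated
#' condition, on a log2 expression scale. Per gene `g`, a baseline
#' `b_g ~ N(6, 2)`; per line, a shared line effect `u ~ N(0, line_sd)`
#' (identical in the control and treated columns of that line, giving the
#' paired structure); independent technical noise `N(0, noise_sd)` on every
#' measurement. A set of `n_true_genes` treatment-responsive genes receives
#' an additional shift `effect_size * s_g` in the treated condition, with
#' `s_g = +1` for half of them (up-regulated) and `-1` for the other half.
#'
#' @param n_lines Number of cell lines. Default 9.
#' @param n_genes Number of genes. Default 5000.
#' @param n_true_genes Number of treatment-responsive genes. Default 200.
#' @param effect_size Treatment shift in log2 units. Default 1.5.
#' @param line_sd Between-line standard deviation. Default 0.5.
#' @param noise_sd Technical noise standard deviation. Default 0.3.
#' @param seed Integer seed; identical inputs give identical outputs.
#' @return A list with `expr` (expression table, `2 * n_lines` columns),
#'   `pheno` (tibble `sample_id`, `condition`, `line`), and `truth` (list
#'   with `true_gene_ids`, `direction`).
#' @export
simulate_cell_lines <- function(n_lines = 9, n_genes = 5000, n_true_genes = 200,
                                effect_size = 1.5, line_sd = 0.5,
                                noise_sd = 0.3, seed = 1) {
  if (n_true_genes > n_genes) abort("`n_true_genes` exceeds `n_genes`.")
  if (effect_size < 0) abort("`effect_size` must be non-negative.")
  if (n_lines < 2L) abort("need at least 2 cell lines.")
  genes <- sprintf("gene%05d", seq_len(n_genes))
  lines <- sprintf("line%02d", seq_len(n_lines))
  with_seed(seed, {
    b <- stats::rnorm(n_genes, 6, 2)
    true_idx <- sort(sample.int(n_genes, n_true_genes))
    s <- rep(c(1, -1), length.out = n_true_genes)[sample.int(n_true_genes)]
    ctrl <- trt <- matrix(0, n_genes, n_lines)
    for (l in seq_len(n_lines)) {
      u <- stats::rnorm(n_genes, 0, line_sd)
      ctrl[, l] <- b + u + stats::rnorm(n_genes, 0, noise_sd)
      trt[, l] <- b + u + stats::rnorm(n_genes, 0, noise_sd)
      trt[true_idx, l] <- trt[true_idx, l] + effect_size * s
    }
  })
  m <- cbind(ctrl, trt)
  colnames(m) <- c(paste0(lines, "_control"), paste0(lines, "_treated"))
  rownames(m) <- genes
  pheno <- tibble(
    sample_id = colnames(m),
    condition = rep(c("control", "treated"), each = n_lines),
    line = rep(lines, 2L)
  )
  list(
    expr = expr_as_tibble(m),
    pheno = pheno,
    truth = list(true_gene_ids = genes[true_idx],
                 direction = ifelse(s > 0, "up_in_treated", "down_in_treated"))
  )
}

#' Simulate a patient cohort with known response structure
#'
#' Emulates a small neoadjuvant trial cohort: per-gene baselines
#' `b_g ~ N(6, 2)` plus `N(0, noise_sd)` sample noise on a log scale.
#' Response is planted per patient (Bernoulli `response_rate`); responders
#' receive a shift `effect_size * s_g` on `n_informative` informative genes
#' (`s_g = +/-1`, half each). When an in vitro signature is supplied, a
#' fraction `overlap_with_invitro` of the informative genes is drawn from
#' the signature genes so the integration step has genuine overlap. Each
#' informative gene also gets `n_redundant_per_informative` redundant
#' copies: another gene whose values are the parent's plus `N(0, 0.1)`
#' noise. Ki67 pre/post staining pairs are generated so that
#' [label_response()] at the default 10% relative threshold reproduces the
#' planted labels exactly (responders: planted relative decrease uniform in
#' 20-80%; non-responders: relative change uniform in -10% to +10%).
#'
#' @param n_patients Cohort size. Default 23.
#' @param n_genes Number of genes. Default 5000.
#' @param n_informative Informative genes. Default 10.
#' @param n_redundant_per_informative Redundant copies per informative
#'   gene. Default 1.
#' @param effect_size Responder shift in log units. Default 2.
#' @param overlap_with_invitro Fraction of informative genes drawn from the
#'   supplied signature. Default 0.3.
#' @param response_rate Probability a patient is a responder. Default 0.5.
#' @param noise_sd Sample noise standard deviation. Default 0.5.
#' @param signature Optional `signature_gene_set` (or character vector)
#'   from the in vitro stage.
#' @param seed Integer seed.
#' @return A list with `expr`, `pheno` (tibble `sample_id`, `ki67_pre`,
#'   `ki67_post`, `response`), and `truth` (list `informative_ids`,
#'   `direction`, `redundant_map` tibble, `response`).
#' @export
simulate_patient_cohort <- function(n_patients = 23, n_genes = 5000,
                                    n_informative = 10,
                                    n_redundant_per_informative = 1,
                                    effect_size = 2, overlap_with_invitro = 0.3,
                                    response_rate = 0.5, noise_sd = 0.5,
                                    signature = NULL, seed = 1) {
  n_red <- n_informative * n_redundant_per_informative
  if (n_informative + n_red > n_genes) {
    abort("informative plus redundant genes exceed `n_genes`.")
  }
  if (response_rate < 0 || response_rate > 1) abort("`response_rate` must be in [0, 1].")
  genes <- sprintf("gene%05d", seq_len(n_genes))
  patients <- sprintf("patient%02d", seq_len(n_patients))
  sig <- if (is.data.frame(signature)) signature$gene_id else as.character(signature)
  sig <- intersect(sig, genes)
  with_seed(seed, {
    n_from_sig <- min(length(sig), round(overlap_with_invitro * n_informative))
    inf_sig <- if (n_from_sig > 0) sample(sig, n_from_sig) else character(0)
    pool <- setdiff(genes, inf_sig)
    inf_other <- sample(pool, n_informative - n_from_sig)
    informative <- c(inf_sig, inf_other)
    red_pool <- setdiff(genes, informative)
    redundant <- sample(red_pool, n_red)
    s <- rep(c(1, -1), length.out = n_informative)[sample.int(n_informative)]
    responder <- stats::rbinom(n_patients, 1L, response_rate) == 1L
    b <- stats::rnorm(n_genes, 6, 2)
    m <- b + matrix(stats::rnorm(n_genes * n_patients, 0, noise_sd),
                    n_genes, n_patients)
    dimnames(m) <- list(genes, patients)
    inf_idx <- match(informative, genes)
    for (i in seq_len(n_informative)) {
      m[inf_idx[i], responder] <- m[inf_idx[i], responder] + effect_size * s[i]
    }
    parent <- rep(informative, each = n_redundant_per_informative)
    for (j in seq_along(redundant)) {
      m[redundant[j], ] <- m[parent[j], ] + stats::rnorm(n_patients, 0, 0.1)
    }
    ki67_pre <- stats::runif(n_patients, 20, 80)
    rel_change <- ifelse(responder,
                         stats::runif(n_patients, 20, 80),
                         stats::runif(n_patients, -10, 10))
    ki67_post <- pmin(ki67_pre * (1 - rel_change / 100), 100)
  })
  if (length(unique(responder)) < 2L) {
    warn("simulated cohort contains a single response class; downstream LOOCV will refuse it")
  }
  pheno <- tibble(
    sample_id = patients,
    ki67_pre = ki67_pre,
    ki67_post = ki67_post,
    response = ifelse(responder, "responder", "non_responder")
  )
  list(
    expr = expr_as_tibble(m),
    pheno = pheno,
    truth = list(
      informative_ids = informative,
      direction = ifelse(s > 0, "up_in_responder", "down_in_responder"),
      redundant_map = tibble(redundant_id = redundant, parent_id = parent),
      response = stats::setNames(pheno$response, pheno$sample_id)
    )
  )
}

#' Simulate an external cohort with ordered group structure
#'
#' Emulates an external validation cohort stratified into risk groups
#' (default low/medium/high): samples share the generative process of the
#' matched patient simulation, and each group's informative-gene shift is
#' the responder shift scaled by that group's entry in `group_means`, so
#' groups with larger multipliers look progressively more like responders.
#'
#' @param truth The `truth` element of a [simulate_patient_cohort()] call
#'   the scoring model was trained on (supplies informative genes and
#'   directions).
#' @param n_per_group Samples per group. Default 50.
#' @param group_means Named numeric multipliers of the responder shift, in
#'   increasing order of expected response. Default
#'   `c(low = 0, medium = 0.5, high = 1)`.
#' @param n_genes,effect_size,noise_sd As in the patient simulation.
#' @param seed Integer seed.
#' @return A list with `expr`, `groups` (tibble `sample_id`, `group`).
#' @export
simulate_external_cohort <- function(truth, n_per_group = 50,
                                     group_means = c(low = 0, medium = 0.5, high = 1),
                                     n_genes = 5000, effect_size = 2,
                                     noise_sd = 0.5, seed = 1) {
  if (length(group_means) < 2L) abort("at least 2 groups are required.")
  if (is.null(names(group_means))) {
    names(group_means) <- paste0("group", seq_along(group_means))
  }
  genes <- sprintf("gene%05d", seq_len(n_genes))
  informative <- truth$informative_ids
  s <- ifelse(truth$direction == "up_in_responder", 1, -1)
  if (!all(informative %in% genes)) abort("truth informative genes exceed `n_genes`.")
  n_total <- n_per_group * length(group_means)
  ids <- sprintf("ext%04d", seq_len(n_total))
  grp <- rep(names(group_means), each = n_per_group)
  with_seed(seed, {
    b <- stats::rnorm(n_genes, 6, 2)
    m <- b + matrix(stats::rnorm(n_genes * n_total, 0, noise_sd), n_genes, n_total)
    dimnames(m) <- list(genes, ids)
    inf_idx <- match(informative, genes)
    for (g in seq_along(group_means)) {
      cols <- grp == names(group_means)[g]
      m[inf_idx, cols] <- m[inf_idx, cols] + effect_size * group_means[[g]] * s
    }
    # redundant genes track their parents here too, so the model's FCBF
    # features stay meaningful on the external cohort
    if (!is.null(truth$redundant_map) && nrow(truth$redundant_map) > 0L) {
      for (j in seq_len(nrow(truth$redundant_map))) {
        m[truth$redundant_map$redundant_id[j], ] <-
          m[truth$redundant_map$parent_id[j], ] + stats::rnorm(n_total, 0, 0.1)
      }
    }
  })
  list(expr = expr_as_tibble(m), groups = tibble(sample_id = ids, group = grp))
}
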