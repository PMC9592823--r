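#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a probit posterior: one row per coefficient
#'
#' @param x A `binreg_posterior`.
#' @param conf_level Credible-interval level. Default 0.95.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (posterior mean), `std.error`
#'   (posterior sd), `conf.low`, `conf.high`.
#' @export
tidy.binreg_posterior <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  qs <- t(apply(x$draws, 2L, stats::quantile, probs = c(a, 1 - a), names = FALSE))
  tibble(
    term = colnames(x$draws),
    estimate = colMeans(x$draws),
    std.error = apply(x$draws, 2L, stats::sd),
    conf.low = qs[, 1L],
    conf.high = qs[, 2L]
  )
}

#' @export
glance.binreg_posterior <- function(x, ...) {
  tibble(n_draws = nrow(x$draws), n_coef = ncol(x$draws),
         n_iter = x$config$n_iter, n_burn = x$config$n_burn,
         prior_variance = x$config$prior_variance, seed = x$config$seed)
}

#' One-row summary of a fitted signature model
#'
#' @param x A `signature_model`.
#' @param ... Unused.
#' @return Tibble with the signature size, up/down counts, metagene count
#'   and sampler settings.
#' @export
glance.signature_model <- function(x, ...) {
  tibble(
    n_genes = nrow(x$gene_set),
    n_up = sum(x$gene_set$direction == "up_in_treated"),
    n_down = sum(x$gene_set$direction == "down_in_treated"),
    k_metagenes = ncol(x$basis$loadings),
    n_draws = nrow(x$posterior$draws)
  )
}

#' @export
tidy.signature_model <- function(x, ...) {
  as_tibble(x$gene_set)
}

#' Per-sample rows of a LOOCV report
#'
#' @param x A `loocv_report` (cell-line or patient).
#' @param ... Unused.
#' @return The per-sample tibble without the report class.
#' @export
tidy.loocv_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "loocv_report")
  attr(out, "fold_genes") <- NULL
  attr(out, "fold_features") <- NULL
  attr(out, "outcome") <- NULL
  out
}

#' One-row accuracy summary of a LOOCV report
#'
#' @param x A `loocv_report`.
#' @param ... Unused.
#' @return Tibble with `n`, `accuracy`, `n_correct`, and the majority-class
#'   rate `majority_rate`.
#' @export
glance.loocv_report <- function(x, ...) {
  correct <- x$predicted == x$truth
  tibble(
    n = nrow(x),
    n_correct = sum(correct),
    accuracy = mean(correct),
    majority_rate = max(table(x$truth)) / nrow(x)
  )
}

#' @export
tidy.tuned_forest <- function(x, ...) {
  x$cv_accuracy
}

#' @export
glance.tuned_forest <- function(x, ...) {
  tibble(chosen_mtry = x$chosen_mtry, n_trees = x$n_trees,
         n_features = length(x$feature_ids),
         best_cv_accuracy = max(x$cv_accuracy$accuracy), seed = x$seed)
}

#' Pairwise Tukey HSD rows of a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return Tibble with `comparison`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tidy.group_comparison <- function(x, ...) {
  x$tukey
}

#' @export
glance.group_comparison <- function(x, ...) {
  dplyr::bind_cols(x$anova, tibble(n_groups = nrow(x$group_summary),
                                   cutoff = x$cutoff))
}

#' @export
print.signature_model <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<signature_model> %d genes (%d up / %d down in treated), %d metagenes, %d posterior draws\n",
    g$n_genes, g$n_up, g$n_down, g$k_metagenes, g$n_draws))
  invisible(x)
}

#' @export
print.integrated_model <- function(x, ...) {
  cat(sprintf(
    "<integrated_model> %d features (%d invitro / %d fcbf / %d both), mtry = %d, %d trees\n",
    nrow(x$features),
    sum(x$features$provenance == "invitro"),
    sum(x$features$provenance == "fcbf"),
    sum(x$features$provenance == "both"),
    x$forest$chosen_mtry, x$forest$n_trees))
  invisible(x)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> one-way ANOVA F = %.3g (p = %.3g), %d groups\n",
              x$anova$f, x$anova$p, nrow(x$group_summary)))
  print(x$group_summary)
  cat("Tukey HSD:\n")
  print(x$tukey)
  invisible(x)
}
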