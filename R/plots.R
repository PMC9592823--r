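#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbar geom_hline
#'   geom_boxplot geom_line labs theme_bw position_jitter
#' @export
ggplot2::autoplot

#' Plot a LOOCV report: out-of-fold probabilities with 95% intervals
#'
#' Each point is one held-out sample's predicted probability of the
#' positive state (treated / responder), with its 95% interval when
#' available, colored by the true class, against the 0.5 decision midline.
#'
#' @param object A `loocv_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loocv_report <- function(object, ...) {
  d <- tidy(object)
  prob_col <- if ("probability" %in% names(d)) "probability" else "prob_response"
  d$prob <- d[[prob_col]]
  d$sample_id <- factor(d$sample_id, levels = d$sample_id)
  p <- ggplot(d, aes(x = .data$sample_id, y = .data$prob, color = .data$truth)) +
    geom_hline(yintercept = 0.5, linetype = "dashed", color = "grey40") +
    geom_point(size = 2)
  if (all(c("ci_low", "ci_high") %in% names(d))) {
    p <- p + geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.2)
  }
  p + labs(x = NULL, y = "out-of-fold probability", color = "true class") +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a tuning curve: internal CV accuracy against mtry
#'
#' @param object A `tuned_forest`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tuned_forest <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$mtry, y = .data$accuracy)) +
    geom_line(color = "grey60") +
    geom_point(size = 2) +
    geom_point(data = d[d$mtry == object$chosen_mtry, , drop = FALSE],
               color = "red", size = 3) +
    labs(x = "mtry", y = "internal CV accuracy") +
    theme_bw()
}

#' Plot external-cohort predictions by group
#'
#' Boxplots of the predicted response probability per group, with the
#' high-response cutoff as a dashed line — the standard view of an external
#' cohort stratified by risk class.
#'
#' @param object A `cohort_prediction` carrying a `group` column (e.g. the
#'   `external_scores` element of [run_full_pipeline()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_prediction <- function(object, ...) {
  if (!"group" %in% names(object)) {
    abort("cohort prediction has no group column to plot by.")
  }
  cutoff <- attr(object, "cutoff", exact = TRUE) %||% 0.75
  ggplot(object, aes(x = .data$group, y = .data$prob_response)) +
    geom_boxplot(outlier.shape = NA) +
    geom_point(position = position_jitter(width = 0.15), alpha = 0.4, size = 0.8) +
    geom_hline(yintercept = cutoff, linetype = "dashed", color = "red") +
    labs(x = NULL, y = "predicted probability of response") +
    theme_bw()
}
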