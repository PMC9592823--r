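#' Label clinical response from Ki67 staining change
#'
#' Clinical response is defined from the proliferation marker Ki67: a
#' patient whose relative decrease in Ki67 staining,
#' `100 * (ki67_pre - ki67_post) / ki67_pre`, exceeds `threshold_pct` is a
#' responder. If the phenotype table already carries a `response` column it
#' is passed through unchanged. The threshold semantics are configurable:
#' `relative = FALSE` switches to an absolute percentage-point decrease.
#'
#' @param pheno Data frame with `sample_id` and either `response` or both
#'   `ki67_pre` and `ki67_post` (percentages).
#' @param threshold_pct Decrease required to call a responder. Default 10.
#' @param relative Interpret the threshold as a relative decrease (fraction
#'   of baseline). Default `TRUE`.
#' @return Tibble with `sample_id`, `ki67_change` (the decrease used, in
#'   percent; `NA` when passed through), `response`.
#' @export
label_response <- function(pheno, threshold_pct = 10, relative = TRUE) {
  stopifnot(is.data.frame(pheno), "sample_id" %in% names(pheno))
  if ("response" %in% names(pheno) && !anyNA(pheno$response)) {
    chg <- if (all(c("ki67_pre", "ki67_post") %in% names(pheno))) {
      if (relative) 100 * (pheno$ki67_pre - pheno$ki67_post) / pheno$ki67_pre
      else pheno$ki67_pre - pheno$ki67_post
    } else NA_real_
    return(tibble(sample_id = pheno$sample_id, ki67_change = chg,
                  response = as.character(pheno$response)))
  }
  if (!all(c("ki67_pre", "ki67_post") %in% names(pheno))) {
    abort("need either a response column or both ki67_pre and ki67_post.")
  }
  if (any(pheno$ki67_pre <= 0)) abort("ki67_pre must be positive to label response.")
  chg <- if (relative) 100 * (pheno$ki67_pre - pheno$ki67_post) / pheno$ki67_pre
         else pheno$ki67_pre - pheno$ki67_post
  tibble(
    sample_id = pheno$sample_id,
    ki67_change = chg,
    response = ifelse(chg > threshold_pct, "responder", "non_responder")
  )
}

#' Fuse the in vitro signature with FCBF-selected clinical features
#'
#' Takes the union of the in vitro signature genes present on the patient
#' platform and the FCBF-selected genes, deduplicated with the in vitro
#' genes first, recording each gene's provenance (`invitro`, `fcbf`, or
#' `both`). Signature genes absent from the platform are dropped with a
#' message.
#'
#' @param signature A `signature_gene_set` (or character vector of gene
#'   ids).
#' @param fcbf_genes Ordered character vector of FCBF-selected gene ids
#'   (may be empty).
#' @param platform_genes Character vector of genes available on the patient
#'   platform.
#' @return A tibble of class `integrated_feature_set`: `gene_id`,
#'   `provenance`.
#' @export
build_integrated_features <- function(signature, fcbf_genes, platform_genes) {
  sig <- if (is.data.frame(signature)) signature$gene_id else as.character(signature)
  fcbf_genes <- as.character(fcbf_genes)
  on_platform <- sig %in% platform_genes
  if (any(!on_platform)) {
    inform(sprintf("%d in vitro signature gene(s) absent from the platform were dropped",
                   sum(!on_platform)))
  }
  sig_kept <- sig[on_platform]
  genes <- c(sig_kept, setdiff(fcbf_genes, sig_kept))
  if (length(genes) == 0L) abort("integrated feature set is empty.")
  out <- tibble(
    gene_id = genes,
    provenance = dplyr::case_when(
      genes %in% sig_kept & genes %in% fcbf_genes ~ "both",
      genes %in% sig_kept ~ "invitro",
      TRUE ~ "fcbf"
    )
  )
  class(out) <- c("integrated_feature_set", class(out))
  out
}

# stratified fold assignment: per class, samples are dealt round-robin into
# k folds after a random shuffle
stratified_folds <- function(cls, k) {
  fold <- integer(length(cls))
  for (lev in unique(cls)) {
    idx <- which(cls == lev)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Tune mtry by repeated stratified cross-validation and fit a random forest
#'
#' For every value in the mtry grid, classification accuracy is estimated
#' by repeated stratified k-fold cross-validation on the supplied training
#' data only; the mtry with the highest mean accuracy wins (ties go to the
#' smaller value). The forest is then refit on all supplied data with the
#' chosen mtry. Grid values exceeding the feature count are skipped with a
#' warning. Fully seeded: the same seed gives the same folds, tuning curve
#' and forest.
#'
#' @param x Expression table restricted to the model features (genes x
#'   samples).
#' @param labels Per-sample response (`responder`/`non_responder`), data
#'   frame or (named) vector.
#' @param n_trees Trees per forest. Default 500.
#' @param mtry_grid Candidate mtry values; default all integers
#'   `2..min(15, n_features)` (or just 1 for a single feature).
#' @param inner_folds,inner_repeats Cross-validation geometry. Defaults 5
#'   and 5.
#' @param seed Integer seed.
#' @return A list of class `tuned_forest`: `forest` (the fitted
#'   `randomForest`), `chosen_mtry`, `n_trees`, `cv_accuracy` (tibble
#'   `mtry`, `accuracy`), `feature_ids`, `classes`, `seed`.
#' @export
tune_and_train_rf <- function(x, labels, n_trees = 500, mtry_grid = NULL,
                              inner_folds = 5, inner_repeats = 5, seed = 1) {
  m <- as_expr_matrix(x)
  p <- nrow(m)
  cls <- align_labels(labels, colnames(m), col = if (is.data.frame(labels)) "response")
  if (length(unique(cls)) < 2L) abort("both classes are required for training.")
  if (is.null(mtry_grid)) {
    mtry_grid <- if (p == 1L) 1L else seq(2L, min(15L, p))
  }
  mtry_grid <- sort(unique(as.integer(mtry_grid)))
  too_big <- mtry_grid > p
  if (any(too_big)) {
    warn(sprintf("skipping mtry value(s) exceeding the %d features: %s",
                 p, paste(mtry_grid[too_big], collapse = ", ")))
    mtry_grid <- mtry_grid[!too_big]
  }
  if (length(mtry_grid) == 0L) abort("empty mtry grid after removing infeasible values.")
  X <- t(m)                                   # samples x features
  yf <- factor(cls, levels = sort(unique(cls)))
  acc <- matrix(NA_real_, nrow = inner_repeats * inner_folds,
                ncol = length(mtry_grid))
  with_seed(seed, {
    row <- 0L
    for (r in seq_len(inner_repeats)) {
      fold <- stratified_folds(cls, inner_folds)
      for (f in seq_len(inner_folds)) {
        row <- row + 1L
        te <- fold == f
        if (all(te) || length(unique(cls[!te])) < 2L) next
        for (g in seq_along(mtry_grid)) {
          fit <- randomForest::randomForest(
            x = X[!te, , drop = FALSE], y = yf[!te],
            ntree = n_trees, mtry = mtry_grid[g])
          pr <- stats::predict(fit, X[te, , drop = FALSE])
          acc[row, g] <- mean(pr == yf[te])
        }
      }
    }
  })
  mean_acc <- colMeans(acc, na.rm = TRUE)
  chosen <- mtry_grid[which.max(mean_acc)]    # which.max keeps the smaller on ties
  final <- with_seed(derive_seed(seed, "final-fit"), {
    randomForest::randomForest(x = X, y = yf, ntree = n_trees, mtry = chosen)
  })
  structure(
    list(forest = final, chosen_mtry = chosen, n_trees = n_trees,
         cv_accuracy = tibble(mtry = mtry_grid, accuracy = mean_acc),
         feature_ids = rownames(m), classes = levels(yf), seed = seed),
    class = "tuned_forest"
  )
}

# probability of response = fraction of trees voting "responder"
rf_response_prob <- function(tf, newX) {
  pr <- stats::predict(tf$forest, newX, type = "prob")
  as.numeric(pr[, "responder"])
}

#' Patient-level LOOCV of the integrative classifier
#'
#' The core evaluation loop: for each held-out patient, the training fold
#' alone is discretized, FCBF selects clinical features against the
#' response labels, the in vitro signature is fused in, and an mtry-tuned
#' random forest is trained — all without ever touching the held-out
#' column. The held-out patient is then scored, yielding one out-of-fold
#' response probability per patient. Per-fold seeds are derived from the
#' global seed and the held-out sample id, so results do not depend on
#' column order.
#'
#' @param x Standardized patient expression table.
#' @param labels Response labels (from [label_response()] or equivalent):
#'   data frame with `sample_id`, `response`, or a named vector.
#' @param signature A `signature_gene_set`, `signature_model`, or character
#'   vector of in vitro signature genes.
#' @param delta FCBF relevance threshold. Default 0.25.
#' @param n_trees,mtry_grid,inner_folds,inner_repeats Forest and tuning
#'   configuration, see [tune_and_train_rf()].
#' @param seed Global seed. Default 17.
#' @return A tibble of class `loocv_report`: `sample_id`,
#'   `prob_response`, `prob_non_response`, `predicted`, `truth`, `n_features`,
#'   `chosen_mtry`; per-fold feature sets in attribute `fold_features`.
#' @export
loocv_patients <- function(x, labels, signature, delta = 0.25,
                           n_trees = 500, mtry_grid = NULL,
                           inner_folds = 5, inner_repeats = 5, seed = 17) {
  x <- validate_expression(x)
  samples <- sample_ids(x)
  if (length(samples) < 6L) abort("patient LOOCV needs at least 6 samples.")
  cls <- align_labels(labels, samples, col = if (is.data.frame(labels)) "response")
  names(cls) <- samples
  if (length(unique(cls)) < 2L) abort("both responders and non-responders are required.")
  sig_genes <- if (inherits(signature, "signature_model")) signature$gene_set$gene_id
               else if (is.data.frame(signature)) signature$gene_id
               else as.character(signature)
  fold_features <- list()
  rows <- purrr::map(samples, function(s) {
    tr <- setdiff(samples, s)
    tr_cls <- cls[tr]
    if (length(unique(tr_cls)) < 2L) {
      abort(sprintf("training fold for '%s' lost one class entirely.", s))
    }
    train <- x[, c("gene_id", tr), drop = FALSE]
    fs <- derive_seed(seed, s)
    disc <- discretize(train)
    sel <- suppressWarnings(fcbf_select(disc, tr_cls, delta = delta))
    feats <- suppressMessages(
      build_integrated_features(sig_genes, fcbf_selected(sel), train$gene_id))
    fold_features[[s]] <<- feats
    tf <- suppressWarnings(tune_and_train_rf(
      dplyr::filter(train, .data$gene_id %in% feats$gene_id),
      tr_cls, n_trees = n_trees, mtry_grid = mtry_grid,
      inner_folds = inner_folds, inner_repeats = inner_repeats, seed = fs))
    held <- as_expr_matrix(x[, c("gene_id", s), drop = FALSE])
    newX <- t(held[tf$feature_ids, , drop = FALSE])
    p1 <- rf_response_prob(tf, newX)
    tibble(sample_id = s, prob_response = p1, prob_non_response = 1 - p1,
           predicted = ifelse(p1 > 0.5, "responder", "non_responder"),
           truth = cls[[s]], n_features = nrow(feats),
           chosen_mtry = tf$chosen_mtry)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fold_features") <- fold_features
  attr(out, "outcome") <- c(positive = "responder", negative = "non_responder")
  class(out) <- c("loocv_report", class(out))
  out
}

#' Fit the final integrative model on the complete patient cohort
#'
#' Runs FCBF on all patients, fuses the selected genes with the in vitro
#' signature, and trains the mtry-tuned random forest on the full cohort.
#' This is the model applied to external cohorts.
#'
#' @inheritParams loocv_patients
#' @return A list of class `integrated_model`: `features`
#'   (`integrated_feature_set`), `forest` (`tuned_forest`), `fcbf`
#'   (`fcbf_result`), `delta`, `seed`.
#' @export
fit_final_model <- function(x, labels, signature, delta = 0.25,
                            n_trees = 500, mtry_grid = NULL,
                            inner_folds = 5, inner_repeats = 5, seed = 17) {
  x <- validate_expression(x)
  samples <- sample_ids(x)
  cls <- align_labels(labels, samples, col = if (is.data.frame(labels)) "response")
  sig_genes <- if (inherits(signature, "signature_model")) signature$gene_set$gene_id
               else if (is.data.frame(signature)) signature$gene_id
               else as.character(signature)
  disc <- discretize(x)
  sel <- suppressWarnings(fcbf_select(disc, cls, delta = delta))
  feats <- suppressMessages(
    build_integrated_features(sig_genes, fcbf_selected(sel), x$gene_id))
  tf <- suppressWarnings(tune_and_train_rf(
    dplyr::filter(x, .data$gene_id %in% feats$gene_id), cls,
    n_trees = n_trees, mtry_grid = mtry_grid,
    inner_folds = inner_folds, inner_repeats = inner_repeats,
    seed = derive_seed(seed, "final-model")))
  structure(
    list(features = feats, forest = tf, fcbf = sel, delta = delta, seed = seed),
    class = "integrated_model"
  )
}

#' Serialize a final integrative model as a portable JSON document
#'
#' Records the integrated feature set with provenance, the chosen mtry and
#' tuning curve, forest size, and all seeds — everything needed to refit or
#' audit the model without binary serialization.
#'
#' @param model An `integrated_model`.
#' @param path Output path; `NULL` returns the JSON string.
#' @return The path (or JSON string), invisibly.
#' @export
write_final_model <- function(model, path = NULL) {
  stopifnot(inherits(model, "integrated_model"))
  doc <- list(
    features = list(gene_id = model$features$gene_id,
                    provenance = model$features$provenance),
    forest = list(chosen_mtry = model$forest$chosen_mtry,
                  n_trees = model$forest$n_trees,
                  cv_accuracy = as.list(model$forest$cv_accuracy),
                  seed = model$forest$seed),
    fcbf = list(delta = attr(model$fcbf, "delta"),
                selected = fcbf_selected(model$fcbf)),
    seed = model$seed
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}

#' Score an external cohort with a fitted integrative model
#'
#' Standardizes the cohort per gene (within the cohort), resolves the model
#' features against the cohort genes, and reports each sample's predicted
#' probability of mTOR inhibitor response (fraction of trees voting
#' responder) plus a high-response flag at the given cutoff. Model genes
#' missing from the cohort are imputed as standardized 0 when at most 20%
#' are missing; more than that is an error.
#'
#' @param model An `integrated_model` from [fit_final_model()].
#' @param cohort Expression table of the external cohort.
#' @param cutoff High-response probability cutoff. Default 0.75.
#' @param standardize Standardize the cohort per gene first. Default `TRUE`
#'   (set to `FALSE` if the cohort is already standardized).
#' @param max_missing Maximum tolerated fraction of missing model features.
#'   Default 0.2.
#' @return A tibble of class `cohort_prediction`: `sample_id`,
#'   `prob_response`, `high_response`; the cutoff is kept in attribute
#'   `cutoff`.
#' @export
score_external_cohort <- function(model, cohort, cutoff = 0.75,
                                  standardize = TRUE, max_missing = 0.2) {
  stopifnot(inherits(model, "integrated_model"))
  cohort <- validate_expression(cohort, "cohort")
  if (standardize) cohort <- suppressWarnings(standardize_genes(cohort))
  feats <- model$forest$feature_ids
  missing <- setdiff(feats, cohort$gene_id)
  if (length(missing) / length(feats) > max_missing) {
    abort(sprintf("%d of %d model features (%.0f%%) missing from the cohort.",
                  length(missing), length(feats),
                  100 * length(missing) / length(feats)))
  }
  m <- as_expr_matrix(cohort)
  X <- matrix(0, nrow = ncol(m), ncol = length(feats),
              dimnames = list(colnames(m), feats))
  present <- intersect(feats, rownames(m))
  X[, present] <- t(m[present, , drop = FALSE])
  if (length(missing) > 0L) {
    warn(sprintf("imputing standardized 0 for %d missing model feature(s)",
                 length(missing)))
  }
  p1 <- rf_response_prob(model$forest, X)
  out <- tibble(sample_id = rownames(X), prob_response = p1,
                high_response = p1 > cutoff)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("cohort_prediction", class(out))
  out
}

#' Compare predicted response probabilities across groups
#'
#' One-way ANOVA of the predicted probabilities on the group labels,
#' followed by Tukey's HSD (studentized-range) adjusted pairwise
#' comparisons, plus the per-group fraction of samples above the
#' high-response cutoff.
#'
#' @param pred A `cohort_prediction` (or any data frame with `sample_id`
#'   and `prob_response`).
#' @param groups Per-sample group labels: data frame with `sample_id`,
#'   `group`, or a (named) vector. `NULL` uses a `group` column of `pred`.
#' @param cutoff High-response cutoff for the per-group fractions; defaults
#'   to the cutoff stored in `pred`, else 0.75.
#' @return A list of class `group_comparison`: `anova` (tibble `f`, `p`,
#'   `df_between`, `df_within`), `tukey` (tibble `comparison`, `diff`,
#'   `lwr`, `upr`, `p_adj`), `group_summary` (tibble `group`, `n`,
#'   `mean_prob`, `frac_high`), `cutoff`.
#' @export
compare_groups <- function(pred, groups = NULL, cutoff = NULL) {
  stopifnot(is.data.frame(pred), all(c("sample_id", "prob_response") %in% names(pred)))
  if (is.null(groups)) {
    if (!"group" %in% names(pred)) abort("no `groups` given and `pred` has no group column.")
    g <- as.character(pred$group)
  } else {
    g <- align_labels(groups, pred$sample_id,
                      col = if (is.data.frame(groups)) "group")
  }
  if (is.null(cutoff)) cutoff <- attr(pred, "cutoff", exact = TRUE) %||% 0.75
  tab <- table(g)
  if (length(tab) < 2L) abort("at least 2 groups are required.")
  if (any(tab < 2L)) {
    abort(sprintf("singleton group(s): %s.",
                  paste(names(tab)[tab < 2L], collapse = ", ")))
  }
  dat <- data.frame(prob = pred$prob_response, group = factor(g))
  fit <- stats::aov(prob ~ group, data = dat)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$group
  out <- structure(
    list(
      anova = tibble(f = an[["F value"]][1L], p = an[["Pr(>F)"]][1L],
                     df_between = an[["Df"]][1L], df_within = an[["Df"]][2L]),
      tukey = tibble(comparison = rownames(tk), diff = tk[, "diff"],
                     lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"]),
      group_summary = dplyr::summarise(
        dplyr::group_by(tibble(prob = dat$prob, group = g), .data$group),
        n = dplyr::n(), mean_prob = mean(.data$prob),
        frac_high = mean(.data$prob > cutoff), .groups = "drop"),
      cutoff = cutoff
    ),
    class = "group_comparison"
  )
  out
}
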