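#' Select signature genes by correlation with treatment status
#'
#' Ranks genes by Pearson correlation with the binary treatment label
#' (control = 0, treated = 1) and returns a balanced signature: the
#' `n_genes / 2` genes with the most positive correlation ("up in treated")
#' and the `n_genes / 2` with the most negative ("down in treated"). Ties
#' are broken by gene id so the selection is reproducible and invariant to
#' gene and sample order.
#'
#' @param x An expression table (typically filtered and quantile
#'   normalized).
#' @param labels Per-sample condition: a data frame with `sample_id` and
#'   `condition` columns, or a (named) character vector of
#'   `"control"`/`"treated"`.
#' @param n_genes Signature size; must be even. Default 100.
#' @return A `signature_gene_set`: tibble with columns `gene_id`,
#'   `correlation`, `direction` (`up_in_treated`/`down_in_treated`),
#'   ordered up-genes by decreasing correlation then down-genes by
#'   increasing correlation.
#' @export
select_signature_genes <- function(x, labels, n_genes = 100) {
  m <- as_expr_matrix(x)
  cond <- align_labels(labels, colnames(m), col = if (is.data.frame(labels)) "condition")
  bad <- setdiff(unique(cond), c("control", "treated"))
  if (length(bad) > 0L) {
    abort(sprintf("labels must be 'control' or 'treated' (found: %s).",
                  paste(bad, collapse = ", ")))
  }
  y <- as.numeric(cond == "treated")
  if (length(unique(y)) < 2L) abort("both control and treated samples are required.")
  if (n_genes %% 2L != 0L) abort("`n_genes` must be even for a balanced up/down split.")
  if (n_genes > nrow(m)) abort("`n_genes` exceeds the number of genes.")
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0)) {
    warn(sprintf("%d constant gene(s) excluded from correlation ranking", sum(sds == 0)))
  }
  r <- rep(NA_real_, nrow(m))
  ok <- sds > 0
  r[ok] <- as.vector(stats::cor(t(m[ok, , drop = FALSE]), y))
  if (sum(ok) < n_genes) abort("too few non-constant genes for the requested signature size.")
  ids <- rownames(m)
  half <- n_genes %/% 2L
  ord_up <- order(-r, ids, na.last = TRUE)
  ord_dn <- order(r, ids, na.last = TRUE)
  up <- ord_up[seq_len(half)]
  dn <- ord_dn[seq_len(half)]
  if (length(intersect(up, dn)) > 0L) {
    abort("up and down selections overlap; reduce `n_genes`.")
  }
  out <- tibble(
    gene_id = c(ids[up], ids[dn]),
    correlation = c(r[up], r[dn]),
    direction = rep(c("up_in_treated", "down_in_treated"), each = half)
  )
  class(out) <- c("signature_gene_set", class(out))
  out
}

#' Compute SVD metagenes of a signature gene submatrix
#'
#' Centers each gene by its training mean and takes the singular value
#' decomposition of the centered genes x samples matrix. The first `k` left
#' singular vectors are the metagene loadings (unit Euclidean norm); each
#' sample's metagene scores are its projections onto those loadings
#' (equivalently the right singular vectors scaled by the singular values).
#' Each loading column's sign is fixed so its largest-magnitude entry is
#' positive, making results deterministic across linear-algebra backends.
#'
#' @param x An expression table restricted to the signature genes, already
#'   quantile normalized.
#' @param k Number of metagenes. Default 2.
#' @return A list of class `metagene_basis` with elements `gene_ids`,
#'   `loadings` (genes x k), `singular_values`, `gene_means`, and `scores`
#'   (tibble: `sample_id` + `mg1..mgk`).
#' @export
compute_metagenes <- function(x, k = 2) {
  m <- as_expr_matrix(x)
  k <- as.integer(k)
  if (k < 1L) abort("`k` must be at least 1.")
  if (k > min(dim(m))) abort("`k` exceeds min(genes, samples).")
  mu <- rowMeans(m)
  xc <- m - mu
  sv <- svd(xc, nu = k, nv = k)
  u <- sv$u[, seq_len(k), drop = FALSE]
  flip <- apply(u, 2L, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  u <- sweep(u, 2L, flip, `*`)
  scores <- t(xc) %*% u
  colnames(scores) <- paste0("mg", seq_len(k))
  rownames(u) <- rownames(m)
  structure(
    list(
      gene_ids = rownames(m),
      loadings = u,
      singular_values = sv$d[seq_len(k)],
      gene_means = mu,
      scores = dplyr::bind_cols(tibble(sample_id = colnames(m)),
                                as_tibble(scores, .name_repair = "minimal"))
    ),
    class = "metagene_basis"
  )
}

#' Project new samples onto a fitted metagene basis
#'
#' Quantile-maps each new column onto the training reference distribution,
#' restricts to the basis genes, centers by the training gene means, and
#' projects onto the loadings. This is how held-out or external samples are
#' scored without refitting.
#'
#' @param basis A `metagene_basis` from [compute_metagenes()].
#' @param reference Quantile reference saved from the training
#'   normalization (see [quantile_reference()]); its length must equal the
#'   number of genes in `new_x` used for the mapping. Pass `NULL` to skip
#'   quantile mapping (inputs already on the training scale).
#' @param new_x Expression table containing (at least) all basis genes.
#' @return Tibble of metagene scores: `sample_id` + `mg1..mgk`.
#' @export
project_new_samples <- function(basis, reference, new_x) {
  stopifnot(inherits(basis, "metagene_basis"))
  new_x <- validate_expression(new_x, "new_x")
  missing <- setdiff(basis$gene_ids, new_x$gene_id)
  if (length(missing) > 0L) {
    abort(sprintf("new samples are missing basis genes: %s",
                  paste(utils::head(missing, 10L), collapse = ", ")))
  }
  if (!is.null(reference)) {
    new_x <- quantile_normalize(new_x, reference = reference)
  }
  m <- as_expr_matrix(new_x)[basis$gene_ids, , drop = FALSE]
  scores <- t(m - basis$gene_means) %*% basis$loadings
  colnames(scores) <- paste0("mg", seq_len(ncol(scores)))
  dplyr::bind_cols(tibble(sample_id = colnames(m)),
                   as_tibble(scores, .name_repair = "minimal"))
}

#' Fit a Bayesian probit regression on metagene scores
#'
#' Binary regression of treatment status on the metagene scores using the
#' Albert-Chib latent-variable Gibbs sampler: latent `z_i ~ N(x_i' beta, 1)`
#' truncated to be positive for treated samples and negative for controls,
#' with conjugate draws of `beta` under the prior
#' `beta ~ N(0, prior_variance * I)`. An intercept is always included.
#'
#' @param scores Tibble of metagene scores (`sample_id` + `mg*` columns),
#'   as returned by [compute_metagenes()] or [project_new_samples()].
#' @param labels Per-sample condition (`control`/`treated`), data frame or
#'   (named) vector.
#' @param n_iter Total Gibbs iterations. Default 5000.
#' @param n_burn Burn-in iterations discarded. Default 1000.
#' @param prior_variance Prior variance tau^2 of the coefficients.
#'   Default 100.
#' @param seed Integer seed; identical seeds give bitwise-identical draws.
#' @return A list of class `binreg_posterior` with `draws` (a
#'   `(n_iter - n_burn) x (k + 1)` matrix, columns `(Intercept)`,
#'   `mg1..mgk`) and `config`.
#' @export
fit_binreg <- function(scores, labels, n_iter = 5000, n_burn = 1000,
                       prior_variance = 100, seed = 17) {
  stopifnot(is.data.frame(scores), "sample_id" %in% names(scores))
  mg_cols <- grep("^mg[0-9]+$", names(scores), value = TRUE)
  if (length(mg_cols) == 0L) abort("`scores` has no mg* columns.")
  X <- cbind(`(Intercept)` = 1, as.matrix(scores[, mg_cols, drop = FALSE]))
  cond <- align_labels(labels, scores$sample_id,
                       col = if (is.data.frame(labels)) "condition")
  y <- as.numeric(cond == "treated")
  if (length(unique(y)) < 2L) abort("both classes are required to fit the model.")
  if (all(apply(X[, -1L, drop = FALSE], 2L, stats::sd) == 0)) {
    abort("degenerate input: all metagene scores identical across samples.")
  }
  if (n_burn >= n_iter) abort("`n_burn` must be smaller than `n_iter`.")
  p <- ncol(X)
  V <- chol2inv(chol(crossprod(X) + diag(1 / prior_variance, p)))
  L <- t(chol(V))
  VXt <- V %*% t(X)
  n <- nrow(X)
  draws <- matrix(NA_real_, n_iter - n_burn, p,
                  dimnames = list(NULL, colnames(X)))
  with_seed(seed, {
    beta <- rep(0, p)
    for (it in seq_len(n_iter)) {
      eta <- as.vector(X %*% beta)
      # truncated-normal draws by inverse-CDF: z > 0 if treated, z < 0 if control
      lo <- ifelse(y == 1, stats::pnorm(0 - eta), 0)
      hi <- ifelse(y == 1, 1, stats::pnorm(0 - eta))
      u <- lo + stats::runif(n) * (hi - lo)
      u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
      z <- eta + stats::qnorm(u)
      mbeta <- as.vector(VXt %*% z)
      beta <- mbeta + as.vector(L %*% stats::rnorm(p))
      if (it > n_burn) draws[it - n_burn, ] <- beta
    }
  })
  if (any(!is.finite(draws))) abort("sampler produced non-finite draws.")
  structure(
    list(draws = draws,
         config = list(n_iter = n_iter, n_burn = n_burn,
                       prior_variance = prior_variance, seed = seed)),
    class = "binreg_posterior"
  )
}

#' Posterior predictive probabilities from a fitted probit model
#'
#' For each sample, evaluates `Phi(x' beta)` at every posterior draw; the
#' reported probability is the mean over draws and the 95% interval the
#' 2.5th/97.5th percentiles of the draw-level probabilities. A probability
#' near 1 indicates the treated (signature-active) state.
#'
#' @param posterior A `binreg_posterior` from [fit_binreg()].
#' @param new_scores Tibble of metagene scores (`sample_id` + `mg*`), with
#'   the same metagene dimension used at fitting.
#' @return Tibble with columns `sample_id`, `probability`, `ci_low`,
#'   `ci_high`.
#' @export
predict_binreg <- function(posterior, new_scores) {
  stopifnot(inherits(posterior, "binreg_posterior"))
  mg_cols <- grep("^mg[0-9]+$", names(new_scores), value = TRUE)
  p <- ncol(posterior$draws)
  if (length(mg_cols) != p - 1L) {
    abort(sprintf("score dimension %d does not match posterior dimension %d.",
                  length(mg_cols), p - 1L))
  }
  X <- cbind(1, as.matrix(new_scores[, mg_cols, drop = FALSE]))
  probs <- stats::pnorm(X %*% t(posterior$draws))   # samples x draws
  qs <- t(apply(probs, 1L, stats::quantile, probs = c(0.025, 0.975), names = FALSE))
  tibble(
    sample_id = new_scores$sample_id,
    probability = rowMeans(probs),
    ci_low = qs[, 1L],
    ci_high = qs[, 2L]
  )
}

#' Fit the full in vitro treatment-response signature
#'
#' Convenience wrapper running the whole in vitro stage on a filtered
#' cell-line matrix: quantile normalization, correlation-based gene
#' selection, metagene computation on the signature submatrix, and the
#' Bayesian probit fit.
#'
#' @inheritParams select_signature_genes
#' @param k Number of metagenes. Default 2.
#' @param n_iter,n_burn,prior_variance,seed Sampler configuration, see
#'   [fit_binreg()].
#' @return A list of class `signature_model` with elements `gene_set`,
#'   `basis`, `posterior`, `quantile_reference`, `universe_genes`.
#' @export
fit_signature_model <- function(x, labels, n_genes = 100, k = 2,
                                n_iter = 5000, n_burn = 1000,
                                prior_variance = 100, seed = 17) {
  xq <- quantile_normalize(x)
  ref <- quantile_reference(xq)
  gs <- select_signature_genes(xq, labels, n_genes = n_genes)
  sub <- dplyr::filter(xq, .data$gene_id %in% gs$gene_id)
  basis <- compute_metagenes(sub, k = k)
  post <- fit_binreg(basis$scores, labels, n_iter = n_iter, n_burn = n_burn,
                     prior_variance = prior_variance, seed = seed)
  structure(
    list(gene_set = gs, basis = basis, posterior = post,
         quantile_reference = ref, universe_genes = xq$gene_id),
    class = "signature_model"
  )
}

# score arbitrary samples with a fitted signature model
score_signature <- function(model, new_x) {
  stopifnot(inherits(model, "signature_model"))
  new_x <- validate_expression(new_x, "new_x")
  missing <- setdiff(model$universe_genes, new_x$gene_id)
  if (length(missing) > 0L) {
    abort(sprintf("new samples are missing %d gene(s) of the training universe.",
                  length(missing)))
  }
  full <- validate_expression(new_x)
  full <- full[match(model$universe_genes, full$gene_id), , drop = FALSE]
  sc <- project_new_samples(model$basis, model$quantile_reference, full)
  predict_binreg(model$posterior, sc)
}

#' Leave-one-out cross-validation of the cell-line signature
#'
#' For each held-out sample the signature is rebuilt from scratch on the
#' remaining samples — quantile normalization, gene selection, metagenes and
#' probit fit — and the held-out sample is projected onto the training
#' normalization and basis before prediction, so no step ever sees the
#' held-out column.
#'
#' @inheritParams fit_signature_model
#' @return A tibble of class `loocv_report` with one row per sample:
#'   `sample_id`, `probability`, `ci_low`, `ci_high`, `predicted`
#'   (`treated` if probability > 0.5), `truth`, and attribute
#'   `fold_genes` (per-fold signature gene sets).
#' @export
loocv_cell_lines <- function(x, labels, n_genes = 100, k = 2,
                             n_iter = 5000, n_burn = 1000,
                             prior_variance = 100, seed = 17) {
  x <- validate_expression(x)
  samples <- sample_ids(x)
  if (length(samples) < 4L) abort("LOOCV needs at least 4 samples.")
  cond <- align_labels(labels, samples, col = if (is.data.frame(labels)) "condition")
  names(cond) <- samples
  fold_genes <- list()
  rows <- purrr::map(samples, function(s) {
    train <- x[, c("gene_id", setdiff(samples, s)), drop = FALSE]
    tr_lab <- cond[setdiff(samples, s)]
    if (length(unique(tr_lab)) < 2L) {
      abort(sprintf("training fold for '%s' lost one class entirely.", s))
    }
    model <- fit_signature_model(train, tr_lab, n_genes = n_genes, k = k,
                                 n_iter = n_iter, n_burn = n_burn,
                                 prior_variance = prior_variance,
                                 seed = derive_seed(seed, s))
    fold_genes[[s]] <<- model$gene_set$gene_id
    pred <- score_signature(model, x[, c("gene_id", s), drop = FALSE])
    dplyr::mutate(pred,
                  predicted = ifelse(.data$probability > 0.5, "treated", "control"),
                  truth = cond[[s]])
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fold_genes") <- fold_genes
  attr(out, "outcome") <- c(positive = "treated", negative = "control")
  class(out) <- c("loocv_report", class(out))
  out
}

#' Serialize a fitted signature model to a portable JSON document
#'
#' Writes gene ids with directions and correlations, metagene loadings,
#' singular values, training gene means, a posterior summary (per-coefficient
#' mean and sd), the sampler configuration and the quantile reference, so
#' the patient pipeline (or any other consumer) can use the signature
#' without R serialization formats.
#'
#' @param model A `signature_model`.
#' @param path Output path; `NULL` returns the JSON string.
#' @return The path (or JSON string), invisibly.
#' @export
write_signature_model <- function(model, path = NULL) {
  stopifnot(inherits(model, "signature_model"))
  doc <- list(
    genes = model$gene_set$gene_id,
    direction = model$gene_set$direction,
    correlation = model$gene_set$correlation,
    metagenes = list(
      k = ncol(model$basis$loadings),
      loadings = unname(apply(model$basis$loadings, 2L, identity, simplify = FALSE)),
      singular_values = model$basis$singular_values,
      gene_means = unname(model$basis$gene_means)
    ),
    posterior = list(
      coef = colnames(model$posterior$draws),
      mean = unname(colMeans(model$posterior$draws)),
      sd = unname(apply(model$posterior$draws, 2L, stats::sd)),
      config = model$posterior$config
    ),
    quantile_reference = model$quantile_reference,
    universe_genes = model$universe_genes
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}
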