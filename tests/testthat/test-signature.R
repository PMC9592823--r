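make_labels <- function(samples, treated) {
  ifelse(samples %in% treated, "treated", "control") |> stats::setNames(samples)
}

test_that("signature gene selection matches brute-force correlation ranking", {
  withr::with_seed(21, {
    m <- matrix(rnorm(20 * 8), 20, 8,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:8)))
  })
  x <- expr_tbl(m)
  lab <- make_labels(colnames(m), paste0("s", 5:8))
  gs <- select_signature_genes(x, lab, n_genes = 4)
  y <- as.numeric(lab == "treated")
  r <- apply(m, 1, function(v) cor(v, y))
  expect_setequal(gs$gene_id[gs$direction == "up_in_treated"],
                  names(sort(r, decreasing = TRUE))[1:2])
  expect_setequal(gs$gene_id[gs$direction == "down_in_treated"],
                  names(sort(r))[1:2])
  expect_equal(gs$correlation, unname(r[gs$gene_id]))
  # direction agrees with the sign of the correlation
  expect_true(all(sign(gs$correlation[gs$direction == "up_in_treated"]) >= 0))
  expect_true(all(sign(gs$correlation[gs$direction == "down_in_treated"]) <= 0))
})

test_that("a perfectly label-correlated gene ranks first among up-genes", {
  withr::with_seed(4, {
    m <- matrix(rnorm(10 * 6), 10, 6,
                dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:6)))
  })
  lab <- make_labels(colnames(m), paste0("s", 4:6))
  m["g05", ] <- as.numeric(lab == "treated")
  gs <- select_signature_genes(expr_tbl(m), lab, n_genes = 4)
  expect_identical(gs$gene_id[1], "g05")
  expect_equal(gs$correlation[1], 1)
})

test_that("signature selection rejects bad inputs and ignores sample/gene order", {
  x <- random_expr(30, 6, seed = 8)
  lab <- make_labels(names(x)[-1], names(x)[5:7])
  expect_error(select_signature_genes(x, lab, n_genes = 5), "even")
  expect_error(select_signature_genes(x, rep("treated", 6) |>
                                        stats::setNames(names(x)[-1]), n_genes = 4),
               "both")
  gs <- select_signature_genes(x, lab, n_genes = 6)
  x_perm <- x[sample.int(nrow(x)), c("gene_id", sample(names(x)[-1]))]
  gs_perm <- select_signature_genes(x_perm, lab, n_genes = 6)
  expect_identical(gs$gene_id, gs_perm$gene_id)
  expect_equal(gs$correlation, gs_perm$correlation)
})

test_that("metagene scores match an independent eigen-decomposition oracle", {
  x <- random_expr(100, 9, seed = 42)
  b <- compute_metagenes(x, k = 2)
  m <- as_matrix_expr(x)
  xc <- m - rowMeans(m)
  e <- eigen(crossprod(xc), symmetric = TRUE)   # samples x samples Gram
  oracle <- e$vectors[, 1:2] %*% diag(sqrt(e$values[1:2]))
  got <- as.matrix(b$scores[, -1])
  for (j in 1:2) {
    expect_lt(min(max(abs(got[, j] - oracle[, j])),
                  max(abs(got[, j] + oracle[, j]))), 1e-8)
  }
  expect_equal(sqrt(colSums(b$loadings^2)), c(1, 1), ignore_attr = TRUE)
})

test_that("metagenes handle rank deficiency and permutation symmetry", {
  u <- c(1, -2, 3, 0.5); v <- c(2, -1, 0.5, 1, -0.25)
  m <- outer(u, v)
  dimnames(m) <- list(paste0("g", 1:4), paste0("s", 1:5))
  b <- compute_metagenes(expr_tbl(m), k = 2)
  expect_lt(b$singular_values[2] / b$singular_values[1], 1e-10)
  expect_lt(max(abs(b$scores$mg2)), 1e-8)

  x <- random_expr(40, 7, seed = 13)
  b1 <- compute_metagenes(x, k = 2)
  b2 <- compute_metagenes(x[rev(seq_len(nrow(x))), ], k = 2)
  for (j in c("mg1", "mg2")) {
    expect_lt(min(max(abs(b1$scores[[j]] - b2$scores[[j]])),
                  max(abs(b1$scores[[j]] + b2$scores[[j]]))), 1e-8)
  }
  expect_error(compute_metagenes(x, k = 9), "exceeds")
})

test_that("projection reproduces training scores and flags missing genes", {
  x <- random_expr(60, 8, seed = 6)
  xq <- quantile_normalize(x)
  gs_genes <- x$gene_id[1:20]
  sub <- xq[xq$gene_id %in% gs_genes, ]
  b <- compute_metagenes(sub, k = 2)
  sc <- project_new_samples(b, quantile_reference(xq), x)
  expect_equal(as.matrix(sc[, -1]), as.matrix(b$scores[, -1]), tolerance = 1e-8)
  expect_error(project_new_samples(b, quantile_reference(xq), x[-1, ]),
               "missing basis genes")
})

test_that("the probit Gibbs sampler identifies a strongly separated slope", {
  withr::with_seed(3, s <- c(rnorm(15, -3, 0.3), rnorm(15, 3, 0.3)))
  scores <- tibble::tibble(sample_id = sprintf("s%02d", 1:30), mg1 = s)
  lab <- ifelse(s > 0, "treated", "control") |> stats::setNames(scores$sample_id)
  post <- fit_binreg(scores, lab, n_iter = 2000, n_burn = 500, seed = 1)
  expect_gt(mean(post$draws[, "mg1"] > 0), 0.99)
})

test_that("posterior means agree with the probit maximum-likelihood oracle", {
  withr::with_seed(99, {
    n <- 200
    x1 <- rnorm(n); x2 <- rnorm(n)
    eta <- 0.3 + 0.8 * x1 - 0.5 * x2
    y <- rbinom(n, 1, pnorm(eta))
  })
  scores <- tibble::tibble(sample_id = sprintf("s%03d", 1:n), mg1 = x1, mg2 = x2)
  lab <- ifelse(y == 1, "treated", "control") |> stats::setNames(scores$sample_id)
  post <- fit_binreg(scores, lab, n_iter = 4000, n_burn = 1000, seed = 2)
  mle <- glm(y ~ x1 + x2, family = binomial(link = "probit"))
  est <- colMeans(post$draws)
  sds <- apply(post$draws, 2, sd)
  expect_true(all(abs(est - coef(mle)) < 3 * sds))
})

test_that("the sampler is seed-reproducible and rejects degenerate scores", {
  scores <- tibble::tibble(sample_id = paste0("s", 1:10),
                           mg1 = c(-(5:1), 1:5) / 2)
  lab <- ifelse(scores$mg1 > 0, "treated", "control") |>
    stats::setNames(scores$sample_id)
  a <- fit_binreg(scores, lab, n_iter = 500, n_burn = 100, seed = 7)
  b <- fit_binreg(scores, lab, n_iter = 500, n_burn = 100, seed = 7)
  expect_identical(a$draws, b$draws)
  c_ <- fit_binreg(scores, lab, n_iter = 500, n_burn = 100, seed = 8)
  expect_false(identical(a$draws, c_$draws))

  degen <- tibble::tibble(sample_id = paste0("s", 1:6), mg1 = rep(2, 6))
  expect_error(fit_binreg(degen, make_labels(degen$sample_id, paste0("s", 1:3))),
               "degenerate")
})

test_that("shrinking the prior variance shrinks the posterior slope monotonically", {
  withr::with_seed(31, s <- c(rnorm(10, -1), rnorm(10, 1)))
  scores <- tibble::tibble(sample_id = sprintf("s%02d", 1:20), mg1 = s)
  lab <- make_labels(scores$sample_id, sprintf("s%02d", 11:20))
  slopes <- vapply(c(100, 1, 0.01), function(tau2) {
    abs(mean(fit_binreg(scores, lab, n_iter = 3000, n_burn = 500,
                        prior_variance = tau2, seed = 5)$draws[, "mg1"]))
  }, numeric(1))
  expect_true(all(diff(slopes) < 0))
})

test_that("posterior predictions respect symmetry, interval containment and monotonicity", {
  # symmetric posterior about zero -> p = 0.5 at x = 0
  withr::with_seed(8, d <- rnorm(2000))
  post <- structure(list(draws = cbind(`(Intercept)` = c(d, -d),
                                       mg1 = rep(1, 4000)),
                         config = list(n_iter = 4000, n_burn = 0,
                                       prior_variance = 100, seed = 0)),
                    class = "binreg_posterior")
  pr <- predict_binreg(post, tibble::tibble(sample_id = "a", mg1 = 0))
  expect_equal(pr$probability, 0.5, tolerance = 1e-10)

  # containment on 100 random samples, and monotonicity in mg1 when the
  # slope draws are all positive
  withr::with_seed(12, {
    draws <- cbind(`(Intercept)` = rnorm(500, 0, 0.5), mg1 = rexp(500) + 0.1)
  })
  post2 <- structure(list(draws = draws, config = list(n_iter = 500, n_burn = 0,
                                                       prior_variance = 100,
                                                       seed = 0)),
                     class = "binreg_posterior")
  withr::with_seed(13, xs <- rnorm(100, 0, 2))
  newsc <- tibble::tibble(sample_id = sprintf("n%03d", 1:100), mg1 = xs)
  pr2 <- predict_binreg(post2, newsc)
  expect_true(all(pr2$ci_low <= pr2$probability + 1e-12))
  expect_true(all(pr2$probability <= pr2$ci_high + 1e-12))
  ord <- order(xs)
  expect_true(all(diff(pr2$probability[ord]) >= 0))
  expect_error(predict_binreg(post2, tibble::tibble(sample_id = "a", mg1 = 1, mg2 = 2)),
               "dimension")
})

test_that("fitted probabilities separate classes on separable training data", {
  withr::with_seed(19, {
    m <- matrix(rnorm(50 * 10), 50, 10,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:10)))
    m[1:10, 6:10] <- m[1:10, 6:10] + 4
  })
  lab <- make_labels(colnames(m), sprintf("s%02d", 6:10))
  model <- fit_signature_model(expr_tbl(m), lab, n_genes = 20,
                               n_iter = 2000, n_burn = 500, seed = 3)
  pred <- predict_binreg(model$posterior, model$basis$scores)
  expect_true(all(pred$probability[lab == "treated"] > 0.5))
  expect_true(all(pred$probability[lab == "control"] < 0.5))
})

test_that("doubling the chain length moves probabilities by less than 3 MC standard errors", {
  withr::with_seed(23, s <- c(rnorm(8, -0.8), rnorm(8, 0.8)))
  scores <- tibble::tibble(sample_id = sprintf("s%02d", 1:16), mg1 = s)
  lab <- make_labels(scores$sample_id, sprintf("s%02d", 9:16))
  p1 <- fit_binreg(scores, lab, n_iter = 4000, n_burn = 1000, seed = 11)
  p2 <- fit_binreg(scores, lab, n_iter = 8000, n_burn = 1000, seed = 12)
  pr1 <- predict_binreg(p1, scores)
  pr2 <- predict_binreg(p2, scores)
  # batch-means Monte-Carlo standard error of the per-sample probability
  mcse <- vapply(seq_len(nrow(scores)), function(i) {
    probs <- pnorm(cbind(1, s[i]) %*% t(p1$draws))
    bm <- colMeans(matrix(probs, nrow = 150))   # 20 batches of 150
    sd(bm) / sqrt(length(bm))
  }, numeric(1))
  expect_true(all(abs(pr1$probability - pr2$probability) < 3 * pmax(mcse, 1e-4)))
})

test_that("cell-line LOOCV has one fold per sample and never reads the held-out column", {
  withr::with_seed(33, {
    m <- matrix(rnorm(150 * 8), 150, 8,
                dimnames = list(sprintf("g%03d", 1:150), sprintf("s%02d", 1:8)))
    m[1:30, 5:8] <- m[1:30, 5:8] + 2
  })
  x <- expr_tbl(m)
  lab <- make_labels(colnames(m), sprintf("s%02d", 5:8))
  rep_ <- loocv_cell_lines(x, lab, n_genes = 20, n_iter = 1000, n_burn = 200,
                           seed = 5)
  expect_equal(nrow(rep_), 8)
  expect_setequal(rep_$sample_id, colnames(m))

  # corrupting the held-out column must not change that fold's gene set
  # or prediction pipeline inputs (only the projected score may differ)
  x2 <- x
  x2$s01 <- rev(x2$s01) * 100
  rep2 <- loocv_cell_lines(x2, lab, n_genes = 20, n_iter = 1000, n_burn = 200,
                           seed = 5)
  expect_identical(attr(rep_, "fold_genes")$s01, attr(rep2, "fold_genes")$s01)

  # a fold that loses one class entirely errors
  lab_bad <- make_labels(colnames(m), colnames(m)[-1])
  expect_error(loocv_cell_lines(x, lab_bad, n_genes = 10, n_iter = 500,
                                n_burn = 100),
               "lost one class")
})

test_that("signature models serialize to a self-contained JSON document", {
  withr::with_seed(41, {
    m <- matrix(rnorm(80 * 6), 80, 6,
                dimnames = list(sprintf("g%03d", 1:80), sprintf("s%02d", 1:6)))
    m[1:10, 4:6] <- m[1:10, 4:6] + 3
  })
  lab <- make_labels(colnames(m), sprintf("s%02d", 4:6))
  model <- fit_signature_model(expr_tbl(m), lab, n_genes = 10,
                               n_iter = 800, n_burn = 200, seed = 2)
  js <- write_signature_model(model)
  doc <- jsonlite::fromJSON(js)
  expect_identical(doc$genes, model$gene_set$gene_id)
  expect_equal(doc$metagenes$k, 2)
  expect_length(doc$posterior$mean, 3)
  expect_equal(doc$quantile_reference, model$quantile_reference)
})
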