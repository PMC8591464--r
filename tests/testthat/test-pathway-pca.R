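test_that("two identical scaled profiles give a rank-1 PCA", {
  set.seed(201)
  base <- rnorm(30)
  v <- rbind(g1 = 5 + 2 * base, g2 = -3 + 0.5 * base)
  colnames(v) <- sprintf("s%02d", 1:30)
  expr <- expression_matrix(v, kind = "continuous")
  fit <- fit_pathway_pca(expr, c("g1", "g2"))
  expect_equal(fit$model$variance_explained, 1, tolerance = 1e-12)
  expect_equal(abs(unname(fit$model$loadings)), rep(1 / sqrt(2), 2),
               tolerance = 1e-12)
})

test_that("variance explained equals the score-variance identity and components are orthonormal", {
  expr <- make_expr(10, 50, seed = 202)
  fit <- fit_pathway_pca(expr, expr$gene_ids)
  z <- scale(t(expr$values))
  total_var <- sum(apply(z, 2, var))
  expect_equal(fit$model$variance_explained,
               var(fit$scores$pc1) / total_var, tolerance = 1e-10)
  expect_equal(sum(fit$model$variance_explained_all), 1, tolerance = 1e-12)
  rot <- fit$model$all_loadings
  expect_equal(crossprod(rot), diag(ncol(rot)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sqrt(sum(fit$model$loadings^2)), 1, tolerance = 1e-12)
})

test_that("sign orientation against a covariate forces negative correlation", {
  set.seed(203)
  for (seed in 1:5) {
    expr <- make_expr(8, 40, seed = 300 + seed)
    covar <- rnorm(40) + colMeans(expr$values)
    fit <- fit_pathway_pca(expr, expr$gene_ids, orient_against = covar)
    expect_lte(cor(fit$scores$pc1, covar), 0)
    expect_identical(fit$model$sign_anchor,
                     "negative_correlation_with_anchor")
  }
})

test_that("a designed one-factor structure recovers its variance-explained", {
  # common factor tuned so PC1 captures ~45% of the scaled variance
  k <- 10
  a <- (0.45 * k - 1) / (k - 1)    # pairwise correlation achieving 45%
  errs <- vapply(1:20, function(seed) {
    set.seed(400 + seed)
    n <- 120
    f <- rnorm(n)
    v <- t(vapply(1:k, function(g) {
      sqrt(a) * f + sqrt(1 - a) * rnorm(n)
    }, numeric(n)))
    rownames(v) <- sprintf("g%02d", 1:k)
    colnames(v) <- sprintf("s%03d", 1:n)
    expr <- expression_matrix(v, kind = "continuous")
    fit_pathway_pca(expr, rownames(v))$model$variance_explained - 0.45
  }, 0)
  expect_lt(abs(mean(errs)), 0.05)
})

test_that("constant genes are dropped with a warning and full absence errors", {
  v <- rbind(g1 = rnorm(20), g2 = rep(3, 20), g3 = rnorm(20))
  colnames(v) <- sprintf("s%02d", 1:20)
  expr <- expression_matrix(v, kind = "continuous")
  expect_warning(fit <- fit_pathway_pca(expr, c("g1", "g2", "g3")),
                 "constant")
  expect_identical(fit$model$dropped_genes, "g2")
  expect_identical(fit$model$gene_ids, c("g1", "g3"))
  expect_error(fit_pathway_pca(expr, c("zz1", "zz2")), "none of the")
})

test_that("translation matches reference moments and is idempotent", {
  expr <- make_expr(12, 40, seed = 204)
  fit <- fit_pathway_pca(expr, expr$gene_ids)
  # self-translation: identity on moments
  self_tr <- translate_cohort(expr, fit$model)
  expect_equal(rowMeans(self_tr$values), fit$model$ref_means,
               tolerance = 1e-12)
  expect_equal(apply(self_tr$values, 1, sd), fit$model$ref_sds,
               tolerance = 1e-12)

  # arbitrary target: post-transform moments equal the reference
  target <- make_expr(12, 80, seed = 205)
  target$values <- target$values * 3 + 40     # different platform scale
  tr <- translate_cohort(target, fit$model)
  expect_equal(rowMeans(tr$values), fit$model$ref_means, tolerance = 1e-10)
  expect_equal(apply(tr$values, 1, sd), fit$model$ref_sds,
               tolerance = 1e-10)

  # translate of a translate changes nothing
  tr2 <- translate_cohort(tr, fit$model)
  expect_equal(tr2$values, tr$values, tolerance = 1e-10)
})

test_that("projection round-trips the training cohort and centers at the reference mean", {
  expr <- make_expr(9, 35, seed = 206)
  fit <- fit_pathway_pca(expr, expr$gene_ids)
  proj <- project_pathway(expr, fit$model)
  expect_equal(proj$pc1, fit$scores$pc1, tolerance = 1e-10)

  # a sample sitting exactly at the reference means scores 0
  at_mean <- expression_matrix(
    matrix(fit$model$ref_means, ncol = 1,
           dimnames = list(fit$model$gene_ids, "m1")),
    kind = "continuous")
  expect_equal(project_pathway(at_mean, fit$model)$pc1, 0,
               tolerance = 1e-12)
})

test_that("missing target genes renormalize the loadings with a warning", {
  expr <- make_expr(8, 30, seed = 207)
  fit <- fit_pathway_pca(expr, expr$gene_ids)
  sub <- expression_matrix(expr$values[-1, ], expr$gene_ids[-1],
                           expr$sample_ids, kind = "continuous")
  expect_warning(tr <- translate_cohort(sub, fit$model), "absent")
  expect_warning(pr <- project_pathway(tr, fit$model), "renormalized")
  expect_true(all(is.finite(pr$pc1)))
  expect_error(translate_cohort(
    expression_matrix(expr$values[1, , drop = FALSE], expr$gene_ids[1],
                      expr$sample_ids, kind = "continuous"),
    fit$model), "fewer than 2")
})

test_that("cross-cohort projection recovers a shared latent factor", {
  cors <- vapply(1:5, function(seed) {
    set.seed(500 + seed)
    k <- 15; n1 <- 80; n2 <- 100
    lam <- runif(k, 0.6, 1)
    f1 <- rnorm(n1); f2 <- rnorm(n2)
    mk <- function(f, n, scale_shift) {
      v <- t(sapply(seq_len(k), function(g) {
        scale_shift[1] * (lam[g] * f + 0.5 * rnorm(n)) + scale_shift[2]
      }))
      rownames(v) <- sprintf("g%02d", seq_len(k))
      colnames(v) <- sprintf("s%03d", seq_len(n))
      expression_matrix(v, kind = "continuous")
    }
    ref <- mk(f1, n1, c(1, 0))
    tgt <- mk(f2, n2, c(5, 20))      # other platform: gain and offset
    fit <- fit_pathway_pca(ref, ref$gene_ids)
    pr <- project_pathway(translate_cohort(tgt, fit$model), fit$model)
    abs(cor(pr$pc1, f2))
  }, 0)
  expect_true(all(cors >= 0.9))
})

test_that("pathway model JSON serialization round-trips", {
  expr <- make_expr(6, 25, seed = 208)
  fit <- fit_pathway_pca(expr, expr$gene_ids)
  path <- withr::local_tempfile(fileext = ".json")
  write_pca_model(fit$model, path)
  back <- read_pca_model(path)
  expect_equal(back$loadings, fit$model$loadings, tolerance = 1e-12)
  expect_equal(back$ref_means, fit$model$ref_means, tolerance = 1e-12)
  pr <- project_pathway(expr, back)
  expect_equal(pr$pc1, fit$scores$pc1, tolerance = 1e-10)
})
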