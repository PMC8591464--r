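# Pathway PCA: condense a gene set's expression into a first principal
# component and carry the model to a second cohort by per-gene moment
# matching.

#' Fit a pathway PCA model on a reference cohort
#'
#' Z-scales each member gene with its training mean/SD (n-1 denominator),
#' eigendecomposes the sample covariance of the scaled data, and keeps unit-
#' norm loadings. PC1 is used as a one-number pathway activity score. The
#' PCA sign is arbitrary; if `orient_against` is supplied, loadings are
#' flipped so that PC1 correlates negatively with it (the convention here:
#' higher pathway score opposes the anchoring covariate); otherwise the
#' largest-magnitude loading is made positive. Constant genes cannot be
#' scaled and are dropped with a warning.
#'
#' @param expr a continuous [expression_matrix()].
#' @param gene_set character vector of member gene ids.
#' @param orient_against optional numeric covariate (e.g. CPE) used to fix
#'   the PC1 sign.
#' @return A list with `model` (class `pathway_pca_model`: `gene_ids`,
#'   `ref_means`, `ref_sds`, `loadings` for PC1, `all_loadings`,
#'   `variance_explained`, per-component `variance_explained_all`,
#'   `sign_anchor`, `dropped_genes`, `train_score_sd`) and `scores` (class
#'   `pathway_scores`: `sample_ids`, `pc1`).
#' @export
fit_pathway_pca <- function(expr, gene_set, orient_against = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  present <- intersect(gene_set, expr$gene_ids)
  if (length(present) == 0L)
    stop("none of the gene set members are in the expression matrix")
  n <- length(expr$sample_ids)
  if (n <= 2L) stop("need more than 2 samples")
  x <- t(expr$values[present, , drop = FALSE])   # samples x genes
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  dropped <- present[sdv == 0]
  if (length(dropped)) {
    warning("dropping constant gene(s): ", paste(dropped, collapse = ", "))
    keep <- sdv > 0
    x <- x[, keep, drop = FALSE]
    mu <- mu[keep]
    sdv <- sdv[keep]
    present <- present[keep]
  }
  if (length(present) < 2L) stop("fewer than 2 usable member genes")
  z <- sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ve_all <- pc$sdev^2 / sum(pc$sdev^2)
  loadings <- pc$rotation[, 1L]
  scores1 <- as.vector(z %*% loadings)
  sign_anchor <- "largest_loading_positive"
  if (!is.null(orient_against)) {
    if (length(orient_against) != n)
      stop("orient_against length must match sample count")
    r <- suppressWarnings(stats::cor(scores1, orient_against))
    if (is.finite(r) && r > 0) {
      loadings <- -loadings
      scores1 <- -scores1
      pc$rotation <- -pc$rotation
    }
    sign_anchor <- "negative_correlation_with_anchor"
  } else if (loadings[which.max(abs(loadings))] < 0) {
    loadings <- -loadings
    scores1 <- -scores1
    pc$rotation[, 1L] <- -pc$rotation[, 1L]
  }
  model <- structure(
    list(gene_ids = present,
         ref_means = stats::setNames(mu, present),
         ref_sds = stats::setNames(sdv, present),
         loadings = stats::setNames(loadings, present),
         all_loadings = pc$rotation,
         variance_explained = ve_all[1L],
         variance_explained_all = ve_all,
         sign_anchor = sign_anchor,
         dropped_genes = dropped,
         train_score_sd = stats::sd(scores1)),
    class = "pathway_pca_model")
  scores <- structure(list(sample_ids = expr$sample_ids, pc1 = scores1),
                      class = "pathway_scores")
  list(model = model, scores = scores)
}

#' @export
print.pathway_pca_model <- function(x, ...) {
  cat(sprintf(
    "pathway_pca_model: %d genes, PC1 explains %.1f%% of scaled variance\n",
    length(x$gene_ids), 100 * x$variance_explained))
  invisible(x)
}

#' Translate a second cohort onto the reference expression scale
#'
#' For each model gene present in the target cohort, linearly rescales the
#' target expression to the reference cohort's per-gene mean and variance:
#' `y' = (y - mean_target) / sd_target * ref_sd + ref_mean`. This makes a
#' cohort measured on a different platform (e.g. microarray vs RNA-seq)
#' directly projectable with the reference PCA loadings. Genes that are
#' constant in the target cannot be rescaled and are set to the reference
#' mean (flagged); model genes absent from the target are recorded so the
#' projection can renormalize.
#'
#' @param target_expr a continuous [expression_matrix()].
#' @param model a `pathway_pca_model`.
#' @return An `expression_matrix` restricted to the shared model genes, with
#'   attributes `missing_genes` and `constant_genes`.
#' @export
translate_cohort <- function(target_expr, model) {
  stopifnot(inherits(model, "pathway_pca_model"))
  shared <- intersect(model$gene_ids, target_expr$gene_ids)
  if (length(shared) < 2L)
    stop("target cohort shares fewer than 2 model genes")
  missing <- setdiff(model$gene_ids, shared)
  if (length(missing))
    warning("model gene(s) absent from target: ",
            paste(missing, collapse = ", "))
  y <- target_expr$values[shared, , drop = FALSE]
  mu_t <- rowMeans(y)
  sd_t <- apply(y, 1L, stats::sd)
  const <- shared[sd_t == 0]
  if (length(const))
    warning("constant gene(s) in target set to reference mean: ",
            paste(const, collapse = ", "))
  out <- y
  ok <- sd_t > 0
  out[ok, ] <- (y[ok, , drop = FALSE] - mu_t[ok]) / sd_t[ok] *
    model$ref_sds[shared][ok] + model$ref_means[shared][ok]
  out[!ok, ] <- model$ref_means[shared][!ok]
  res <- expression_matrix(out, shared, target_expr$sample_ids,
                           kind = "continuous")
  attr(res, "missing_genes") <- missing
  attr(res, "constant_genes") <- const
  res
}

#' Project a (translated) cohort onto the reference PC1
#'
#' Centers by the reference means, scales by the reference SDs, and takes
#' the dot product with the PC1 loadings. When model genes are missing from
#' the target the remaining loadings are renormalized to unit norm, which
#' keeps the score scale comparable rather than biasing scores toward zero.
#'
#' @param target_expr an `expression_matrix` on the reference scale
#'   (typically from [translate_cohort()]).
#' @param model a `pathway_pca_model`.
#' @param standardize_by_train if TRUE, divide scores by the training-score
#'   SD.
#' @return A `pathway_scores` list (`sample_ids`, `pc1`).
#' @export
project_pathway <- function(target_expr, model,
                            standardize_by_train = FALSE) {
  stopifnot(inherits(model, "pathway_pca_model"))
  shared <- intersect(model$gene_ids, target_expr$gene_ids)
  if (length(shared) < 2L)
    stop("target cohort shares fewer than 2 model genes")
  load <- model$loadings[shared]
  if (length(shared) < length(model$gene_ids)) {
    warning(sprintf("projecting on %d of %d model genes (renormalized)",
                    length(shared), length(model$gene_ids)))
    load <- load / sqrt(sum(load^2))
  }
  z <- (target_expr$values[shared, , drop = FALSE] -
          model$ref_means[shared]) / model$ref_sds[shared]
  sc <- as.vector(t(z) %*% load)
  if (standardize_by_train) sc <- sc / model$train_score_sd
  structure(list(sample_ids = target_expr$sample_ids, pc1 = sc),
            class = "pathway_scores")
}

#' Serialize / deserialize a pathway PCA model as JSON
#'
#' @param model a `pathway_pca_model`.
#' @param path JSON file path.
#' @export
write_pca_model <- function(model, path) {
  obj <- list(gene_ids = model$gene_ids,
              ref_means = unname(model$ref_means),
              ref_sds = unname(model$ref_sds),
              loadings = unname(model$loadings),
              variance_explained = model$variance_explained,
              sign_anchor = model$sign_anchor,
              train_score_sd = model$train_score_sd)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(gene_ids = obj$gene_ids,
         ref_means = stats::setNames(obj$ref_means, obj$gene_ids),
         ref_sds = stats::setNames(obj$ref_sds, obj$gene_ids),
         loadings = stats::setNames(obj$loadings, obj$gene_ids),
         all_loadings = NULL,
         variance_explained = obj$variance_explained,
         variance_explained_all = NULL,
         sign_anchor = obj$sign_anchor,
         dropped_genes = character(0),
         train_score_sd = obj$train_score_sd),
    class = "pathway_pca_model")
}
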