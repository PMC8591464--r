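# Discovery and validation orchestration: CPE -> gene ranking -> GSEA ->
# pathway selection -> PCA -> penalized survival models, and the
# cross-cohort validation arm (translate -> project -> Cox).

#' Run the discovery analysis
#'
#' Executes the discovery arm end to end: standardize CPE, transform counts
#' to log-CPM, rank genes against CPE, score the gene set collection by
#' permutation GSEA, select the top pathway (maximal NES among sets passing
#' the FDR threshold; ties broken by higher leading-edge fraction, then set
#' name), condense it to a PC1 pathway score oriented negatively against
#' CPE, and fit the three adjusted survival models (CPE only, PC1 only,
#' both). If no set passes the FDR threshold the survival stages are
#' skipped and the report says so.
#'
#' Pathway selection is by association strength regardless of direction
#' (`select_by = "abs_nes"`, the default): a set whose members sit at the
#' bottom of the ranking (negative NES, expression decreasing with CPE) is
#' as much a discovery as one at the top. Set `select_by = "nes"` to
#' restrict selection to positively enriched sets.
#'
#' @param counts a counts [expression_matrix()].
#' @param clinical a [clinical_table()] aligned with the expression samples.
#' @param cpe raw CPE values, one per sample.
#' @param collection a [gene_set_collection()].
#' @param n_perm,scheme,weight_exponent,min_set_size,max_set_size,moderation
#'   GSEA options, see [run_gsea()].
#' @param fdr_threshold FDR significance threshold for pathway selection.
#' @param select_by `"abs_nes"` (default) or `"nes"`: selection statistic
#'   among FDR-passing sets.
#' @param penalize survival penalization, `"firth"` (default) or `"none"`.
#' @param seed integer seed controlling the permutation null.
#' @param out_dir optional directory for report files (JSON report, TSV
#'   tables).
#' @return A `run_report` list: `parameters`, `cpe_summary`, `gsea_table`,
#'   `selected_set`, `pca` (model + variance explained + PC1-CPE
#'   correlation), `models` (three `cox_fit`s), `warnings`.
#' @export
run_discovery <- function(counts, clinical, cpe, collection,
                          n_perm = 1000, scheme = "response",
                          weight_exponent = 1, min_set_size = 5,
                          max_set_size = 500, moderation = "none",
                          fdr_threshold = 0.25, select_by = c("abs_nes",
                                                              "nes"),
                          penalize = "firth", seed = 1, out_dir = NULL) {
  select_by <- match.arg(select_by)
  stopifnot(fdr_threshold >= 0, fdr_threshold < 1 || fdr_threshold == 1)
  if (length(cpe) != length(counts$sample_ids))
    stop("cpe length must match sample count")
  notes <- character(0)
  cpe_z <- standardize(cpe)
  logcpm <- log_cpm(counts)
  gsea_res <- run_gsea(logcpm, as.numeric(cpe_z), collection,
                       n_perm = n_perm, scheme = scheme, seed = seed,
                       weight_exponent = weight_exponent,
                       min_set_size = min_set_size,
                       max_set_size = max_set_size,
                       moderation = moderation)
  passing <- gsea_res[is.finite(gsea_res$fdr_q) &
                        gsea_res$fdr_q < fdr_threshold, ]
  report <- list(
    parameters = list(n_samples = length(cpe), n_genes =
                        length(counts$gene_ids),
                      n_perm = n_perm, scheme = scheme,
                      weight_exponent = weight_exponent,
                      min_set_size = min_set_size,
                      max_set_size = max_set_size,
                      moderation = moderation,
                      fdr_threshold = fdr_threshold,
                      penalize = penalize, seed = seed),
    cpe_summary = list(median = stats::median(cpe),
                       range = range(cpe),
                       mean = attr(cpe_z, "center"),
                       sd = attr(cpe_z, "scale")),
    gsea_table = as.data.frame(gsea_res),
    selected_set = NULL, pca = NULL, models = NULL)
  if (nrow(passing) == 0L) {
    notes <- c(notes, sprintf(
      "no gene set passes FDR < %g; survival stages skipped",
      fdr_threshold))
    report$warnings <- notes
    class(report) <- "run_report"
    if (!is.null(out_dir)) write_report(report, out_dir)
    return(report)
  }
  key <- if (select_by == "abs_nes") abs(passing$nes) else passing$nes
  sel <- passing[order(-key, -passing$leading_edge,
                       passing$set_name), ][1L, ]
  filtered <- attr(gsea_res, "collection")
  members <- filtered$sets[[sel$set_name]]
  pca <- fit_pathway_pca(logcpm, members, orient_against = as.numeric(cpe_z))
  pc1_z <- standardize(pca$scores$pc1)
  pc1_cpe <- pearson_with_ci(pca$scores$pc1, as.numeric(cpe_z))
  models <- list(
    cpe_only = fit_paper_models(clinical, cpe = as.numeric(cpe_z),
                                which = "cpe_only", penalize = penalize),
    pc1_only = fit_paper_models(clinical, pc1 = as.numeric(pc1_z),
                                which = "pc1_only", penalize = penalize),
    both = fit_paper_models(clinical, cpe = as.numeric(cpe_z),
                            pc1 = as.numeric(pc1_z), which = "both",
                            penalize = penalize))
  report$selected_set <- list(
    set_name = sel$set_name, nes = sel$nes, fdr_q = sel$fdr_q,
    es = sel$es, max_es_at = sel$max_es_at,
    leading_edge = sel$leading_edge, n_passing = nrow(passing))
  report$pca <- list(model = pca$model,
                     variance_explained = pca$model$variance_explained,
                     pc1_cpe_correlation = pc1_cpe,
                     scores = pca$scores,
                     pc1_standardized = as.numeric(pc1_z))
  report$models <- models
  report$warnings <- notes
  class(report) <- "run_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Run the validation analysis on an independent cohort
#'
#' Translates the validation cohort's expression onto the reference scale
#' per gene (mean/variance matching), projects it with the reference PC1
#' loadings, standardizes the score within the validation cohort, and fits
#' the adjusted survival model with PC1 (unpenalized by default, suitable
#' for large cohorts).
#'
#' @param expr continuous [expression_matrix()] of the validation cohort.
#' @param clinical a [clinical_table()] for the validation cohort.
#' @param model a `pathway_pca_model` fitted on the discovery cohort.
#' @param penalize `"none"` (default) or `"firth"`.
#' @param min_gene_overlap minimal number of model genes that must be
#'   present in the validation cohort.
#' @param out_dir optional report directory.
#' @return A `run_report` with `pc1` scores and the fitted model.
#' @export
run_validation <- function(expr, clinical, model, penalize = "none",
                           min_gene_overlap = 2, out_dir = NULL) {
  shared <- intersect(model$gene_ids, expr$gene_ids)
  if (length(shared) < min_gene_overlap)
    stop(sprintf("gene overlap %d below floor %d", length(shared),
                 min_gene_overlap))
  translated <- translate_cohort(expr, model)
  scores <- project_pathway(translated, model)
  pc1_z <- standardize(scores$pc1)
  fit <- fit_paper_models(clinical, pc1 = as.numeric(pc1_z),
                          which = "pc1_only", penalize = penalize)
  report <- list(
    parameters = list(n_samples = length(expr$sample_ids),
                      gene_overlap = length(shared),
                      penalize = penalize),
    pc1 = list(scores = scores, standardized = as.numeric(pc1_z)),
    models = list(pc1_only = fit),
    warnings = character(0))
  class(report) <- "run_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a run report to disk
#'
#' Emits a machine-readable JSON report plus TSV tables (GSEA results,
#' model coefficient tables) in the standard layout.
#'
#' @param report a `run_report`.
#' @param dir output directory, created if absent.
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(report$gsea_table))
    utils::write.table(report$gsea_table, file.path(dir, "gsea.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(report$models)) {
    write_model_table(report$models[[nm]],
                      path_tsv = file.path(dir,
                                           sprintf("model_%s.tsv", nm)))
  }
  if (!is.null(report$pca))
    write_pca_model(report$pca$model, file.path(dir, "pca_model.json"))
  js <- list(parameters = report$parameters,
             cpe_summary = report$cpe_summary,
             selected_set = report$selected_set,
             warnings = report$warnings)
  if (!is.null(report$pca)) {
    js$pca <- list(variance_explained = report$pca$variance_explained,
                   pc1_cpe_correlation =
                     unclass(report$pca$pc1_cpe_correlation))
  }
  if (!is.null(report$models)) {
    js$models <- lapply(report$models, function(f) {
      list(penalized = f$penalized, converged = f$converged,
           n = f$n, n_events = f$n_events, terms = f$terms)
    })
  }
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  if (!is.null(x$selected_set)) {
    cat(sprintf("  selected set: %s (NES %.2f, FDR %.3f, LE %.0f%%)\n",
                x$selected_set$set_name, x$selected_set$nes,
                x$selected_set$fdr_q,
                100 * x$selected_set$leading_edge))
  } else if (!is.null(x$gsea_table)) {
    cat("  no gene set passed the FDR threshold\n")
  }
  if (!is.null(x$pca))
    cat(sprintf("  PC1: %.0f%% variance explained, cor with CPE %.3f\n",
                100 * x$pca$variance_explained,
                x$pca$pc1_cpe_correlation$r))
  for (nm in names(x$models)) {
    f <- x$models[[nm]]
    pred <- f$terms[f$terms$term %in% c("cpe", "pc1"), ]
    for (i in seq_len(nrow(pred)))
      cat(sprintf("  model %s: %s HR %.2f (%.2f, %.2f), p = %.3f\n", nm,
                  pred$term[i], pred$hr[i], pred$ci_low[i],
                  pred$ci_high[i], pred$p[i]))
  }
  if (length(x$warnings)) cat("  notes:", paste(x$warnings, collapse = "; "),
                              "\n")
  invisible(x)
}
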