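#' Clinical / survival table
#'
#' Validates the clinical table the survival models consume. Columns:
#' `sample_id`, `age` (years), `size_mm`, `grade` (1/2/3), `axillary_load`
#' ("0", "1-3", "4+"), `ast` ("yes"/"no"), `time` (> 0), `event` (0/1).
#' Rows with any missing value are dropped (complete-case analysis; no
#' imputation) and counted in attribute `n_dropped`.
#'
#' @param df data.frame with the columns above.
#' @return A `clinical_table` data.frame with `grade`, `axillary_load`,
#'   `ast` as factors at their reference levels.
#' @export
clinical_table <- function(df) {
  needed <- c("sample_id", "age", "size_mm", "grade", "axillary_load",
              "ast", "time", "event")
  miss <- setdiff(needed, colnames(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, needed]
  complete <- stats::complete.cases(df)
  n_dropped <- sum(!complete)
  if (n_dropped) {
    message(n_dropped, " incomplete row(s) dropped (complete-case)")
    df <- df[complete, , drop = FALSE]
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  if (!all(df$grade %in% c(1, 2, 3))) stop("grade must be 1, 2 or 3")
  if (!all(df$axillary_load %in% c("0", "1-3", "4+")))
    stop("axillary_load must be one of '0', '1-3', '4+'")
  if (!all(df$ast %in% c("yes", "no"))) stop("ast must be 'yes' or 'no'")
  if (any(df$time <= 0)) stop("time must be > 0")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  df$grade <- factor(df$grade, levels = c(1, 2, 3))
  df$axillary_load <- factor(df$axillary_load, levels = c("0", "1-3", "4+"))
  df$ast <- factor(df$ast, levels = c("no", "yes"))
  attr(df, "n_dropped") <- n_dropped
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a clinical CSV
#'
#' @param path CSV with the [clinical_table()] columns.
#' @return A `clinical_table`.
#' @export
read_clinical_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(axillary_load = "character"))
  clinical_table(df)
}

#' Construct covariate combining adjuvant systemic therapy and nodal status
#'
#' Axillary load and AST are strongly correlated; modelling them jointly as
#' one four-level factor (the "construct" covariate) avoids the collinearity
#' of separate terms. Nodal status collapses axillary load to any-positive:
#' node+ iff `axillary_load != "0"`. Reference level: no AST with no
#' positive nodes.
#'
#' @param ast "yes"/"no" vector (or factor).
#' @param axillary_load "0"/"1-3"/"4+" vector (or factor).
#' @return Factor with levels `noAST/node-`, `AST/node-`, `noAST/node+`,
#'   `AST/node+`.
#' @export
make_construct <- function(ast, axillary_load) {
  ast <- as.character(ast)
  axillary_load <- as.character(axillary_load)
  if (!all(ast %in% c("yes", "no"))) stop("unknown ast value")
  if (!all(axillary_load %in% c("0", "1-3", "4+")))
    stop("unknown axillary_load category")
  node_pos <- axillary_load != "0"
  lev <- c("noAST/node-", "AST/node-", "noAST/node+", "AST/node+")
  lab <- ifelse(ast == "yes",
                ifelse(node_pos, "AST/node+", "AST/node-"),
                ifelse(node_pos, "noAST/node+", "noAST/node-"))
  factor(lab, levels = lev)
}

#' Build the adjusted design matrix used by the survival models
#'
#' Age, tumor size, tumor grade (two indicators, grade 1 reference) and the
#' [make_construct()] factor (three indicators).
#'
#' @param clinical a `clinical_table`.
#' @return Numeric matrix with named columns.
#' @export
survival_design <- function(clinical) {
  construct <- make_construct(clinical$ast, clinical$axillary_load)
  m <- cbind(
    age = clinical$age,
    size_mm = clinical$size_mm,
    grade2 = as.numeric(clinical$grade == 2),
    grade3 = as.numeric(clinical$grade == 3),
    `AST/node-` = as.numeric(construct == "AST/node-"),
    `noAST/node+` = as.numeric(construct == "noAST/node+"),
    `AST/node+` = as.numeric(construct == "AST/node+"))
  rownames(m) <- clinical$sample_id
  m
}

#' Fit the adjusted survival models with CPE and/or the pathway score
#'
#' Fits a multivariable proportional-hazards model adjusted for age, tumor
#' size, grade and the AST-by-nodal-status construct, plus the requested
#' standardized predictor(s): CPE only, PC1 only, or both. Firth
#' penalization is on by default (appropriate when events are few); hazard
#' ratios for CPE and PC1 are per SD unit because the inputs are
#' standardized.
#'
#' @param clinical a [clinical_table()].
#' @param cpe standardized CPE vector aligned with `clinical$sample_id`
#'   (required unless `which = "pc1_only"`).
#' @param pc1 standardized pathway score vector (required unless
#'   `which = "cpe_only"`).
#' @param which `"cpe_only"`, `"pc1_only"` or `"both"`.
#' @param penalize,ci passed to [cox_fit()].
#' @return A `cox_fit`.
#' @export
fit_paper_models <- function(clinical, cpe = NULL, pc1 = NULL,
                             which = c("cpe_only", "pc1_only", "both"),
                             penalize = "firth", ci = "wald") {
  which <- match.arg(which)
  design <- survival_design(clinical)
  n <- nrow(design)
  add <- function(design, v, nm) {
    if (is.null(v)) stop("predictor '", nm, "' required for model ", which)
    if (length(v) != n) stop(nm, " length must match clinical rows")
    cbind(design, stats::setNames(data.frame(as.numeric(v)), nm))
  }
  if (which %in% c("cpe_only", "both"))
    design <- add(design, cpe, "cpe")
  if (which %in% c("pc1_only", "both"))
    design <- add(design, pc1, "pc1")
  cox_fit(as.matrix(design), clinical$time, clinical$event,
          penalize = penalize, ci = ci)
}

#' Write a fitted model table in the standard report layout
#'
#' @param fit a `cox_fit`.
#' @param path_tsv,path_json optional output paths.
#' @return The terms data.frame, invisibly.
#' @export
write_model_table <- function(fit, path_tsv = NULL, path_json = NULL) {
  tab <- fit$terms[, c("term", "beta", "hr", "ci_low", "ci_high", "p")]
  if (!is.null(path_tsv))
    utils::write.table(tab, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(list(penalized = fit$penalized, n = fit$n,
                              n_events = fit$n_events,
                              converged = fit$converged, terms = tab),
                         path_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(tab)
}
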