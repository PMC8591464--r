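#' Rank genes by the strength of their association with CPE
#'
#' Regresses each gene's expression on the (standardized) CPE vector by
#' simple least squares and summarizes the association with the t statistic
#' t = slope / se. Optionally an empirical-Bayes variance moderation shrinks
#' the per-gene residual variances toward their trimmed mean with `prior_df`
#' pseudo-observations before forming t, which stabilizes the ranking when
#' sample sizes are small. Genes are ordered by t descending; ties are broken
#' by gene id so output files are deterministic.
#'
#' @param expr a continuous [expression_matrix()] (e.g. from [log_cpm()]).
#' @param cpe numeric vector aligned with `expr$sample_ids` (names, if
#'   present, are checked against the sample ids).
#' @param moderation `"none"` for the plain OLS t, `"empirical_bayes"` for
#'   moderated t.
#' @param prior_df prior degrees of freedom for the moderation.
#' @return A `ranked_gene_list`: data.frame with columns `gene_id`, `slope`,
#'   `se`, `t`, `rank`, `zero_variance`, ordered by `t` descending.
#' @export
gene_cpe_ranking <- function(expr, cpe,
                             moderation = c("none", "empirical_bayes"),
                             prior_df = 4) {
  moderation <- match.arg(moderation)
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$kind != "continuous")
    stop("ranking expects continuous expression; transform counts first")
  n <- length(expr$sample_ids)
  if (length(cpe) != n) stop("cpe length must match sample count")
  if (!is.null(names(cpe)) && !identical(names(cpe), expr$sample_ids))
    stop("cpe names do not match expression sample ids")
  if (n < 4L) stop("need at least 4 samples")
  if (!all(is.finite(cpe))) stop("cpe must be finite")
  x <- as.numeric(cpe) - mean(cpe)
  sxx <- sum(x^2)
  if (sxx == 0) stop("zero-variance CPE")

  y <- expr$values
  slope <- as.vector(y %*% x) / sxx
  ybar <- rowMeans(y)
  ss_tot <- rowSums(y^2) - n * ybar^2
  ss_res <- pmax(ss_tot - slope^2 * sxx, 0)
  df <- n - 2L
  s2 <- ss_res / df

  zero_var <- ss_tot <= .Machine$double.eps * n * pmax(ybar^2, 1)
  if (moderation == "empirical_bayes") {
    pos <- s2[!zero_var & s2 > 0]
    s2_prior <- if (length(pos)) mean(pos, trim = 0.1) else 0
    s2_post <- (prior_df * s2_prior + df * s2) / (prior_df + df)
  } else {
    s2_post <- s2
  }
  se <- sqrt(s2_post / sxx)
  t_stat <- ifelse(se > 0, slope / se,
                   sign(slope) * .Machine$double.xmax)
  t_stat[zero_var] <- 0
  se[zero_var] <- NA_real_

  ord <- order(-t_stat, expr$gene_ids, method = "radix")
  out <- data.frame(gene_id = expr$gene_ids[ord], slope = slope[ord],
                    se = se[ord], t = t_stat[ord],
                    rank = seq_along(ord),
                    zero_variance = zero_var[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_gene_list", "data.frame")
  out
}

#' Write a ranked gene list as TSV
#'
#' @param ranked a `ranked_gene_list`.
#' @param path output path.
#' @export
write_ranked_tsv <- function(ranked, path) {
  utils::write.table(ranked[, c("gene_id", "slope", "se", "t", "rank")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' r with a 95% interval `tanh(atanh(r) +/- z / sqrt(n - 3))` and the
#' two-sided p-value from the t transform `r * sqrt(n-2) / sqrt(1 - r^2)`.
#' A perfect correlation degenerates to the point interval at +/-1.
#'
#' @param x,y numeric vectors of equal length, n >= 4.
#' @param conf_level confidence level for the interval.
#' @return A `correlation_result`: list with `r`, `ci_low`, `ci_high`, `n`,
#'   `p`.
#' @export
pearson_with_ci <- function(x, y, conf_level = 0.95) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (n < 4L) stop("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  r <- stats::cor(x, y)
  z_crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (abs(r) >= 1) {
    ci <- c(r, r)
    p <- 0
  } else {
    ci <- tanh(atanh(r) + c(-1, 1) * z_crit / sqrt(n - 3))
    tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  structure(list(r = r, ci_low = ci[1L], ci_high = ci[2L], n = n, p = p),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (95%% CI %.3f, %.3f), n = %d, p = %.3g\n",
              x$r, x$ci_low, x$ci_high, x$n, x$p))
  invisible(x)
}
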