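# Gene set enrichment: weighted Kolmogorov-Smirnov-like running sum over a
# ranked gene list, permutation null, sign-stratified NES and FDR.

# Core running-sum statistic. t_sorted: statistics in ranking order
# (descending); is_member: logical of same length. Members step up by
# |t|^p / sum(member |t|^p); non-members step down by 1/(N - k). Returns the
# walk, its extremum (first position of maximal |value|) and member
# positions.
.es_walk <- function(t_sorted, is_member, weight_exponent) {
  N <- length(t_sorted)
  k <- sum(is_member)
  if (k == 0L) stop("gene set has empty intersection with the ranking")
  if (k == N) stop("gene set equals the whole universe")
  if (weight_exponent < 0) stop("weight_exponent must be >= 0")
  w <- if (weight_exponent == 0) rep(1, N) else abs(t_sorted)^weight_exponent
  nr <- sum(w[is_member])
  if (nr == 0)
    stop("all member statistics are zero with weight_exponent > 0")
  step <- numeric(N)
  step[is_member] <- w[is_member] / nr
  step[!is_member] <- -1 / (N - k)
  walk <- cumsum(step)
  # extremum position: first index attaining the maximal |excursion|;
  # the 1e-9 slack makes exact-arithmetic ties (common at p = 0) robust
  # to the accumulation order
  aw <- abs(walk)
  i_star <- which(aw >= max(aw) - 1e-9)[1L]
  list(es = walk[i_star], max_es_at = i_star, walk = walk,
       member_positions = which(is_member))
}

#' Enrichment score of a gene set on a ranked list
#'
#' Walks the ranked gene list from top to bottom accumulating a running sum:
#' each set member at rank i adds `|t_i|^p / sum_members |t|^p`, each
#' non-member subtracts `1/(N - k)`. The enrichment score (ES) is the walk
#' value of maximal absolute excursion; `max_es_at` is its 1-based rank
#' position — the first position whose |excursion| reaches the maximum
#' (ties, common in the unweighted walk, resolve to the earliest rank). A
#' set
#' concentrated at the top of the list yields ES near +1, one at the bottom
#' a negative ES.
#'
#' @param ranked a `ranked_gene_list` from [gene_cpe_ranking()], or any
#'   data.frame with columns `gene_id` and `t` in ranking order.
#' @param gene_set character vector of member gene ids.
#' @param weight_exponent p >= 0; 0 gives the unweighted (classic KS) walk,
#'   1 the standard weighted statistic.
#' @param min_set_size minimum size of the intersection with the universe.
#' @return A list with `es`, `max_es_at`, `walk` (length-N numeric),
#'   `member_positions`, `set_size` (intersection size).
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1,
                             min_set_size = 5) {
  is_member <- ranked$gene_id %in% gene_set
  if (sum(is_member) < min_set_size)
    stop(sprintf("set intersection (%d) below min_set_size (%d)",
                 sum(is_member), min_set_size))
  res <- .es_walk(ranked$t, is_member, weight_exponent)
  res$set_size <- length(res$member_positions)
  res
}

#' Leading-edge fraction of an enrichment walk
#'
#' The fraction of a gene set's members that contribute to the enrichment
#' score: members at ranks at or before the walk extremum for a positive ES,
#' at or after it for a negative ES. A value near 1 means nearly the whole
#' set drives the signal.
#'
#' @param walk_result the list returned by [enrichment_score()].
#' @return Fraction in (0, 1].
#' @export
leading_edge_fraction <- function(walk_result) {
  pos <- walk_result$member_positions
  at <- walk_result$max_es_at
  if (walk_result$es >= 0) mean(pos <= at) else mean(pos >= at)
}

# Per-gene OLS t statistics against a centered covariate; shared by the
# observed ranking and the response-permutation null so both use the exact
# same statistic.
.ols_t <- function(values, x, moderation = "none", prior_df = 4) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- as.vector(values %*% xc) / sxx
  ybar <- rowMeans(values)
  ss_tot <- rowSums(values^2) - n * ybar^2
  ss_res <- pmax(ss_tot - slope^2 * sxx, 0)
  df <- n - 2L
  s2 <- ss_res / df
  zero_var <- ss_tot <= .Machine$double.eps * n * pmax(ybar^2, 1)
  if (moderation == "empirical_bayes") {
    pos <- s2[!zero_var & s2 > 0]
    s2_prior <- if (length(pos)) mean(pos, trim = 0.1) else 0
    s2 <- (prior_df * s2_prior + df * s2) / (prior_df + df)
  }
  se <- sqrt(s2 / sxx)
  t_stat <- ifelse(se > 0, slope / se, sign(slope) * .Machine$double.xmax)
  t_stat[zero_var] <- 0
  t_stat
}

#' Permutation null distribution of enrichment scores
#'
#' Two schemes. `"response"` permutes the CPE vector, recomputes the entire
#' per-gene ranking, and rescores every set per permutation — this preserves
#' inter-gene correlation and matches the regression-based ranking design.
#' `"gene"` keeps the observed ranking fixed and permutes gene labels
#' (equivalently, draws uniformly random member positions), a fast fallback
#' whose null ignores gene-gene correlation.
#'
#' @param expr continuous [expression_matrix()] (response scheme).
#' @param cpe numeric CPE vector aligned with samples.
#' @param collection a [gene_set_collection()] already filtered to the
#'   universe (see [filter_collection()]).
#' @param n_perm number of permutations (>= 50).
#' @param scheme `"response"` or `"gene"`.
#' @param seed integer seed; the null is fully reproducible.
#' @param weight_exponent walk weight p.
#' @param moderation passed to the ranking statistic (response scheme).
#' @return Numeric matrix, sets x permutations, of null enrichment scores.
#' @export
permutation_null <- function(expr, cpe, collection, n_perm = 1000,
                             scheme = c("response", "gene"), seed = 1,
                             weight_exponent = 1, moderation = "none") {
  scheme <- match.arg(scheme)
  if (n_perm < 50)
    warning("n_perm < 50 gives poor FDR resolution; proceeding")
  set_names <- names(collection$sets)
  null_es <- matrix(NA_real_, nrow = length(set_names), ncol = n_perm,
                    dimnames = list(set_names, NULL))
  set.seed(seed)
  values <- expr$values
  gene_ids <- expr$gene_ids
  if (scheme == "response") {
    member_flags <- lapply(collection$sets, function(s) gene_ids %in% s)
    for (j in seq_len(n_perm)) {
      perm <- sample.int(length(cpe))
      t_perm <- .ols_t(values, cpe[perm], moderation = moderation)
      ord <- order(-t_perm, gene_ids, method = "radix")
      t_sorted <- t_perm[ord]
      for (i in seq_along(set_names)) {
        is_member <- member_flags[[i]][ord]
        null_es[i, j] <- .es_walk(t_sorted, is_member,
                                  weight_exponent)$es
      }
    }
  } else {
    t_obs <- .ols_t(values, cpe, moderation = moderation)
    ord <- order(-t_obs, gene_ids, method = "radix")
    t_sorted <- t_obs[ord]
    N <- length(t_sorted)
    sizes <- lengths(collection$sets)
    for (j in seq_len(n_perm)) {
      for (i in seq_along(set_names)) {
        is_member <- logical(N)
        is_member[sample.int(N, sizes[i])] <- TRUE
        null_es[i, j] <- .es_walk(t_sorted, is_member,
                                  weight_exponent)$es
      }
    }
  }
  null_es
}

#' Normalize enrichment scores and attach permutation p and FDR q
#'
#' NES divides each observed ES by the mean of the same-sign null ES of its
#' own set, making magnitudes comparable across sets (null NES magnitudes
#' are ~1 by construction). The permutation p-value is the same-sign null
#' tail fraction at the observed ES. The FDR q follows the sign-stratified
#' gene-set-enrichment convention: for each observed NES*, the pooled null
#' NES tail fraction divided by the observed NES tail fraction, on the
#' matching sign, clipped to [0, 1].
#'
#' @param observed data.frame with columns `set_name`, `es`, `max_es_at`,
#'   `leading_edge`, `set_size` (as built by [score_collection()]).
#' @param null_es matrix from [permutation_null()], rows matching
#'   `observed$set_name`.
#' @return An `enrichment_result` data.frame: `set_name`, `set_size`, `es`,
#'   `nes`, `max_es_at`, `leading_edge`, `p_perm`, `fdr_q`. Sets without a
#'   sign-matched null value get `NA` NES and are flagged in attribute
#'   `undefined_nes`.
#' @export
normalize_and_fdr <- function(observed, null_es) {
  stopifnot(identical(observed$set_name, rownames(null_es)))
  if (ncol(null_es) < 1L) stop("need at least one null column")
  n_sets <- nrow(observed)
  nes <- rep(NA_real_, n_sets)
  p_perm <- rep(NA_real_, n_sets)
  null_nes <- matrix(NA_real_, n_sets, ncol(null_es))
  for (i in seq_len(n_sets)) {
    es <- observed$es[i]
    row <- null_es[i, ]
    pos <- row[row >= 0]
    neg <- row[row < 0]
    mu_pos <- if (length(pos)) mean(pos) else NA_real_
    mu_neg <- if (length(neg)) mean(abs(neg)) else NA_real_
    null_nes[i, row >= 0] <- row[row >= 0] / mu_pos
    null_nes[i, row < 0] <- row[row < 0] / mu_neg
    if (es >= 0) {
      if (length(pos) && mu_pos > 0) {
        nes[i] <- es / mu_pos
        p_perm[i] <- sum(pos >= es) / length(pos)
      }
    } else {
      if (length(neg) && mu_neg > 0) {
        nes[i] <- -abs(es) / mu_neg
        p_perm[i] <- sum(abs(neg) >= abs(es)) / length(neg)
      }
    }
  }
  pooled <- null_nes[is.finite(null_nes)]
  fdr_q <- rep(NA_real_, n_sets)
  for (i in seq_len(n_sets)) {
    if (!is.finite(nes[i])) next
    if (nes[i] >= 0) {
      null_side <- pooled[pooled >= 0]
      obs_side <- nes[is.finite(nes) & nes >= 0]
      num <- if (length(null_side)) mean(null_side >= nes[i]) else 0
      den <- mean(obs_side >= nes[i])
    } else {
      null_side <- pooled[pooled < 0]
      obs_side <- nes[is.finite(nes) & nes < 0]
      num <- if (length(null_side)) mean(null_side <= nes[i]) else 0
      den <- mean(obs_side <= nes[i])
    }
    fdr_q[i] <- min(max(num / den, 0), 1)
  }
  out <- data.frame(set_name = observed$set_name,
                    set_size = observed$set_size,
                    es = observed$es, nes = nes,
                    max_es_at = observed$max_es_at,
                    leading_edge = observed$leading_edge,
                    p_perm = p_perm, fdr_q = fdr_q,
                    stringsAsFactors = FALSE)
  attr(out, "undefined_nes") <- observed$set_name[!is.finite(nes)]
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Observed enrichment scores for a whole collection
#'
#' @param ranked a `ranked_gene_list`.
#' @param collection a filtered [gene_set_collection()].
#' @param weight_exponent walk weight p.
#' @param min_set_size minimum intersection size.
#' @return data.frame with `set_name`, `set_size`, `es`, `max_es_at`,
#'   `leading_edge`.
#' @export
score_collection <- function(ranked, collection, weight_exponent = 1,
                             min_set_size = 5) {
  rows <- lapply(names(collection$sets), function(nm) {
    w <- enrichment_score(ranked, collection$sets[[nm]],
                          weight_exponent = weight_exponent,
                          min_set_size = min_set_size)
    data.frame(set_name = nm, set_size = w$set_size, es = w$es,
               max_es_at = w$max_es_at,
               leading_edge = leading_edge_fraction(w),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full GSEA of a collection against CPE
#'
#' Convenience wrapper: rank genes against CPE, score each set, build the
#' permutation null, and return the normalized table.
#'
#' @inheritParams permutation_null
#' @param min_set_size,max_set_size collection size filter.
#' @param moderation ranking statistic moderation, see [gene_cpe_ranking()].
#' @return An `enrichment_result` data.frame (see [normalize_and_fdr()]),
#'   ordered by `nes` descending, with the filtered collection and the
#'   observed ranking attached as attributes `collection` and `ranked`.
#' @export
run_gsea <- function(expr, cpe, collection, n_perm = 1000,
                     scheme = c("response", "gene"), seed = 1,
                     weight_exponent = 1, min_set_size = 5,
                     max_set_size = 500, moderation = "none") {
  scheme <- match.arg(scheme)
  collection <- filter_collection(collection, expr$gene_ids,
                                  min_size = min_set_size,
                                  max_size = max_set_size)
  ranked <- gene_cpe_ranking(expr, cpe, moderation = moderation)
  observed <- score_collection(ranked, collection,
                               weight_exponent = weight_exponent,
                               min_set_size = min_set_size)
  null_es <- permutation_null(expr, cpe, collection, n_perm = n_perm,
                              scheme = scheme, seed = seed,
                              weight_exponent = weight_exponent,
                              moderation = moderation)
  res <- normalize_and_fdr(observed, null_es)
  res <- res[order(-res$nes, res$set_name), ]
  rownames(res) <- NULL
  attr(res, "collection") <- collection
  attr(res, "ranked") <- ranked
  res
}

#' Write an enrichment result table as TSV
#'
#' @param result an `enrichment_result`.
#' @param path output path.
#' @export
write_enrichment_tsv <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
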