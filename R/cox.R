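# Cox proportional hazards with optional Firth penalization.
#
# The partial likelihood uses Breslow's approximation for tied event times.
# Firth's penalty adds half the log-determinant of the observed information
# to the partial log-likelihood (the Jeffreys-prior penalty), which keeps
# estimates finite under monotone likelihood / separation and reduces
# small-sample bias when events are few.

# Breslow partial log-likelihood, score and information at beta.
# Returns list(loglik, score, info). design: n x p matrix; time, event
# vectors. Computed by a single pass over decreasing time with cumulative
# risk-set sums; ties grouped by unique event time.
.cox_quantities <- function(design, time, event, beta) {
  n <- nrow(design)
  p <- ncol(design)
  ord <- order(-time)
  x <- design[ord, , drop = FALSE]
  tt <- time[ord]
  ev <- event[ord]
  eta <- as.vector(x %*% beta)
  eta <- eta - max(eta)               # guard against overflow; cancels below
  w <- exp(eta)
  s0 <- cumsum(w)
  s1 <- apply(x * w, 2L, cumsum)
  if (p == 1L) s1 <- matrix(s1, ncol = 1L)
  # s2 as cumulative sums of the p*(p+1)/2 upper-triangle products
  ut <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  xx <- x[, ut[, 1L], drop = FALSE] * x[, ut[, 2L], drop = FALSE]
  s2flat <- apply(xx * w, 2L, cumsum)
  if (nrow(ut) == 1L) s2flat <- matrix(s2flat, ncol = 1L)

  loglik <- 0
  score <- numeric(p)
  info <- matrix(0, p, p)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && tt[j + 1L] == tt[i]) j <- j + 1L
    idx <- i:j
    d_idx <- idx[ev[idx] == 1]
    d <- length(d_idx)
    if (d > 0L) {
      S0 <- s0[j]
      S1 <- s1[j, ]
      S2 <- matrix(0, p, p)
      S2[upper.tri(S2, diag = TRUE)] <- s2flat[j, ]
      S2 <- S2 + t(S2) - diag(diag(S2), p)
      xb <- S1 / S0
      loglik <- loglik + sum(eta[d_idx]) - d * log(S0)
      score <- score + colSums(x[d_idx, , drop = FALSE]) - d * xb
      info <- info + d * (S2 / S0 - tcrossprod(xb))
    }
    i <- j + 1L
  }
  list(loglik = loglik, score = score, info = info)
}

# Gradient of 0.5 * log det I(beta) by central finite differences.
.firth_penalty_grad <- function(design, time, event, beta, h = 1e-5) {
  p <- length(beta)
  g <- numeric(p)
  for (r in seq_len(p)) {
    bp <- bm <- beta
    bp[r] <- bp[r] + h
    bm[r] <- bm[r] - h
    lp <- determinant(.cox_quantities(design, time, event, bp)$info,
                      logarithm = TRUE)$modulus
    lm <- determinant(.cox_quantities(design, time, event, bm)$info,
                      logarithm = TRUE)$modulus
    g[r] <- 0.5 * (lp - lm) / (2 * h)
  }
  g
}

.penalized_loglik <- function(design, time, event, beta, penalize) {
  q <- .cox_quantities(design, time, event, beta)
  ll <- q$loglik
  if (penalize) {
    ld <- determinant(q$info, logarithm = TRUE)
    if (ld$sign <= 0) return(list(value = -Inf, q = q))
    ll <- ll + 0.5 * as.numeric(ld$modulus)
  }
  list(value = ll, q = q)
}

#' Fit a Cox proportional hazards model, optionally Firth-penalized
#'
#' Maximizes the Breslow partial log-likelihood by Newton-Raphson with
#' step-halving. With `penalize = "firth"` the objective is the partial
#' log-likelihood plus half the log-determinant of the observed information
#' (Jeffreys-prior penalty), whose maximizer is finite even under complete
#' separation / monotone likelihood. Convergence is declared when the
#' maximal absolute (modified) score falls below `score_tol` or the
#' objective change falls below `loglik_tol`.
#'
#' An unpenalized fit whose coefficients run away (any |beta| above
#' `separation_bound` while the likelihood still climbs) is flagged
#' `monotone = TRUE` and `converged = FALSE` rather than silently reported.
#'
#' @param design numeric matrix (n x p) with column names; no intercept.
#' @param time follow-up times > 0.
#' @param event event indicators in \{0, 1\}.
#' @param penalize `"none"` or `"firth"`.
#' @param ci `"wald"` (default) or `"profile"` for penalized-likelihood
#'   ratio intervals found by bisection.
#' @param conf_level confidence level.
#' @param maxit,score_tol,loglik_tol Newton control.
#' @param separation_bound |beta| beyond which an unpenalized fit is
#'   declared monotone.
#' @return A `cox_fit`: list with `terms` (data.frame: term, beta, se, hr,
#'   ci_low, ci_high, p), `penalized`, `loglik`, `n`, `n_events`,
#'   `converged`, `monotone`, `iterations`, `vcov`, `ci_type`.
#' @export
cox_fit <- function(design, time, event, penalize = c("none", "firth"),
                    ci = c("wald", "profile"), conf_level = 0.95,
                    maxit = 100, score_tol = 1e-6, loglik_tol = 1e-9,
                    separation_bound = 15) {
  penalize <- match.arg(penalize)
  ci <- match.arg(ci)
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  if (anyNA(design) || anyNA(time) || anyNA(event))
    stop("missing values in design, time or event (complete cases only)")
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  n_events <- sum(event)
  if (n_events < 1) stop("need at least one event")
  p <- ncol(design)
  if (n_events / p < 5)
    warning(sprintf("only %.1f events per parameter (< 5); estimates %s",
                    n_events / p,
                    if (penalize == "firth") "rely on the penalty"
                    else "may be unstable"))
  qr_rank <- qr(cbind(design))$rank
  if (qr_rank < p) {
    stop("singular design: collinear term(s) among ",
         paste(colnames(design), collapse = ", "))
  }
  firth <- penalize == "firth"
  beta <- numeric(p)
  pl <- .penalized_loglik(design, time, event, beta, firth)
  if (!is.finite(pl$value))
    stop("information matrix not positive definite at beta = 0")
  monotone <- FALSE
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxit)) {
    u <- pl$q$score
    if (firth)
      u <- u + .firth_penalty_grad(design, time, event, beta)
    if (max(abs(u)) < score_tol) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(pl$q$info, u), error = function(e) NULL)
    if (is.null(step))
      stop("singular information matrix; collinear term(s) among ",
           paste(colnames(design), collapse = ", "))
    # step-halving: the (penalized) likelihood never decreases
    new_pl <- NULL
    for (half in 0:25) {
      cand <- beta + step / 2^half
      new_pl <- .penalized_loglik(design, time, event, cand, firth)
      if (is.finite(new_pl$value) && new_pl$value >= pl$value) break
    }
    if (!is.finite(new_pl$value) || new_pl$value < pl$value) {
      break   # no uphill step found
    }
    delta <- new_pl$value - pl$value
    beta <- cand
    pl <- new_pl
    if (!firth && max(abs(beta)) > separation_bound) {
      monotone <- TRUE
      break
    }
    if (delta < loglik_tol) {
      u_new <- pl$q$score
      if (firth)
        u_new <- u_new + .firth_penalty_grad(design, time, event, beta)
      converged <- max(abs(u_new)) < sqrt(score_tol)
      break
    }
  }
  if (monotone)
    warning("monotone partial likelihood (separation): unpenalized ",
            "estimates diverge; consider penalize = 'firth'")
  vcov <- tryCatch(solve(pl$q$info), error = function(e)
    matrix(NA_real_, p, p))
  se <- sqrt(diag(vcov))
  z_crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (ci == "profile") {
    ci_mat <- .profile_ci(design, time, event, beta, pl$value, firth,
                          conf_level)
  } else {
    ci_mat <- cbind(beta - z_crit * se, beta + z_crit * se)
  }
  zval <- beta / se
  terms <- data.frame(term = colnames(design), beta = beta, se = se,
                      hr = exp(beta), ci_low = exp(ci_mat[, 1L]),
                      ci_high = exp(ci_mat[, 2L]),
                      p = 2 * stats::pnorm(-abs(zval)),
                      stringsAsFactors = FALSE)
  structure(list(terms = terms, penalized = firth, loglik = pl$value,
                 n = nrow(design), n_events = n_events,
                 converged = converged, monotone = monotone,
                 iterations = iter, vcov = vcov, ci_type = ci),
            class = "cox_fit")
}

# Profile (penalized) likelihood CI by bisection on the likelihood-ratio
# boundary: find beta_r where the profile objective drops by
# qchisq(level, 1) / 2, maximizing over the other coefficients.
.profile_ci <- function(design, time, event, beta_hat, ll_max, firth,
                        conf_level, maxit_inner = 40) {
  p <- length(beta_hat)
  target <- ll_max - stats::qchisq(conf_level, 1) / 2
  prof <- function(r, val) {
    if (p == 1L) {
      return(.penalized_loglik(design, time, event, val, firth)$value)
    }
    beta <- beta_hat
    beta[r] <- val
    free <- setdiff(seq_len(p), r)
    for (it in seq_len(maxit_inner)) {
      plq <- .penalized_loglik(design, time, event, beta, firth)
      u <- plq$q$score
      if (firth)
        u <- u + .firth_penalty_grad(design, time, event, beta)
      u <- u[free]
      if (max(abs(u)) < 1e-6) break
      info_f <- plq$q$info[free, free, drop = FALSE]
      step <- tryCatch(solve(info_f, u), error = function(e) NULL)
      if (is.null(step)) break
      for (half in 0:20) {
        cand <- beta
        cand[free] <- beta[free] + step / 2^half
        new <- .penalized_loglik(design, time, event, cand, firth)
        if (is.finite(new$value) && new$value >= plq$value) break
      }
      if (!is.finite(new$value) || new$value < plq$value) break
      beta <- cand
    }
    .penalized_loglik(design, time, event, beta, firth)$value
  }
  out <- matrix(NA_real_, p, 2L)
  for (r in seq_len(p)) {
    for (side in 1:2) {
      dir <- if (side == 1L) -1 else 1
      width <- 0.5
      lo <- beta_hat[r]
      hi <- beta_hat[r] + dir * width
      # expand until the profile objective crosses the boundary
      for (e in 1:30) {
        if (prof(r, hi) < target) break
        width <- width * 2
        lo <- hi
        hi <- beta_hat[r] + dir * width
      }
      if (prof(r, hi) >= target) {
        out[r, side] <- hi   # boundary not crossed within range
        next
      }
      for (b in 1:40) {
        mid <- (lo + hi) / 2
        if (prof(r, mid) >= target) lo <- mid else hi <- mid
        if (abs(hi - lo) < 1e-6) break
      }
      out[r, side] <- (lo + hi) / 2
    }
  }
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit (%s, %s CI): n = %d, events = %d, loglik = %.3f%s\n",
              if (x$penalized) "Firth-penalized" else "unpenalized",
              x$ci_type, x$n, x$n_events, x$loglik,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  if (x$monotone) cat("  monotone likelihood flagged\n")
  df <- x$terms
  df[, -1L] <- lapply(df[, -1L], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  invisible(x)
}
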