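# Synthetic cohort generator: DCE imaging volumes with controllable
# parenchymal enhancement, negative-binomial RNA-seq counts with a planted
# CPE-correlated gene set, clinical covariates, and Weibull
# proportional-hazards survival. Every planted parameter is recorded so
# downstream stages can be tested for recovery.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the discovery-cohort conditions the pipeline is designed
#' for: 226 subjects, five DCE timepoints (pre-contrast plus four
#' post-contrast series 90 s apart), ~2000 measured genes with a planted
#' 40-gene set whose expression decreases with CPE, and heavily censored
#' survival (~90%, i.e. few events — the regime that motivates Firth
#' penalization).
#'
#' @param n_subjects number of subjects.
#' @param volume_shape integer triple of voxel dimensions.
#' @param n_timepoints number of DCE series including pre-contrast (>= 3).
#' @param timepoint_spacing seconds between series.
#' @param n_genes number of genes.
#' @param planted_set_size size of the planted gene set.
#' @param gene_effect slope of planted-gene log-mean expression per SD of
#'   CPE (negative: high CPE, low pathway expression).
#' @param pathway_factor_sd SD of the shared latent factor added to planted
#'   genes (makes the pathway score correlated with, not collinear to, CPE).
#' @param dispersion median negative-binomial overdispersion.
#' @param survival_betas named log-hazard coefficients; names must be
#'   columns of the cohort covariate matrix (`age`, `size_mm`, `grade2`,
#'   `grade3`, `cpe`, `pc1`, ...).
#' @param baseline_shape,baseline_scale Weibull baseline (time unit:
#'   months).
#' @param censoring_rate target censoring fraction in [0, 1).
#' @param n_gene_sets total number of gene sets (one planted + background).
#' @param cpe_range range of the fast-mode CPE distribution.
#' @param seed integer master seed.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_subjects = 226,
                         volume_shape = c(32L, 32L, 32L),
                         n_timepoints = 5, timepoint_spacing = 90,
                         n_genes = 2000, planted_set_size = 40,
                         gene_effect = -0.5, pathway_factor_sd = 0.3,
                         dispersion = 0.15,
                         survival_betas = c(age = 0.04, size_mm = 0.015,
                                            grade2 = 0.2, grade3 = 0.5,
                                            cpe = -0.5, pc1 = 0.3),
                         baseline_shape = 1.2, baseline_scale = 400,
                         censoring_rate = 0.9, n_gene_sets = 50,
                         cpe_range = c(0.1, 1.0), seed = 1) {
  stopifnot(n_subjects >= 1, n_genes >= 1, planted_set_size >= 1,
            n_timepoints >= 3, all(volume_shape >= 1),
            planted_set_size <= n_genes,
            censoring_rate >= 0, censoring_rate < 1,
            baseline_shape > 0, baseline_scale > 0,
            dispersion > 0, n_gene_sets >= 1)
  if (is.null(names(survival_betas)) && length(survival_betas))
    stop("survival_betas must be named")
  structure(list(n_subjects = as.integer(n_subjects),
                 volume_shape = as.integer(volume_shape),
                 n_timepoints = as.integer(n_timepoints),
                 timepoint_spacing = timepoint_spacing,
                 n_genes = as.integer(n_genes),
                 planted_set_size = as.integer(planted_set_size),
                 gene_effect = gene_effect,
                 pathway_factor_sd = pathway_factor_sd,
                 dispersion = dispersion,
                 survival_betas = survival_betas,
                 baseline_shape = baseline_shape,
                 baseline_scale = baseline_scale,
                 censoring_rate = censoring_rate,
                 n_gene_sets = as.integer(n_gene_sets),
                 cpe_range = cpe_range,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Ellipsoid mask helper.
.ellipsoid_mask <- function(shape, semi_frac) {
  ctr <- (shape + 1) / 2
  semi <- semi_frac * shape / 2
  i <- (seq_len(shape[1L]) - ctr[1L]) / semi[1L]
  j <- (seq_len(shape[2L]) - ctr[2L]) / semi[2L]
  k <- (seq_len(shape[3L]) - ctr[3L]) / semi[3L]
  d2 <- outer(outer(i^2, j^2, "+"), k^2, "+")
  d2 <= 1
}

#' Generate one subject's DCE study with a controlled CPE
#'
#' Fibroglandular voxels follow S(t) = S0 * (1 + A_v * f(t)) with a smooth
#' uptake curve f (linear rise to the first post-contrast series, then a
#' persistent linear slope), and per-voxel amplitudes A_v chosen so the CPE
#' statistic computed on the study recovers `target_cpe` (up to top-decile
#' sampling noise, which the amplitude scaling removes). Non-fibroglandular
#' breast tissue enhances negligibly; background air carries a small
#' positive signal.
#'
#' @param config a [synth_config()].
#' @param target_cpe desired CPE (> -1); 0 yields exactly zero enhancement
#'   change between the early and late series.
#' @param subject_seed integer seed; identical seeds give bit-identical
#'   volumes.
#' @return list(study = [dce_study()], masks = [tissue_masks()],
#'   target_cpe).
#' @export
gen_dce_study <- function(config, target_cpe, subject_seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  if (target_cpe <= -1) stop("target_cpe must be > -1 (ratio undefined)")
  shape <- config$volume_shape
  breast <- .ellipsoid_mask(shape, c(0.9, 0.9, 0.9))
  fgt <- .ellipsoid_mask(shape, c(0.45, 0.45, 0.45))
  if (!any(fgt)) stop("volume too small to contain a fibroglandular mask")
  set.seed(subject_seed)
  m <- sum(fgt)
  nvox <- prod(shape)

  # baseline T1 signal: fat bright, fibroglandular intermediate, air low
  s0 <- array(20 * exp(stats::rnorm(nvox, 0, 0.05)), shape)
  s0[breast] <- 400 * exp(stats::rnorm(sum(breast), 0, 0.1))
  s0[fgt] <- 200 * exp(stats::rnorm(m, 0, 0.1))

  times <- seq(0, by = config$timepoint_spacing,
               length.out = config$n_timepoints)
  t_early <- times[2L]
  t_late <- times[config$n_timepoints]

  # desired per-voxel delayed enhancement ratios: uniform draws scaled so
  # the top-decile mean equals target_cpe exactly
  if (target_cpe == 0) {
    r <- numeric(m)
    delta <- 0                      # no change between early and late
  } else {
    u <- stats::runif(m)
    k10 <- max(1L, as.integer(ceiling(0.10 * m)))
    top_mean <- mean(sort(u, decreasing = TRUE)[seq_len(k10)])
    r <- u * target_cpe / top_mean
    delta <- max(1.25, 1.5 * max(abs(r)))   # late/early uptake increment
  }
  # f(t): 0 at injection, 1 at the early series, 1 + delta at the late one
  f_of <- function(t) {
    ifelse(t <= t_early, t / t_early,
           1 + delta * (t - t_early) / (t_late - t_early))
  }
  # invert ratio = A * delta / (1 + A) -> per-voxel amplitude
  a_fgt <- if (target_cpe == 0) rep(0.3, m) else r / (delta - r)
  if (any(a_fgt <= -1))
    stop("target_cpe implies non-physical (negative) signal")

  amp <- array(0, shape)
  amp[breast] <- 0.01               # negligible fat enhancement
  amp[fgt] <- a_fgt
  vols <- lapply(times, function(t) {
    v <- s0 * (1 + amp * f_of(t))
    if (any(v <= 0)) stop("generated non-positive intensity")
    v
  })
  list(study = dce_study(vols, times),
       masks = tissue_masks(breast, fgt),
       target_cpe = target_cpe)
}

#' Generate an RNA-seq-like count matrix with a planted CPE-associated set
#'
#' Counts are negative binomial with gene-wise dispersions drawn from a
#' log-normal around the configured median and log-normal library-size
#' offsets. Planted genes have log-mean `baseline + gene_effect * cpe_z`
#' plus a shared latent pathway factor; background genes are independent of
#' CPE.
#'
#' @param config a [synth_config()].
#' @param cpe_z standardized CPE vector, length `n_subjects`.
#' @param seed integer seed.
#' @param planted_gene_ids optional explicit planted set (e.g. to share one
#'   planted pathway across two cohorts); default samples
#'   `planted_set_size` ids.
#' @return list(expr = counts [expression_matrix()], truth = list with
#'   `planted_gene_ids`, `gene_effect_used`, `latent_factor`,
#'   `latent_pc_scores`).
#' @export
gen_expression_matrix <- function(config, cpe_z, seed = config$seed,
                                  planted_gene_ids = NULL) {
  stopifnot(inherits(config, "synth_config"))
  n <- length(cpe_z)
  if (n != config$n_subjects)
    stop("cpe_z length must equal n_subjects")
  if (n < 2L) stop("need at least 2 subjects (no variance definable)")
  if (!all(is.finite(cpe_z))) stop("cpe_z must be finite")
  set.seed(seed)
  g <- config$n_genes
  gene_ids <- sprintf("g%05d", seq_len(g))
  sample_ids <- sprintf("s%04d", seq_len(n))
  planted <- if (is.null(planted_gene_ids)) {
    sort(sample(gene_ids, config$planted_set_size))
  } else {
    if (!all(planted_gene_ids %in% gene_ids))
      stop("planted_gene_ids outside the generated gene universe")
    sort(planted_gene_ids)
  }
  is_planted <- gene_ids %in% planted

  baseline <- stats::rnorm(g, mean = log(50), sd = 1.5)
  disp <- stats::rlnorm(g, meanlog = log(config$dispersion), sdlog = 0.5)
  libsize <- stats::rlnorm(n, meanlog = 0, sdlog = 0.2)
  eta <- stats::rnorm(n)                      # shared latent pathway factor

  log_mu <- matrix(baseline, g, n)
  shift <- config$gene_effect * cpe_z + config$pathway_factor_sd * eta
  log_mu[is_planted, ] <- log_mu[is_planted, ] +
    matrix(shift, sum(is_planted), n, byrow = TRUE)
  mu <- exp(log_mu) * matrix(libsize, g, n, byrow = TRUE)
  counts <- matrix(stats::rnbinom(g * n, mu = mu, size = 1 / disp), g, n)
  expr <- expression_matrix(counts, gene_ids, sample_ids, kind = "counts")
  lat <- config$gene_effect * cpe_z + config$pathway_factor_sd * eta
  lat_z <- if (stats::sd(lat) > 0) as.numeric(scale(lat)) else numeric(n)
  truth <- list(planted_gene_ids = planted,
                gene_effect_used = config$gene_effect,
                latent_factor = eta,
                latent_pc_scores = lat_z)
  list(expr = expr, truth = truth)
}

#' Generate gene set collection: one planted set plus background sets
#'
#' Background sets are drawn from the non-planted genes so they are true
#' negatives: sets with no CPE-associated members, against which planted-
#' signal recovery can be judged cleanly.
#'
#' @param config a [synth_config()].
#' @param planted_gene_ids members of the planted set.
#' @param gene_ids the full gene universe.
#' @param seed integer seed.
#' @return A [gene_set_collection()] whose first set is `PLANTED_PATHWAY`.
#' @export
gen_gene_sets <- function(config, planted_gene_ids, gene_ids,
                          seed = config$seed) {
  set.seed(seed)
  n_bg <- config$n_gene_sets - 1L
  background <- setdiff(gene_ids, planted_gene_ids)
  sizes <- sample(10:60, n_bg, replace = TRUE)
  sizes <- pmin(sizes, length(background))
  bg <- lapply(sizes, function(k) sample(background, k))
  names(bg) <- sprintf("RANDOM_SET_%02d", seq_len(n_bg))
  gene_set_collection(c(list(PLANTED_PATHWAY = planted_gene_ids), bg))
}

#' Simulate proportional-hazards survival with calibrated censoring
#'
#' Event times follow a Weibull proportional-hazards model
#' `T = scale * (-log U * exp(-x'beta))^(1/shape)`. Censoring is
#' exponential; its rate is solved numerically so the expected censoring
#' fraction, given the drawn event times, equals the target.
#'
#' @param covariates numeric matrix with named columns.
#' @param betas named log-hazard coefficients; every name must be a column
#'   of `covariates`.
#' @param baseline_shape,baseline_scale Weibull baseline parameters (> 0).
#' @param censoring_rate target fraction in [0, 1).
#' @param seed integer seed.
#' @return data.frame(time, event) with attribute `censoring_rate_used`
#'   (the solved exponential rate).
#' @export
gen_survival_data <- function(covariates, betas, baseline_shape = 1.2,
                              baseline_scale = 400, censoring_rate = 0,
                              seed = 1) {
  if (baseline_shape <= 0 || baseline_scale <= 0)
    stop("baseline parameters must be > 0")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must be in [0, 1)")
  covariates <- as.matrix(covariates)
  if (length(betas)) {
    miss <- setdiff(names(betas), colnames(covariates))
    if (length(miss))
      stop("betas name covariate(s) not in the matrix: ",
           paste(miss, collapse = ", "))
  }
  set.seed(seed)
  n <- nrow(covariates)
  lp <- if (length(betas)) {
    as.vector(covariates[, names(betas), drop = FALSE] %*% betas)
  } else numeric(n)
  u <- stats::runif(n)
  t_event <- baseline_scale * (-log(u) * exp(-lp))^(1 / baseline_shape)
  if (censoring_rate == 0) {
    time <- t_event
    event <- rep(1L, n)
    rate <- 0
  } else {
    # expected censoring fraction given event times: mean(1 - exp(-r * T))
    f <- function(log_r) {
      mean(1 - exp(-exp(log_r) * t_event)) - censoring_rate
    }
    sol <- stats::uniroot(f, c(-30, 30), tol = 1e-10)
    rate <- exp(sol$root)
    cens <- stats::rexp(n, rate = rate)
    time <- pmin(t_event, cens)
    event <- as.integer(t_event <= cens)
  }
  out <- data.frame(time = time, event = event)
  attr(out, "censoring_rate_used") <- rate
  out
}

#' Generate a complete synthetic cohort
#'
#' Ties the generators together: per-subject CPE (either full DCE volume
#' synthesis, or "fast mode" drawing CPE directly from a scaled Beta
#' distribution spanning the configured range), RNA-seq-like counts with the
#' planted set, clinical covariates, a gene set collection, and survival
#' driven by the configured coefficients (which may reference `cpe` and the
#' latent pathway factor `pc1`). With `dir` given, all external-interface
#' files are written (TSV counts, CSV clinical, GMT sets, JSON truth, and
#' NIfTI volumes in imaging mode).
#'
#' @param config a [synth_config()].
#' @param mode `"fast"` (draw CPE values directly) or `"imaging"`
#'   (synthesize DCE volumes and compute CPE through the imaging module).
#' @param planted_gene_ids optional explicit planted set shared with
#'   another cohort (see [gen_expression_matrix()]).
#' @param dir optional output directory.
#' @return A `cohort_bundle`: list with `cpe` (raw), `cpe_z`
#'   (standardized), `counts`, `collection`, `clinical`, `truth`, `config`,
#'   `mode`, and in imaging mode `studies` (list of study/mask pairs).
#' @export
gen_cohort <- function(config, mode = c("fast", "imaging"),
                       planted_gene_ids = NULL, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  mode <- match.arg(mode)
  n <- config$n_subjects
  set.seed(config$seed)
  target <- config$cpe_range[1L] +
    diff(config$cpe_range) * stats::rbeta(n, 2, 3)
  studies <- NULL
  if (mode == "imaging") {
    studies <- lapply(seq_len(n), function(i) {
      gen_dce_study(config, target[i],
                    subject_seed = config$seed + 7919L * i)
    })
    cpe_raw <- vapply(studies, function(s) {
      cpe_from_study(s$study, s$masks,
                     early_time = config$timepoint_spacing,
                     late_time = config$timepoint_spacing *
                       (config$n_timepoints - 1L))$value
    }, 0)
  } else {
    cpe_raw <- target
  }
  cpe_z <- standardize(cpe_raw)

  gx <- gen_expression_matrix(config, as.numeric(cpe_z),
                              seed = config$seed + 1L,
                              planted_gene_ids = planted_gene_ids)
  collection <- gen_gene_sets(config, gx$truth$planted_gene_ids,
                              gx$expr$gene_ids, seed = config$seed + 2L)

  set.seed(config$seed + 3L)
  age <- pmin(pmax(round(stats::rnorm(n, 59, 9)), 30), 85)
  size_mm <- pmin(pmax(round(stats::rlnorm(n, log(19), 0.4)), 5), 80)
  grade <- sample(1:3, n, replace = TRUE, prob = c(0.36, 0.50, 0.14))
  axillary_load <- sample(c("0", "1-3", "4+"), n, replace = TRUE,
                          prob = c(0.63, 0.29, 0.08))
  node_pos <- axillary_load != "0"
  ast <- ifelse(stats::runif(n) < ifelse(node_pos, 0.8, 0.3), "yes", "no")

  covariates <- cbind(age = age, size_mm = size_mm,
                      grade2 = as.numeric(grade == 2),
                      grade3 = as.numeric(grade == 3),
                      cpe = as.numeric(cpe_z),
                      pc1 = gx$truth$latent_pc_scores)
  surv <- gen_survival_data(covariates, config$survival_betas,
                            baseline_shape = config$baseline_shape,
                            baseline_scale = config$baseline_scale,
                            censoring_rate = config$censoring_rate,
                            seed = config$seed + 4L)
  clinical <- clinical_table(data.frame(
    sample_id = gx$expr$sample_ids, age = age, size_mm = size_mm,
    grade = grade, axillary_load = axillary_load, ast = ast,
    time = surv$time, event = surv$event, stringsAsFactors = FALSE))

  truth <- c(gx$truth,
             list(true_cpe_per_subject = cpe_raw,
                  target_cpe_per_subject = target,
                  survival_betas_used = config$survival_betas,
                  censoring_rate_target = config$censoring_rate))
  bundle <- structure(list(cpe = cpe_raw, cpe_z = cpe_z, counts = gx$expr,
                           collection = collection, clinical = clinical,
                           truth = truth, config = config, mode = mode,
                           studies = studies),
                      class = "cohort_bundle")
  if (!is.null(dir)) write_cohort(bundle, dir)
  bundle
}

#' Write a cohort bundle in the external interface formats
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory, created if absent.
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression_tsv(bundle$counts, file.path(dir, "expression.tsv"))
  cl <- as.data.frame(bundle$clinical)
  cl$cpe <- bundle$cpe
  utils::write.csv(cl, file.path(dir, "clinical.csv"), row.names = FALSE)
  write_gmt(bundle$collection, file.path(dir, "gene_sets.gmt"))
  tr <- bundle$truth
  jsonlite::write_json(tr, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$studies)) {
    for (i in seq_along(bundle$studies)) {
      write_dce_study(bundle$studies[[i]]$study, bundle$studies[[i]]$masks,
                      file.path(dir, "imaging"),
                      prefix = bundle$counts$sample_ids[i])
    }
  }
  invisible(dir)
}
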