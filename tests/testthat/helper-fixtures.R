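# Shared fixture builders; all generated in code, seeded by the caller.

# Tiny DCE study: constant pre-contrast signal with a prescribed voxelwise
# enhancement ratio between the early and late series.
make_toy_study <- function(shape = c(4, 4, 4), ratio = 0.5, s0 = 100) {
  pre <- array(s0, shape)
  early <- array(s0, shape)
  late <- early * (1 + ratio)
  dce_study(list(pre, early, array(s0 * 1.1, shape), late),
            acquisition_times = c(0, 90, 180, 360))
}

full_masks <- function(shape) {
  tissue_masks(array(TRUE, shape), array(TRUE, shape))
}

# Random expression matrix (continuous) with named genes/samples.
make_expr <- function(n_genes, n_samples, seed = 1, kind = "continuous") {
  set.seed(seed)
  if (kind == "counts") {
    v <- matrix(rnbinom(n_genes * n_samples, mu = 50, size = 5),
                n_genes, n_samples)
  } else {
    v <- matrix(rnorm(n_genes * n_samples, 8, 2), n_genes, n_samples)
  }
  expression_matrix(v, sprintf("g%04d", seq_len(n_genes)),
                    sprintf("s%03d", seq_len(n_samples)), kind = kind)
}

# Independent step-by-step ES walk oracle: explicit loop, no vectorization.
es_walk_oracle <- function(t_sorted, member_positions, p) {
  N <- length(t_sorted)
  k <- length(member_positions)
  nr <- sum(abs(t_sorted[member_positions])^p)
  walk <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    if (i %in% member_positions) {
      cur <- cur + abs(t_sorted[i])^p / nr
    } else {
      cur <- cur - 1 / (N - k)
    }
    walk[i] <- cur
  }
  # contract: extremum = first position attaining the maximal |excursion|
  # (to numerical tolerance)
  aw <- abs(walk)
  i_star <- which(aw >= max(aw) - 1e-9)[1L]
  es <- walk[i_star]
  le <- if (es >= 0) {
    sum(member_positions <= i_star) / k
  } else {
    sum(member_positions >= i_star) / k
  }
  list(es = es, max_es_at = i_star, walk = walk, leading_edge = le)
}

# Simple clinical table generator for survival tests.
make_clinical <- function(n, seed = 1, censoring_rate = 0.5,
                          betas = c(age = 0.03)) {
  set.seed(seed)
  age <- round(rnorm(n, 60, 8))
  size_mm <- round(rlnorm(n, log(20), 0.3))
  grade <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.5, 0.2))
  axl <- sample(c("0", "1-3", "4+"), n, replace = TRUE,
                prob = c(0.6, 0.3, 0.1))
  ast <- sample(c("yes", "no"), n, replace = TRUE)
  cov <- cbind(age = age, size_mm = size_mm,
               grade2 = as.numeric(grade == 2),
               grade3 = as.numeric(grade == 3))
  sv <- gen_survival_data(cov, betas, censoring_rate = censoring_rate,
                          seed = seed + 100)
  clinical_table(data.frame(
    sample_id = sprintf("s%04d", seq_len(n)), age = age,
    size_mm = size_mm, grade = grade, axillary_load = axl, ast = ast,
    time = sv$time, event = sv$event, stringsAsFactors = FALSE))
}
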