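test_that("unpenalized fit reproduces the survival::coxph partial-likelihood maximizer", {
  skip_if_not_installed("survival")
  set.seed(601)
  for (rep in 1:6) {
    n <- sample(40:100, 1)
    p <- sample(1:3, 1)
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", 1:p)))
    beta_true <- runif(p, -0.6, 0.6)
    sv <- gen_survival_data(x, setNames(beta_true, colnames(x)),
                            censoring_rate = 0.3, seed = 600 + rep)
    own <- cox_fit(x, sv$time, sv$event, penalize = "none")
    ref <- survival::coxph(survival::Surv(sv$time, sv$event) ~ x,
                           ties = "breslow")
    expect_true(own$converged)
    expect_lt(max(abs(own$terms$beta - unname(coef(ref)))), 1e-5)
    expect_lt(max(abs(own$terms$se - unname(sqrt(diag(vcov(ref)))))), 1e-5)
    expect_lt(abs(own$loglik - ref$loglik[2]), 1e-5)
  }
})

test_that("complete separation: unpenalized fit is flagged monotone, Firth stays finite", {
  # binary covariate perfectly splitting the event order
  n <- 20
  x <- matrix(rep(c(1, 0), each = n / 2), ncol = 1,
              dimnames = list(NULL, "arm"))
  time <- c(seq(1, 10), seq(11, 20))   # all arm=1 events come first
  event <- rep(1, n)
  expect_warning(mle <- cox_fit(x, time, event, penalize = "none"),
                 "monotone")
  expect_true(mle$monotone)
  expect_false(mle$converged)

  firth <- cox_fit(x, time, event, penalize = "firth")
  expect_true(firth$converged)
  expect_lt(abs(firth$terms$beta), 10)
  expect_true(all(is.finite(c(firth$terms$ci_low, firth$terms$ci_high))))

  prof <- cox_fit(x, time, event, penalize = "firth", ci = "profile")
  expect_true(all(is.finite(c(prof$terms$ci_low, prof$terms$ci_high))))
  expect_lt(prof$terms$ci_low, prof$terms$hr)
  expect_gt(prof$terms$ci_high, prof$terms$hr)
})

test_that("the Firth penalty vanishes at large n", {
  set.seed(602)
  n <- 1000
  x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "z"))
  sv <- gen_survival_data(x, c(z = 0.7), censoring_rate = 0.2, seed = 603)
  firth <- cox_fit(x, sv$time, sv$event, penalize = "firth")
  mle <- cox_fit(x, sv$time, sv$event, penalize = "none")
  expect_lt(abs(firth$terms$beta - mle$terms$beta), 0.02)
})

test_that("Firth estimates are invariant to covariate recentering", {
  set.seed(604)
  n <- 120
  x <- matrix(rnorm(n, 5, 2), ncol = 1, dimnames = list(NULL, "z"))
  sv <- gen_survival_data(x, c(z = 0.4), censoring_rate = 0.4, seed = 605)
  f1 <- cox_fit(x, sv$time, sv$event, penalize = "firth")
  x2 <- x - 100
  f2 <- cox_fit(x2, sv$time, sv$event, penalize = "firth")
  expect_equal(f1$terms$beta, f2$terms$beta, tolerance = 1e-6)
})

test_that("degenerate designs and inputs are rejected", {
  set.seed(606)
  n <- 30
  x <- cbind(a = rnorm(n))
  x2 <- cbind(x, b = 2 * x[, 1])
  time <- rexp(n) + 0.1
  event <- rbinom(n, 1, 0.7)
  expect_error(suppressWarnings(cox_fit(x2, time, event)), "collinear")
  expect_error(cox_fit(x, time, rep(0, n)), "at least one event")
  expect_error(cox_fit(x, c(time[-1], -1), event), "positive")
  xna <- x; xna[1] <- NA
  expect_error(cox_fit(xna, time, event), "missing")
})

test_that("survival generator calibrates censoring and respects the null", {
  set.seed(607)
  x <- cbind(z = rnorm(800))
  # no censoring -> every subject has an event
  sv0 <- gen_survival_data(x, c(z = 0.3), censoring_rate = 0, seed = 1)
  expect_true(all(sv0$event == 1))
  # target fraction realized within 0.05 at n >= 500
  for (target in c(0.3, 0.6, 0.9)) {
    sv <- gen_survival_data(x, c(z = 0.3), censoring_rate = target,
                            seed = 2)
    expect_lt(abs(mean(sv$event == 0) - target), 0.05)
  }
  expect_error(gen_survival_data(x, c(z = 0.3), censoring_rate = 1),
               "censoring_rate")
  expect_error(gen_survival_data(x, c(q = 1)), "not in the matrix")
  expect_error(gen_survival_data(x, c(z = 1), baseline_shape = -1),
               "baseline")
})

test_that("a planted log-hazard is recovered across replicates", {
  est <- vapply(1:20, function(seed) {
    set.seed(seed)
    x <- matrix(rbinom(300, 1, 0.5), ncol = 1, dimnames = list(NULL, "b"))
    sv <- gen_survival_data(x, c(b = 0.5), censoring_rate = 0.3,
                            seed = 1000 + seed)
    cox_fit(x, sv$time, sv$event, penalize = "none")$terms$beta
  }, 0)
  expect_lt(abs(mean(est) - 0.5), 0.08)
})

test_that("construct covariate maps AST x nodal status to four levels", {
  expect_identical(as.character(make_construct("no", "0")), "noAST/node-")
  expect_identical(as.character(make_construct("yes", "4+")), "AST/node+")
  expect_identical(as.character(make_construct("yes", "1-3")),
                   as.character(make_construct("yes", "4+")))
  expect_identical(levels(make_construct("no", "0"))[1], "noAST/node-")
  expect_error(make_construct("maybe", "0"), "unknown ast")
  expect_error(make_construct("yes", "5"), "unknown axillary_load")
})

test_that("clinical table validates and applies the complete-case rule", {
  df <- data.frame(sample_id = c("a", "b", "c"), age = c(50, NA, 60),
                   size_mm = c(20, 22, 19), grade = c(1, 2, 3),
                   axillary_load = c("0", "1-3", "4+"),
                   ast = c("no", "yes", "yes"),
                   time = c(10, 20, 30), event = c(1, 0, 1),
                   stringsAsFactors = FALSE)
  expect_message(ct <- clinical_table(df), "complete-case")
  expect_identical(nrow(ct), 2L)
  expect_identical(attr(ct, "n_dropped"), 1L)

  bad <- df[c(1, 3), ]; bad$grade <- c(1, 4)
  expect_error(clinical_table(bad), "grade")

  design <- survival_design(ct)
  expect_identical(colnames(design),
                   c("age", "size_mm", "grade2", "grade3", "AST/node-",
                     "noAST/node+", "AST/node+"))

  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(ct), path, row.names = FALSE)
  back <- read_clinical_csv(path)
  expect_identical(back$sample_id, ct$sample_id)
  expect_identical(as.character(back$axillary_load),
                   as.character(ct$axillary_load))
})

test_that("fit_paper_models recovers a planted per-SD CPE effect", {
  set.seed(608)
  n <- 400
  cl <- make_clinical(n, seed = 609, censoring_rate = 0.5,
                      betas = c(age = 0.03))
  cpe_z <- as.numeric(standardize(rnorm(n)))
  # rebuild survival with the cpe effect included
  cov <- cbind(survival_design(cl), cpe = cpe_z)
  sv <- gen_survival_data(cov, c(age = 0.03, cpe = -0.6),
                          censoring_rate = 0.5, seed = 610)
  cl$time <- sv$time
  cl$event <- sv$event
  fit <- fit_paper_models(cl, cpe = cpe_z, which = "cpe_only")
  row <- fit$terms[fit$terms$term == "cpe", ]
  expect_lt(row$hr, 1)
  expect_lt(abs(row$beta - (-0.6)), 2 * row$se)
})
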