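make_ranked <- function(t_sorted) {
  structure(data.frame(gene_id = sprintf("g%03d", seq_along(t_sorted)),
                       t = t_sorted, stringsAsFactors = FALSE),
            class = c("ranked_gene_list", "data.frame"))
}

test_that("enrichment walk matches the explicit step-loop oracle", {
  set.seed(101)
  for (rep in 1:60) {
    N <- sample(10:50, 1)
    k <- sample(2:min(8, N - 1), 1)
    t_sorted <- sort(rnorm(N, sd = 2), decreasing = TRUE)
    pos <- sort(sample(N, k))
    p <- sample(c(0, 1, 1.5), 1)
    ranked <- make_ranked(t_sorted)
    got <- enrichment_score(ranked, ranked$gene_id[pos],
                            weight_exponent = p, min_set_size = 2)
    oracle <- es_walk_oracle(t_sorted, pos, p)
    expect_equal(got$es, oracle$es, tolerance = 1e-12)
    expect_identical(got$max_es_at, oracle$max_es_at)
    expect_equal(got$walk, oracle$walk, tolerance = 1e-12)
    expect_equal(leading_edge_fraction(got), oracle$leading_edge,
                 tolerance = 1e-12)
  }
})

test_that("top-k sets score ES = 1 at p = 0 and bottom sets score negative", {
  t_sorted <- sort(rnorm(30), decreasing = TRUE)
  ranked <- make_ranked(t_sorted)
  k <- 6L
  top <- enrichment_score(ranked, ranked$gene_id[1:k], weight_exponent = 0)
  expect_equal(top$es, 1, tolerance = 1e-12)
  expect_identical(top$max_es_at, k)
  expect_equal(leading_edge_fraction(top), 1)

  bottom <- enrichment_score(ranked, ranked$gene_id[26:30],
                             weight_exponent = 0)
  expect_lt(bottom$es, 0)

  single <- enrichment_score(ranked, ranked$gene_id[17],
                             weight_exponent = 0, min_set_size = 1)
  expect_equal(leading_edge_fraction(single), 1)
})

test_that("walk starts/ends at zero and ES is bounded in [-1, 1]", {
  set.seed(103)
  for (rep in 1:20) {
    N <- sample(10:40, 1)
    t_sorted <- sort(rnorm(N), decreasing = TRUE)
    pos <- sort(sample(N, 4))
    got <- enrichment_score(make_ranked(t_sorted),
                            sprintf("g%03d", pos), weight_exponent = 1,
                            min_set_size = 2)
    expect_equal(got$walk[N], 0, tolerance = 1e-12)
    expect_true(all(abs(got$walk) <= 1 + 1e-12))
    expect_lte(abs(got$es), 1 + 1e-12)
  }
})

test_that("reversing the ranking mirrors ES and extremum position at p = 0", {
  set.seed(104)
  N <- 25L
  t_sorted <- sort(rnorm(N), decreasing = TRUE)
  pos <- c(2, 7, 11, 20)
  fwd <- enrichment_score(make_ranked(t_sorted), sprintf("g%03d", pos),
                          weight_exponent = 0, min_set_size = 2)
  # reversed ranking: members sit at mirrored positions
  rev_ranked <- make_ranked(rev(t_sorted))
  rev_ids <- rev_ranked$gene_id[N - pos + 1]
  bwd <- enrichment_score(rev_ranked, rev_ids, weight_exponent = 0,
                          min_set_size = 2)
  expect_equal(bwd$es, -fwd$es, tolerance = 1e-12)
  # reversed walk is the negated forward walk read backwards from the
  # zero endpoint: W_rev(j) = -W_fwd(N - j), so the extremum mirrors to
  # N - i* under the first-occurrence tie rule
  expect_identical(bwd$max_es_at, N - fwd$max_es_at)
})

test_that("ES agrees with the fgsea reference statistic", {
  skip_if_not_installed("fgsea")
  set.seed(105)
  for (rep in 1:10) {
    N <- 60
    t_sorted <- sort(rnorm(N, sd = 2), decreasing = TRUE)
    pos <- sort(sample(N, 7))
    got <- enrichment_score(make_ranked(t_sorted),
                            sprintf("g%03d", pos), weight_exponent = 1)
    sref <- fgsea::calcGseaStat(stats::setNames(t_sorted,
                                                sprintf("g%03d", 1:N)),
                                selectedStats = pos, gseaParam = 1)
    expect_equal(got$es, sref, tolerance = 1e-10)
  }
})

test_that("degenerate sets are rejected with clear errors", {
  ranked <- make_ranked(sort(rnorm(20), decreasing = TRUE))
  expect_error(enrichment_score(ranked, c("zz1", "zz2")), "min_set_size")
  expect_error(enrichment_score(ranked, ranked$gene_id), "universe")
  flat <- make_ranked(rep(0, 20))
  expect_error(enrichment_score(flat, flat$gene_id[1:6],
                                weight_exponent = 1), "zero")
})

test_that("permutation null is reproducible and respects the scheme", {
  expr <- make_expr(60, 20, seed = 106)
  cpe <- as.numeric(standardize(rnorm(20)))
  coll <- gene_set_collection(list(
    A = expr$gene_ids[1:8], B = expr$gene_ids[30:45]))
  n1 <- permutation_null(expr, cpe, coll, n_perm = 60, scheme = "response",
                         seed = 5)
  n2 <- permutation_null(expr, cpe, coll, n_perm = 60, scheme = "response",
                         seed = 5)
  expect_identical(n1, n2)
  n3 <- permutation_null(expr, cpe, coll, n_perm = 60, scheme = "gene",
                         seed = 5)
  expect_identical(dim(n3), c(2L, 60L))
  expect_false(identical(n1, n3))
  expect_warning(permutation_null(expr, cpe, coll, n_perm = 10,
                                  scheme = "gene", seed = 1), "n_perm")
})

test_that("NES normalization and FDR behave at the identities", {
  observed <- data.frame(set_name = c("A", "B"), set_size = c(5L, 5L),
                         es = c(0.5, 0.9), max_es_at = c(3L, 4L),
                         leading_edge = c(0.8, 1.0),
                         stringsAsFactors = FALSE)
  # null for A has positive mean exactly 0.5 -> NES = 1
  null_es <- rbind(A = c(0.4, 0.6, 0.5, -0.3, 0.5),
                   B = c(0.1, 0.2, 0.15, -0.2, 0.05))
  res <- normalize_and_fdr(observed, null_es)
  expect_equal(res$nes[res$set_name == "A"], 1, tolerance = 1e-12)
  # B exceeds every null value -> p = 0, q = 0
  expect_equal(res$p_perm[res$set_name == "B"], 0)
  expect_equal(res$fdr_q[res$set_name == "B"], 0)
  expect_true(all(res$fdr_q >= 0 & res$fdr_q <= 1))
  expect_equal(sign(res$nes), sign(res$es))
})

test_that("null NES magnitudes center near 1 and observed nulls are calibrated", {
  set.seed(107)
  expr <- make_expr(200, 30, seed = 107)
  cpe <- as.numeric(standardize(rnorm(30)))
  sets <- lapply(1:15, function(i) sample(expr$gene_ids, 12))
  names(sets) <- sprintf("S%02d", 1:15)
  coll <- gene_set_collection(sets)
  res <- run_gsea(expr, cpe, coll, n_perm = 200, scheme = "gene", seed = 9)
  # no planted signal: NES magnitudes around 1, none extreme
  expect_lt(abs(median(abs(res$nes)) - 1), 0.35)
  # observed ES within the null central interval for most sets
  null_es <- permutation_null(expr, cpe, coll, n_perm = 200,
                              scheme = "gene", seed = 9)
  inside <- vapply(seq_len(nrow(res)), function(i) {
    q <- quantile(null_es[res$set_name[i], ], c(0.025, 0.975))
    res$es[i] >= q[1] && res$es[i] <= q[2]
  }, TRUE)
  expect_gte(mean(inside), 0.7)
})

test_that("GMT files round-trip and filter by universe and size", {
  sets <- list(ALPHA = sprintf("g%02d", 1:10),
               BETA = sprintf("g%02d", 5:30),
               TINY = c("g01", "g02"))
  coll <- gene_set_collection(sets, c("first", "second", "small"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, path)
  back <- read_gmt(path)
  expect_identical(back$sets, coll$sets)
  expect_identical(unname(back$descriptions), c("first", "second", "small"))

  filt <- filter_collection(back, sprintf("g%02d", 1:20), min_size = 5,
                            max_size = 50)
  expect_identical(names(filt$sets), c("ALPHA", "BETA"))
  expect_identical(filt$sets$BETA, sprintf("g%02d", 5:20))
  expect_error(filter_collection(back, c("zz"), min_size = 1), "survives")
})
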