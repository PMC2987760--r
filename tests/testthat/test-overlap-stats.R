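test_that("log binomial coefficients are exact and symmetric", {
  expect_equal(log_binomial(4, 2), log(6), tolerance = 1e-14)
  expect_identical(log_binomial(10, 0), 0)
  expect_equal(log_binomial(50, 25), log(oracle_choose(50, 25)),
               tolerance = 1e-13)
  ns <- c(17, 30, 45)
  for (n in ns) {
    k <- 0:n
    expect_equal(log_binomial(n, k), log_binomial(n, n - k), tolerance = 1e-13)
  }
  expect_error(log_binomial(3, 4), class = "sigreverse_domain_error")
  expect_error(log_binomial(-1, 0), class = "sigreverse_domain_error")
})

test_that("overlap counts enforce the hypergeometric bounds", {
  oc <- overlap_counts(716, 419, 56, 41)
  expect_s3_class(oc, "overlap_counts")
  expect_error(overlap_counts(10, 11, 2, 1), class = "sigreverse_domain_error")
  expect_error(overlap_counts(10, 4, 3, 4), class = "sigreverse_domain_error")
  # k below the lower support bound n + K - N
  expect_error(overlap_counts(10, 8, 7, 4), class = "sigreverse_domain_error")
  expect_error(overlap_counts(10, 4, 3, -1), class = "sigreverse_domain_error")
})

test_that("point mass matches closed forms and an independent distribution oracle", {
  expect_equal(hypergeom_pmf(overlap_counts(4, 2, 2, 1)), 2 / 3,
               tolerance = 1e-14)
  expect_equal(round(hypergeom_pmf(overlap_counts(419, 9, 41, 3)), 3), 0.041)
  expect_equal(round(hypergeom_pmf(overlap_counts(419, 5, 41, 3)), 3), 0.007)
  set.seed(5)
  for (rep in 1:50) {
    N <- sample(2:500, 1); K <- sample.int(N, 1); n <- sample.int(N, 1)
    k <- sample(max(0, n + K - N):min(K, n), 1)
    c0 <- overlap_counts(N, K, n, k)
    expect_equal(hypergeom_pmf(c0), stats::dhyper(k, K, N - K, n),
                 tolerance = 1e-12)
    expect_equal(hypergeom_upper(c0),
                 stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_equal(hypergeom_lower(c0), stats::phyper(k, K, N - K, n),
                 tolerance = 1e-12)
  }
})

test_that("tails hit their boundary values and obey the complement identity", {
  expect_identical(hypergeom_upper(overlap_counts(100, 30, 10, 0)), 1)
  expect_identical(hypergeom_lower(overlap_counts(100, 30, 10, 10)), 1)
  expect_equal(hypergeom_upper(overlap_counts(419, 9, 41, 3)),
               oracle_hyper_upper(3, 419, 9, 41), tolerance = 1e-12)
  # P[X <= 1] = 1 - P[X >= 2] at (N=10, K=4, n=3)
  expect_equal(hypergeom_lower(overlap_counts(10, 4, 3, 1)),
               1 - hypergeom_upper(overlap_counts(10, 4, 3, 2)),
               tolerance = 1e-14)
})

test_that("the upper tail is strictly decreasing in k on the support interior", {
  for (par in list(c(50, 20, 15), c(200, 80, 33), c(716, 419, 56))) {
    N <- par[1]; K <- par[2]; n <- par[3]
    ks <- max(0, n + K - N):min(K, n)
    pu <- vapply(ks, function(k) hypergeom_upper(overlap_counts(N, K, n, k)), 0)
    expect_true(all(diff(pu) <= 0))
    # strict decrease wherever the step is representable in doubles
    w <- pu > 1e-12 & pu < 1 - 1e-12
    expect_true(all(diff(pu[w]) < 0))
  }
})

test_that("overlap tests call enrichment/depletion by tail and direction", {
  up <- overlap_test(overlap_counts(716, 419, 56, 41))
  expect_identical(up$call, "enriched")
  down <- overlap_test(overlap_counts(716, 301, 56, 16))
  expect_identical(down$call, "depleted")
  mid <- overlap_test(overlap_counts(100, 50, 10, 5))
  expect_identical(mid$call, "neutral")
  # point convention switches the driving probability
  pt <- overlap_test(overlap_counts(419, 9, 41, 3), convention = "point")
  expect_identical(pt$call, "enriched")
  expect_true(pt$p_point < 0.05 && pt$p_upper < 0.05)
})

test_that("directional overlap test uses the pooled universe and excludes outside drug genes", {
  # tiny instance: universe 6, up/down disjoint triples, drug = up
  pooled <- sig(c("A", "B", "C"), c("D", "E", "F"), "p")
  drug <- gene_set(c("A", "B", "C", "ZZ_OUTSIDE"), "drug")
  res <- directional_overlap_test(pooled, drug)
  expect_identical(res$venn$n_universe_drug, 3L)  # outside gene excluded
  expect_identical(res$up_test$counts$k, 3L)
  expect_equal(res$up_test$p_upper, 1 / 20, tolerance = 1e-14)
  # p equals exactly 1/20, so it is not below alpha = 0.05; at a looser
  # level the enrichment call fires
  expect_identical(res$up_test$call, "neutral")
  expect_identical(directional_overlap_test(pooled, drug, alpha = 0.1)$up_test$call,
                   "enriched")

  # disjoint drug: both tests neutral with p = 1
  res0 <- directional_overlap_test(pooled, gene_set(c("X", "Y"), "drug"))
  expect_identical(res0$up_test$call, "neutral")
  expect_identical(res0$down_test$call, "neutral")
  expect_identical(res0$up_test$p_upper, 1)
  expect_identical(res0$down_test$p_lower, 1)

  empty <- sig(character(0), character(0), "e")
  expect_error(directional_overlap_test(empty, drug),
               class = "sigreverse_domain_error")
})
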