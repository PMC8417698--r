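# Fisher over-representation, BH, TSEA running sum and leading prioritization.

test_that("the inflammasome-style contingency reproduces p = 0.19", {
  uni <- sprintf("g%05d", 1:12466)
  top <- uni[1:125]                      # the top-1% set
  query <- c(uni[1], uni[500:519])       # 1 of 21 query genes inside it
  r <- fisher_enrichment(query, list(top1 = top), uni)
  expect_equal(round(r$p, 2), 0.19)
  expect_equal(r$k, 1L)
})

test_that("k = 0 gives p = 1 exactly and query outside universe errors", {
  uni <- letters[1:20]
  r <- fisher_enrichment(c("a", "b"), list(s = c("c", "d")), uni)
  expect_identical(r$p, 1)
  expect_error(fisher_enrichment(c("a", "zzz"), list(s = "c"), uni), "zzz")
})

test_that("Fisher p matches brute-force mass summation on random small tables", {
  set.seed(10)
  for (i in 1:50) {
    N <- sample(8:60, 1)
    uni <- sprintf("u%02d", 1:N)
    n <- sample(1:(N - 1), 1)
    K <- sample(1:(N - 1), 1)
    query <- sample(uni, n)
    set <- sample(uni, K)
    r <- fisher_enrichment(query, list(s = set), uni)
    expect_equal(r$p, oracle_hyper_tail(r$k, K, N, n), tolerance = 1e-12)
  }
})

test_that("odds ratio uses Haldane correction on zero cells and FDR >= p", {
  uni <- sprintf("u%02d", 1:40)
  sets <- list(a = uni[1:10], b = uni[11:14], c = uni[30:40])
  r <- fisher_enrichment(uni[1:10], sets, uni)
  expect_true(all(is.finite(r$OR)))
  expect_true(all(r$OR >= 0))
  expect_true(all(r$CI_low <= r$OR & r$OR <= r$CI_high))
  expect_true(all(r$FDR >= r$p - 1e-15))
})

test_that("bh_adjust matches the from-scratch step-up oracle", {
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("TSEA walk matches the hand-computed KS walk on a tiny example", {
  # N = 5, set = ranks {1, 2}, weight 0: steps +1/2, +1/2, -1/3, -1/3, -1/3
  pt <- toy_priority(c(5, 4, 3, 2, 1))
  set <- list(s = pt$gene[1:2])
  res <- tsea(pt, set, n_perm = 50, weight_exponent = 0, seed = 1)
  expect_equal(res$ES, 1)
  expect_equal(res$leading_genes, paste(pt$gene[1:2], collapse = ","))
})

test_that("a top-K set scores higher than a random set of the same size", {
  set.seed(2)
  pt <- toy_priority(runif(100))
  sets <- list(top = pt$gene[1:10], rand = sample(pt$gene, 10))
  res <- tsea(pt, sets, n_perm = 100, seed = 3)
  expect_gt(res$ES[res$set_id == "top"], res$ES[res$set_id == "rand"])
  expect_lt(res$p_perm[res$set_id == "top"], 0.05)
})

test_that("ES with weight 0 is invariant under order-preserving rating transforms", {
  set.seed(5)
  pt <- toy_priority(runif(50))
  set <- list(s = sample(pt$gene, 8))
  es1 <- tsea(pt, set, n_perm = 20, weight_exponent = 0, seed = 9)$ES
  pt2 <- pt; pt2$rating <- sqrt(pt2$rating) + 1  # monotone transform
  es2 <- tsea(pt2, set, n_perm = 20, weight_exponent = 0, seed = 9)$ES
  expect_equal(es1, es2, tolerance = 1e-12)
})

test_that("leading prioritization is the left-most region ahead of the peak", {
  # peak at the last hit -> all members are leading
  pt <- toy_priority(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1))
  expect_setequal(leading_prioritization(pt, pt$gene[c(1, 2, 3)], 0),
                  pt$gene[c(1, 2, 3)])
  # hits at ranks 1, 2, 9 (w = 0): walk peaks after rank 2 -> first two hits
  expect_equal(leading_prioritization(pt, pt$gene[c(1, 2, 9)], 0),
               pt$gene[c(1, 2)])
})

test_that("TSEA permutation p-values are calibrated under the null", {
  set.seed(99)
  pt <- toy_priority(runif(200), sprintf("g%03d", 1:200))
  sets <- lapply(1:100, function(i) sample(pt$gene, 15))
  names(sets) <- sprintf("S%03d", 1:100)
  res <- tsea(pt, sets, n_perm = 200, seed = 7)
  rate <- mean(res$p_perm < 0.05)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.10)
})

test_that("missing members and tiny sets produce warnings, not errors", {
  pt <- toy_priority(c(3, 2, 1))
  expect_warning(res <- tsea(pt, list(s = c(pt$gene[1:2], "ghost")), n_perm = 10),
                 "missing")
  expect_equal(res$size, 2L)
  expect_warning(tsea(pt, list(tiny = pt$gene[1]), n_perm = 10), "skipped")
})

test_that("Fisher p-values stay calibrated on null synthetic collections", {
  ps <- unlist(lapply(1:10, function(sd) {
    sim <- simulate_all(synthetic_config(seed = 100 + sd, evidence_effect = 0,
                                         n_enriched_sets = 0L))
    pr <- prioritize(sim$network, sim$evidence)
    fisher_enrichment(top_fraction(pr, 0.02), sim$genesets,
                      igraph::V(sim$network)$name)$p
  }))
  rate <- mean(ps < 0.05)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.10)
})
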