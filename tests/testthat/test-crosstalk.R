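# Max-scoring connected subnetwork, degree-preserving permutation null,
# pathway-centric MST graph.

test_that("score_nodes shifts ratings by theta", {
  pt <- toy_priority(runif(10, 1, 4))
  expect_true(all(score_nodes(pt, 0) >= 0))
  expect_true(all(score_nodes(pt, 5) <= 0))
  # theta = median rating, N even, distinct -> exactly half positive
  pt2 <- toy_priority(seq(0.1, 1, length.out = 10))
  expect_equal(sum(score_nodes(pt2, median(pt2$rating)) > 0), 5L)
})

test_that("all-positive scores on a connected graph return the whole graph", {
  g <- rand_connected_graph(8, 0.5)
  s <- setNames(runif(8, 0.1, 1), igraph::V(g)$name)
  m <- find_crosstalk(g, s)
  expect_setequal(m$genes, igraph::V(g)$name)
})

test_that("a mild-negative bridge joining two positive clusters is included", {
  g <- igraph::graph_from_literal(p1 - p2, p2 - p3, p1 - p3,   # clique 1
                                  q1 - q2, q2 - q3, q1 - q3,   # clique 2
                                  p3 - b, b - q1,              # bridge
                                  p1 - n1, q3 - n2, n1 - n3, n2 - n4)
  s <- c(p1 = 1, p2 = 1, p3 = 1, q1 = 1, q2 = 1, q3 = 1, b = -0.3,
         n1 = -1, n2 = -1, n3 = -1, n4 = -1)
  m <- find_crosstalk(g, s)
  expect_setequal(m$genes, c("p1", "p2", "p3", "b", "q1", "q2", "q3"))
  expect_equal(m$total_score, 5.7, tolerance = 1e-12)
  # agrees with the independent exhaustive oracle
  o <- oracle_best_connected(g, s)
  expect_equal(m$total_score, o$score, tolerance = 1e-12)
})

test_that("no positive score is an error", {
  g <- igraph::make_graph(~ A - B)
  expect_error(find_crosstalk(g, c(A = -1, B = 0)), "no signal")
})

test_that("exact search matches the recursive-enumeration oracle on random instances", {
  set.seed(20)
  for (i in 1:15) {
    n <- sample(6:12, 1)
    g <- rand_connected_graph(n, 0.35)
    s <- setNames(round(runif(n, -2, 2), 2), igraph::V(g)$name)
    if (!any(s > 0)) s[1] <- 1
    m <- find_crosstalk(g, s)
    o <- oracle_best_connected(g, s)
    expect_equal(m$total_score, o$score, tolerance = 1e-9)
    expect_true(igraph::is_connected(m$subgraph))
  }
})

test_that("the heuristic always returns a connected module beating the best single node", {
  set.seed(30)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    g <- rand_connected_graph(n, 0.12)
    s <- setNames(round(runif(n, -2, 2), 2), igraph::V(g)$name)
    if (!any(s > 0)) s[1] <- 1
    m <- find_crosstalk(g, s, crosstalk_params(exact_limit = 0))
    expect_true(igraph::is_connected(m$subgraph))
    expect_gte(m$total_score, max(s) - 1e-12)
  }
})

test_that("degree-preserving permutation keeps per-bin score multisets", {
  set.seed(8)
  g <- rand_connected_graph(40, 0.12)
  s <- setNames(runif(40, -1, 1), igraph::V(g)$name)
  deg <- igraph::degree(g)
  for (i in 1:50) {
    ps <- netprior:::permute_scores_degree_preserving(s, deg, 1L)
    for (d in unique(deg)) {
      expect_equal(sort(unname(ps[deg == d])), sort(unname(s[deg == d])),
                   tolerance = 1e-15)
    }
  }
})

test_that("permutation significance: constant scores tie to p = 1; floor is 1/(1+n_perm)", {
  g <- rand_connected_graph(12, 0.4)
  s <- setNames(rep(1, 12), igraph::V(g)$name)
  m <- find_crosstalk(g, s)
  sig <- permutation_significance(g, s, m$total_score,
                                  crosstalk_params(n_perm = 20, seed = 1))
  expect_equal(sig$p_perm, 1)
  # empirical floor with 100 permutations is ~9.9e-3
  expect_equal(1 / (1 + 100), 0.00990099, tolerance = 1e-6)
  expect_gte(sig$p_perm, 1 / (1 + 20))
})

test_that("extrapolated p can drop far below the empirical floor", {
  set.seed(41)
  g <- rand_connected_graph(60, 0.08)
  nodes <- igraph::V(g)$name
  mod <- unique(unlist(igraph::ego(g, 1, nodes[1])))
  s <- setNames(rep(-1, 60), nodes)
  s[nodes[mod]] <- 3
  m <- find_crosstalk(g, s, crosstalk_params(exact_limit = 0))
  sig <- permutation_significance(g, s, m$total_score,
                                  crosstalk_params(n_perm = 50, seed = 2, exact_limit = 0))
  expect_gte(sig$p_perm, 1 / 51)
  expect_lt(sig$p_extrapolated, sig$p_perm + 1e-12)
})

test_that("pathway graph keeps only MST edges with deterministic ties", {
  uni <- sprintf("u%02d", 1:40)
  # three significant pathways sharing one common gene pairwise equally
  sets <- list(A = c(uni[1:6], "u40"), B = c(uni[7:12], "u40"), C = c(uni[13:18], "u40"))
  sets <- lapply(sets, unique)
  query <- uni[c(1:3, 7:9, 13:15)]
  pg <- pathway_graph(query, sets, uni, fdr_cutoff = 0.2)
  expect_equal(nrow(pg$nodes), 3L)
  expect_equal(sum(pg$edges$mst_flag), 2L)  # |V| - 1

  # Kruskal by hand: shared counts A-B 6, B-C 6, A-C 1 -> MST = {A-B, B-C}
  sets2 <- list(A = c(uni[1:6], uni[20]), B = c(uni[1:6], uni[11:16]),
                C = c(uni[11:16], uni[20]))
  query2 <- c(uni[1:4], uni[11:13], uni[20])
  pg2 <- pathway_graph(query2, sets2, uni, fdr_cutoff = 0.9)
  e <- pg2$edges
  key <- paste(e$p1, e$p2)
  expect_true(e$mst_flag[key == "A B"])
  expect_true(e$mst_flag[key == "B C"])
  expect_false(e$mst_flag[key == "A C"])
})

test_that("fewer than two significant pathways warns and returns no edges", {
  uni <- sprintf("u%02d", 1:30)
  sets <- list(A = uni[25:30])
  expect_warning(pg <- pathway_graph(uni[1:5], sets, uni), "fewer than 2")
  expect_equal(nrow(pg$edges), 0L)
})
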