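# Supra-hexagonal map: lattice geometry, SOM training, clustering, overlays.
# (block_profiles lives in helper-oracles.R; it is shared with the
# acceptance suite.)

test_that("hexagon counts follow 1 + sum(6i) and rings are correct", {
  for (r in 1:6) {
    map <- build_map(r)
    expect_equal(nrow(map$hexes), 1 + sum(6 * seq_len(r - 1)))
  }
  expect_equal(nrow(build_map(3)$hexes), 19L)
  expect_equal(as.vector(table(build_map(3)$hexes$ring)), c(1L, 6L, 12L))
  m2 <- build_map(2)
  expect_equal(nrow(m2$hexes), 7L)
  expect_equal(sum(map_adjacency(m2)[1, ]), 6L)  # centre touches the whole ring
  expect_equal(sum(map_adjacency(build_map(1))), 0L)
})

test_that("hex-grid distance is a metric on the radius-3 map", {
  co <- build_map(3)$coords
  n <- nrow(co)
  d <- outer(1:n, 1:n, Vectorize(function(i, j) hex_distance(co[i, ], co[j, ])))
  expect_true(all(d == t(d)))
  expect_true(all(diag(d) == 0))
  expect_true(all(d[upper.tri(d)] > 0))
  for (i in 1:n) for (j in 1:n) {
    expect_true(all(d[i, j] <= d[i, ] + d[, j]))
  }
})

test_that("training is deterministic and identical profiles collapse to one hexagon", {
  prof <- block_profiles(1)
  m1 <- train_som(build_map(3), prof, som_params(seed = 5))
  m2 <- train_som(build_map(3), prof, som_params(seed = 5))
  expect_identical(m1$codebook, m2$codebook)
  expect_identical(m1$bmu, m2$bmu)

  same <- matrix(2.5, nrow = 30, ncol = 3,
                 dimnames = list(sprintf("g%02d", 1:30), c("D1", "D2", "D3")))
  ms <- suppressWarnings(train_som(build_map(3), same, som_params(seed = 1)))
  expect_length(unique(ms$bmu), 1L)
  expect_lt(tail(ms$qe, 1), 1e-6)
})

test_that("well-separated profile blobs land in disjoint map regions", {
  seps <- sapply(1:20, function(sd) {
    set.seed(sd)
    prof <- rbind(matrix(runif(150, 0, 1), 30), matrix(runif(150, 4, 5), 30))
    rownames(prof) <- sprintf("g%02d", 1:60)
    colnames(prof) <- paste0("D", 1:5)
    map <- train_som(build_map(3), prof, som_params(seed = sd))
    length(intersect(unique(map$bmu[1:30]), unique(map$bmu[31:60]))) == 0
  })
  expect_gte(sum(seps), 18L)
})

test_that("quantization error does not increase from first to final epoch; BMUs optimal", {
  for (sd in 1:10) {
    map <- train_som(build_map(3), block_profiles(sd), som_params(seed = sd))
    expect_lte(tail(map$qe, 1), map$qe[1] + 1e-12)
    prof <- block_profiles(sd)
    prof_dists <- apply(prof, 1, function(x) colSums((t(map$codebook) - x)^2))
    expect_equal(unname(prof_dists[cbind(map$bmu, seq_len(nrow(prof)))]),
                 unname(apply(prof_dists, 2, min)), tolerance = 1e-12)
  }
})

test_that("clusters are contiguous on every seed and recover planted blocks", {
  aris <- sapply(1:20, function(sd) {
    prof <- block_profiles(sd)
    map <- train_som(build_map(3), prof, som_params(seed = sd))
    cl <- cluster_map(map, 4)
    adj <- map_adjacency(map)
    for (cc in unique(cl)) {
      idx <- which(cl == cc)
      sub <- igraph::graph_from_adjacency_matrix(adj[idx, idx, drop = FALSE],
                                                 mode = "undirected")
      expect_true(igraph::is_connected(sub))
    }
    adjusted_rand_index(cl[map$bmu], rep(1:4, each = 15))
  })
  expect_gte(sum(aris >= 0.7), 18L)
})

test_that("degenerate cluster counts work", {
  map <- train_som(build_map(3), block_profiles(3), som_params(seed = 3))
  expect_equal(unique(cluster_map(map, 1)), "C1")
  expect_length(unique(cluster_map(map, 19)), 19L)
  expect_error(cluster_map(map, 0), "k must be")
})

test_that("binary overlay: extremes and the pooled-percentage identity", {
  prof <- block_profiles(4)
  map <- train_som(build_map(3), prof, som_params(seed = 4))
  genes <- rownames(prof)
  all_tr <- data.frame(gene = genes, tractable = 1L)
  ov <- overlay_binary(map, all_tr)
  expect_true(all(ov$hexagons$probability[ov$hexagons$n_genes > 0] == 1))
  none_tr <- data.frame(gene = genes, tractable = 0L)
  ov0 <- overlay_binary(map, none_tr)
  expect_true(all(ov0$hexagons$probability[ov0$hexagons$n_genes > 0] == 0))

  set.seed(9)
  mixed <- data.frame(gene = genes, tractable = rbinom(length(genes), 1, 0.4))
  cl <- cluster_map(map, 4)
  ovm <- overlay_binary(map, mixed, clusters = cl)
  hx <- ovm$hexagons
  for (i in seq_len(nrow(ovm$clusters))) {
    idx <- which(cl == ovm$clusters$cluster[i])
    pooled <- 100 * sum(hx$n_tractable[idx]) / sum(hx$n_genes[idx])
    # pooled ratio == mapped-count-weighted mean of hexagon probabilities
    wmean <- 100 * sum(hx$probability[idx] * hx$n_genes[idx], na.rm = TRUE) /
      sum(hx$n_genes[idx])
    expect_equal(ovm$clusters$percentage[i], pooled, tolerance = 1e-12)
    expect_equal(pooled, wmean, tolerance = 1e-12)
  }
})

test_that("disease correlations: identities, hand cases, null behaviour", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  dc <- disease_correlations(m)
  expect_equal(dc$r["a", "a"], 1)
  expect_equal(dc$r["a", "b"], 1)
  expect_equal(dc$r["a", "c"], -1)
  set.seed(17)
  meds <- sapply(1:100, function(i) {
    x <- matrix(rnorm(53 * 2), 53)
    cor(x[, 1], x[, 2])
  })
  expect_lt(abs(median(meds)), 0.1)
  const <- cbind(a = rep(1, 5), b = rnorm(5))
  expect_warning(dcz <- disease_correlations(const), "zero-variance")
  expect_true(is.na(dcz$r["a", "b"]))
  expect_error(disease_correlations(m[1:2, ]), "at least 3")
})

test_that("tractability enrichment returns a one-sided Fisher row", {
  uni <- sprintf("u%02d", 1:50)
  tract <- data.frame(gene = uni, tractable = c(rep(1L, 10), rep(0L, 40)))
  r <- tractability_enrichment(uni[1:10], tract, uni)
  expect_equal(r$k, 10L)
  expect_lt(r$p, 1e-6)
})

test_that("disease_order returns a permutation of the diseases", {
  map <- train_som(build_map(3), block_profiles(6), som_params(seed = 6))
  expect_setequal(disease_order(map), paste0("D", 1:4))
})
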