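# Generator: planted structure, determinism, and distributional contracts.

test_that("generate_network meets its postconditions and rejects bad models", {
  cfg <- synthetic_config(n_genes = 100L, mean_degree = 4, seed = 1L)
  g <- generate_network(cfg)
  expect_equal(igraph::vcount(g), 100L)
  expect_true(igraph::is_connected(g))
  expect_true(igraph::is_simple(g))
  expect_true(all(igraph::E(g)$evidence %in% c("experiments", "databases")))

  dense <- generate_network(synthetic_config(n_genes = 10L, mean_degree = 9,
                                             module_size = 5L, seed = 2L))
  expect_true(igraph::is_simple(dense))
  expect_lte(igraph::ecount(dense), choose(10, 2))

  expect_error(synthetic_config(network_model = "smallworld"))
})

test_that("configuration-model networks are connected and simple too", {
  g <- generate_network(synthetic_config(n_genes = 200L, network_model = "configuration",
                                         seed = 5L))
  expect_true(igraph::is_connected(g))
  expect_true(igraph::is_simple(g))
})

test_that("preferential attachment has a heavier degree tail than the configuration model", {
  maxdeg <- sapply(1:10, function(sd) {
    pa <- generate_network(synthetic_config(n_genes = 2000L, seed = sd))
    cm <- generate_network(synthetic_config(n_genes = 2000L, seed = sd,
                                            network_model = "configuration"))
    c(pa = max(igraph::degree(pa)), cm = max(igraph::degree(cm)))
  })
  expect_true(all(maxdeg["pa", ] > maxdeg["cm", ]))
})

test_that("plant_module grows a connected induced subgraph for every seed", {
  g <- generate_network(synthetic_config(n_genes = 200L, seed = 3L))
  set.seed(11)
  expect_length(plant_module(g, 1L), 1L)
  expect_setequal(plant_module(g, 200L), igraph::V(g)$name)
  for (sd in 1:20) {
    set.seed(sd)
    mod <- plant_module(g, 25L)
    expect_length(mod, 25L)
    expect_true(igraph::is_connected(igraph::induced_subgraph(g, mod)))
  }
  expect_error(plant_module(g, 500L), "exceeds")
})

test_that("evidence uplift is present at effect 3 and absent at effect 0", {
  # null case: planted and background layer means agree within sampling error
  cfg0 <- synthetic_config(seed = 4L, evidence_effect = 0)
  g <- generate_network(cfg0)
  set.seed(21); mod <- plant_module(g, 20L)
  ev0 <- generate_evidence(g, mod, cfg0)
  comb0 <- rowSums(ev0[, c("nGene", "eGene", "cGene")])
  expect_true(all(comb0 >= 0))
  d0 <- mean(comb0[ev0$gene %in% mod]) - mean(comb0[!ev0$gene %in% mod])
  expect_lt(abs(d0), 1)  # ~3 sd of the planted-mean sampling error

  hits <- sapply(1:20, function(sd) {
    cfg <- synthetic_config(seed = sd, evidence_effect = 3, noise_sd = 1)
    sim <- simulate_all(cfg)
    comb <- rowSums(sim$evidence[, c("nGene", "eGene", "cGene")])
    planted <- sim$evidence$gene %in% sim$truth$module_genes
    mean(comb[planted]) > mean(comb[!planted])
  })
  expect_gte(sum(hits), 19L)  # >= 95% of 20 seeds
})

test_that("gene sets, drugs, disease profiles and tractability obey their contracts", {
  sim <- simulate_all(synthetic_config(seed = 6L))
  cfg <- sim$config
  sizes <- lengths(sim$genesets)
  expect_true(all(sizes >= cfg$set_size_range[1] & sizes <= cfg$set_size_range[2]))
  expect_length(sim$truth$enriched_set_ids, cfg$n_enriched_sets)
  expect_true(all(sim$truth$enriched_set_ids %in% names(sim$genesets)))

  expect_true(all(sim$drugs$phase %in% 1:4))
  expect_true(all(table(sim$drugs$gene) >= 1))
  expect_true(all(sim$truth$true_drug_targets %in% sim$truth$module_genes))

  expect_true(all(sim$disease_profiles >= 0 & sim$disease_profiles <= 5))
  expect_equal(dim(sim$disease_profiles), c(cfg$n_genes, cfg$n_diseases))

  tr1 <- generate_tractability(letters, rate = 1, seed = 1L)
  expect_true(all(tr1$tractable == 1L))
  expect_true(all(sim$tractability$tractable %in% 0:1))
})

test_that("drug table round-trips through TSV exactly", {
  sim <- simulate_all(synthetic_config(seed = 8L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(sim$drugs, path)
  back <- read_tsv(path)
  d <- sim$drugs
  attr(d, "true_drug_targets") <- NULL
  expect_equal(back, d)
})

test_that("identical config and seed give identical outputs", {
  a <- simulate_all(synthetic_config(seed = 123L))
  b <- simulate_all(synthetic_config(seed = 123L))
  expect_identical(igraph::as_edgelist(a$network), igraph::as_edgelist(b$network))
  expect_identical(a$evidence, b$evidence)
  expect_identical(unclass(a$genesets), unclass(b$genesets))
  expect_identical(a$truth, b$truth)
  expect_identical(a$disease_profiles, b$disease_profiles)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(a, d1); write_simulation(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})
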