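# Synthetic-data generator with planted ground truth.
#
# Emulates the *processed* inputs of a genetics-led prioritization study:
# a degree-heterogeneous gene-interaction network (STRING-like, with
# "experiments"/"databases" evidence tags), per-gene evidence layers
# (nGene/eGene/cGene-like), gene-set collections, a phase-annotated drug-target
# table, correlated multi-disease priority profiles and sparse binary
# tractability labels.  Raw GWAS/eQTL/Hi-C derivation is out of scope.

#' Configuration for the synthetic-data generator
#'
#' Defaults are the package's "stated world": a 500-gene scale-free network
#' with mean degree 4, a planted connected module of 20 genes receiving a mean
#' evidence uplift of 3 on a half-normal noise floor of sd 1, 50 gene sets of
#' 10-50 members of which 5 oversample planted genes, 9 disease profiles
#' (one index disease plus eight comparators) and a 30% background
#' tractability rate.
#'
#' @param n_genes number of genes (>= 10)
#' @param network_model "preferential_attachment" or "configuration"
#' @param mean_degree target mean degree (> 0)
#' @param module_size planted-module size (<= n_genes)
#' @param evidence_effect mean evidence uplift for planted genes (>= 0)
#' @param noise_sd sd of the half-normal evidence noise (>= 0)
#' @param n_sets number of gene sets
#' @param set_size_range integer pair, inclusive size range for gene sets
#' @param n_enriched_sets how many sets oversample planted genes
#' @param n_diseases number of disease profiles (index disease first)
#' @param shared_signal_fraction fraction of planted genes elevated in all
#'   diseases (the rest are elevated in the index disease only)
#' @param tractable_rate background probability that a gene is tractable
#' @param seed integer run seed (all sub-generators derive from it)
#' @return a validated `synthetic_config` list
#' @export
synthetic_config <- function(n_genes = 500L,
                             network_model = c("preferential_attachment", "configuration"),
                             mean_degree = 4,
                             module_size = 20L,
                             evidence_effect = 3,
                             noise_sd = 1,
                             n_sets = 50L,
                             set_size_range = c(10L, 50L),
                             n_enriched_sets = 5L,
                             n_diseases = 9L,
                             shared_signal_fraction = 0.5,
                             tractable_rate = 0.3,
                             seed = 42L) {
  network_model <- match.arg(network_model)
  stopifnot_scalar_number(n_genes, "n_genes", lower = 10)
  stopifnot_scalar_number(mean_degree, "mean_degree", lower = 1e-9)
  stopifnot_scalar_number(module_size, "module_size", lower = 1, upper = n_genes)
  stopifnot_scalar_number(evidence_effect, "evidence_effect", lower = 0)
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 0)
  stopifnot_scalar_number(n_sets, "n_sets", lower = 1)
  stopifnot_scalar_number(n_enriched_sets, "n_enriched_sets", lower = 0, upper = n_sets)
  stopifnot_scalar_number(n_diseases, "n_diseases", lower = 1)
  stopifnot_scalar_number(shared_signal_fraction, "shared_signal_fraction", 0, 1)
  stopifnot_scalar_number(tractable_rate, "tractable_rate", 0, 1)
  if (length(set_size_range) != 2L || set_size_range[1] > set_size_range[2] ||
      set_size_range[1] < 1) {
    stop("`set_size_range` must be an increasing positive integer pair", call. = FALSE)
  }
  cfg <- list(
    n_genes = as.integer(n_genes), network_model = network_model,
    mean_degree = mean_degree, module_size = as.integer(module_size),
    evidence_effect = evidence_effect, noise_sd = noise_sd,
    n_sets = as.integer(n_sets), set_size_range = as.integer(set_size_range),
    n_enriched_sets = as.integer(n_enriched_sets),
    n_diseases = as.integer(n_diseases),
    shared_signal_fraction = shared_signal_fraction,
    tractable_rate = tractable_rate, seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  cfg
}

gene_names <- function(n) sprintf(paste0("G%0", nchar(n), "d"), seq_len(n))

# Fixed sub-seed offsets, one per generator component.
.seed_offsets <- c(network = 101L, module = 211L, evidence = 307L,
                   genesets = 401L, drugs = 503L, diseases = 601L,
                   tractability = 701L)

#' Generate a connected, simple, evidence-tagged gene network
#'
#' Preferential attachment gives a scale-free degree distribution; the
#' configuration model gives a matched-mean-degree graph with a lighter tail.
#' After simplification, any disconnected parts are reconnected by bridging
#' edges to the largest component, so the returned graph always has a single
#' component. Each edge carries an `evidence` tag drawn from
#' "experiments"/"databases".
#'
#' @param config a [synthetic_config()]
#' @return undirected simple connected igraph with vertex names
#' @export
generate_network <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, config)
  }
  set.seed(sub_seed(config$seed, .seed_offsets[["network"]]))
  n <- config$n_genes
  if (config$network_model == "preferential_attachment") {
    m <- max(1L, round_half_up(config$mean_degree / 2))
    g <- igraph::sample_pa(n, m = m, directed = FALSE)
  } else if (config$network_model == "configuration") {
    deg <- stats::rpois(n, lambda = config$mean_degree)
    deg <- pmax(deg, 1L)
    deg <- pmin(deg, n - 1L)
    if (sum(deg) %% 2L == 1L) deg[which.min(deg)] <- deg[which.min(deg)] + 1L
    g <- igraph::sample_degseq(deg, method = "configuration.simple")
  } else {
    stop("unknown network model: ", config$network_model, call. = FALSE)
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  igraph::V(g)$name <- gene_names(n)

  comps <- igraph::components(g)
  if (comps$no > 1L) {
    main <- which.max(comps$csize)
    main_nodes <- which(comps$membership == main)
    bridges <- NULL
    for (cid in setdiff(seq_len(comps$no), main)) {
      from <- sample(which(comps$membership == cid), 1L)
      to <- sample(main_nodes, 1L)
      bridges <- c(bridges, from, to)
    }
    g <- igraph::add_edges(g, bridges)
  }
  igraph::E(g)$evidence <- sample(c("experiments", "databases"),
                                  igraph::ecount(g), replace = TRUE)
  g
}

#' Plant a connected module by breadth-first frontier sampling
#'
#' Starting from a uniformly random seed node, repeatedly adds a uniformly
#' random member of the current frontier (neighbours of the module not yet in
#' it).  Connectivity of the induced subgraph is guaranteed by construction —
#' no rejection sampling.
#'
#' @param network igraph with vertex names
#' @param module_size number of genes to plant (<= node count)
#' @return character vector of module gene symbols (sorted)
#' @export
plant_module <- function(network, module_size) {
  n <- igraph::vcount(network)
  if (module_size > n) stop("module_size exceeds node count", call. = FALSE)
  nodes <- igraph::V(network)$name
  adj <- igraph::as_adj_list(network, mode = "all")
  start <- sample.int(n, 1L)
  in_mod <- logical(n)
  in_mod[start] <- TRUE
  frontier <- setdiff(as.integer(adj[[start]]), start)
  while (sum(in_mod) < module_size) {
    if (length(frontier) == 0L) break  # component exhausted (connected nets: only if module = all)
    pick <- frontier[sample.int(length(frontier), 1L)]
    in_mod[pick] <- TRUE
    frontier <- setdiff(union(frontier, as.integer(adj[[pick]])), which(in_mod))
  }
  sort(nodes[in_mod])
}

#' Generate per-gene evidence layers with a planted uplift
#'
#' Background scores in each of the three layers (nGene/eGene/cGene-like) are
#' half-normal, `|N(0, noise_sd)|` — non-negative without a truncation mass
#' point at zero. Each planted gene receives an additive uplift of
#' `evidence_effect` in a random non-empty subset of layers.
#'
#' @param network igraph with vertex names
#' @param truth planted truth (list with `module_genes`) or a character vector
#' @param config [synthetic_config()]
#' @return data frame: gene, nGene, eGene, cGene
#' @export
generate_evidence <- function(network, truth, config) {
  set.seed(sub_seed(config$seed, .seed_offsets[["evidence"]]))
  genes <- igraph::V(network)$name
  planted <- if (is.list(truth)) truth$module_genes else truth
  if (!all(planted %in% genes)) stop("planted genes missing from network", call. = FALSE)
  n <- length(genes)
  layers <- c("nGene", "eGene", "cGene")
  ev <- matrix(abs(stats::rnorm(n * 3L, 0, config$noise_sd)), nrow = n,
               dimnames = list(genes, layers))
  for (g in planted) {
    sel <- which(stats::runif(3) < 0.5)
    if (length(sel) == 0L) sel <- sample.int(3L, 1L)
    ev[g, sel] <- ev[g, sel] + config$evidence_effect
  }
  data.frame(gene = genes, ev, row.names = NULL, stringsAsFactors = FALSE)
}

#' Generate a gene-set collection with planted-enriched sets
#'
#' `n_enriched_sets` of the sets draw roughly half their members from the
#' planted module (capped by module size), the rest uniformly from the
#' background; remaining sets are uniform draws.
#'
#' @param genes universe of gene symbols
#' @param truth planted truth list (uses `module_genes`)
#' @param config [synthetic_config()]
#' @return `gene_set_collection` (named list); enriched ids in
#'   `attr(, "enriched_set_ids")`
#' @export
generate_genesets <- function(genes, truth, config) {
  set.seed(sub_seed(config$seed, .seed_offsets[["genesets"]]))
  planted <- truth$module_genes
  ids <- sprintf("S%03d", seq_len(config$n_sets))
  enriched <- if (config$n_enriched_sets > 0L) ids[seq_len(config$n_enriched_sets)] else character(0)
  lo <- config$set_size_range[1]; hi <- config$set_size_range[2]
  sets <- vector("list", config$n_sets)
  names(sets) <- ids
  for (i in seq_len(config$n_sets)) {
    size <- sample(seq(lo, hi), 1L)
    if (ids[i] %in% enriched && length(planted) > 0L) {
      k_pl <- min(length(planted), max(1L, size %/% 2L))
      mem <- c(sample(planted, k_pl),
               sample(setdiff(genes, planted), size - k_pl))
    } else {
      mem <- sample(genes, min(size, length(genes)))
    }
    sets[[i]] <- sort(unique(mem))
  }
  attr(sets, "description") <- stats::setNames(
    ifelse(ids %in% enriched, "planted-enriched synthetic set", "background synthetic set"), ids)
  attr(sets, "enriched_set_ids") <- enriched
  class(sets) <- "gene_set_collection"
  sets
}

#' Generate a phase-annotated drug-target table
#'
#' True targets are drawn from the planted module (about half of it) plus a
#' matched number of background genes; each target receives 1-3 drugs with
#' development phases in 1-4 and at least one drug at the gene's maximum
#' phase.  Mimics a ChEMBL-style extract (gene, drug, phase, indication,
#' mechanism of action).
#'
#' @param genes universe of gene symbols
#' @param truth planted truth list
#' @param config [synthetic_config()]
#' @return data frame: gene, drug, phase, indication, moa; true planted
#'   targets in `attr(, "true_drug_targets")`
#' @export
generate_drug_table <- function(genes, truth, config) {
  set.seed(sub_seed(config$seed, .seed_offsets[["drugs"]]))
  planted <- truth$module_genes
  n_true <- max(1L, length(planted) %/% 2L)
  true_targets <- sort(sample(planted, n_true))
  bg_pool <- setdiff(genes, planted)
  bg_targets <- sort(sample(bg_pool, min(n_true, length(bg_pool))))
  targets <- c(true_targets, bg_targets)
  rows <- lapply(seq_along(targets), function(i) {
    gene <- targets[i]
    n_drugs <- sample.int(3L, 1L)
    phases <- sample.int(4L, n_drugs, replace = TRUE)
    data.frame(gene = gene,
               drug = sprintf("drug_%s_%d", gene, seq_len(n_drugs)),
               phase = phases,
               indication = sample(c("nephrolithiasis", "inflammation", "oncology"),
                                   n_drugs, replace = TRUE),
               moa = sample(c("inhibitor", "antagonist", "antibody"),
                            n_drugs, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "true_drug_targets") <- true_targets
  out
}

#' Generate gene x disease priority-rating profiles
#'
#' Values live on the 0-5 priority-rating scale used downstream.  Background
#' ratings are uniform on \[0, 5\]; a `shared_signal_fraction` of the planted
#' genes is elevated (uniform on \[3.5, 5\]) in every disease, the remaining
#' planted genes only in the first (index) disease.
#'
#' @param genes gene symbols (rows)
#' @param truth planted truth list
#' @param config [synthetic_config()]
#' @return numeric matrix genes x diseases, colnames "D1".."Dk"
#' @export
generate_disease_profiles <- function(genes, truth, config) {
  set.seed(sub_seed(config$seed, .seed_offsets[["diseases"]]))
  n <- length(genes); d <- config$n_diseases
  m <- matrix(stats::runif(n * d, 0, 5), nrow = n,
              dimnames = list(genes, paste0("D", seq_len(d))))
  planted <- intersect(truth$module_genes, genes)
  n_shared <- round_half_up(config$shared_signal_fraction * length(planted))
  shared <- if (n_shared > 0L) sample(planted, n_shared) else character(0)
  specific <- setdiff(planted, shared)
  if (length(shared) > 0L) {
    m[shared, ] <- stats::runif(length(shared) * d, 3.5, 5)
  }
  if (length(specific) > 0L) {
    m[specific, 1L] <- stats::runif(length(specific), 3.5, 5)
  }
  m
}

#' Generate binary tractability labels
#'
#' Bernoulli(`rate`) per gene; tractable genes get a positive predicted
#' druggable-pocket count (1 + Poisson(1)) and a synthetic structure id.
#'
#' @param genes gene symbols
#' @param rate tractable probability in \[0, 1\]
#' @param seed optional integer seed (defaults to the current RNG stream)
#' @return data frame: gene, tractable (0/1), n_pockets, structures
#' @export
generate_tractability <- function(genes, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(sub_seed(seed, .seed_offsets[["tractability"]]))
  tr <- stats::rbinom(length(genes), 1L, rate)
  np <- ifelse(tr == 1L, 1L + stats::rpois(length(genes), 1), 0L)
  data.frame(gene = genes, tractable = tr, n_pockets = np,
             structures = ifelse(tr == 1L, paste0("SYN-", genes), ""),
             stringsAsFactors = FALSE)
}

#' Run the whole generator
#'
#' Produces every pipeline input plus the planted truth. Identical config
#' (including seed) gives byte-identical outputs.
#'
#' @param config a [synthetic_config()]
#' @return list: network, truth (module_genes, enriched_set_ids,
#'   true_drug_targets), evidence, genesets, drugs, disease_profiles,
#'   tractability, config
#' @export
simulate_all <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) config <- do.call(synthetic_config, config)
  network <- generate_network(config)
  set.seed(sub_seed(config$seed, .seed_offsets[["module"]]))
  module_genes <- plant_module(network, config$module_size)
  truth <- list(module_genes = module_genes)
  evidence <- generate_evidence(network, truth, config)
  genes <- igraph::V(network)$name
  genesets <- generate_genesets(genes, truth, config)
  drugs <- generate_drug_table(genes, truth, config)
  profiles <- generate_disease_profiles(genes, truth, config)
  tract <- generate_tractability(genes, config$tractable_rate, seed = config$seed)
  truth$enriched_set_ids <- attr(genesets, "enriched_set_ids")
  truth$true_drug_targets <- attr(drugs, "true_drug_targets")
  list(network = network, truth = truth, evidence = evidence,
       genesets = genesets, drugs = drugs, disease_profiles = profiles,
       tractability = tract, config = config)
}

#' Write all simulated inputs to a directory
#'
#' Emits edge list, evidence, GMT, drug, disease-matrix and tractability
#' tables plus `truth.json`.
#'
#' @param sim result of [simulate_all()]
#' @param outdir output directory (created if missing)
#' @return `outdir`, invisibly
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_edge_list(sim$network, file.path(outdir, "network.tsv"))
  ev <- sim$evidence[order(sim$evidence$gene), , drop = FALSE]
  write_tsv(ev, file.path(outdir, "evidence.tsv"))
  write_gmt(sim$genesets, file.path(outdir, "genesets.gmt"))
  write_tsv(sim$drugs, file.path(outdir, "drugs.tsv"))
  write_disease_matrix(sim$disease_profiles, file.path(outdir, "disease_profiles.tsv"))
  write_tsv(sim$tractability[order(sim$tractability$gene), , drop = FALSE],
            file.path(outdir, "tractability.tsv"))
  jsonlite::write_json(sim$truth, file.path(outdir, "truth.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(outdir)
}
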