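# End-to-end pipeline driver: simulate (or read) inputs, prioritize, enrich,
# extract crosstalk, repurpose, run removal analysis, and compare across
# diseases on the supra-hexagonal map.  Reruns with the same config are
# bit-identical.

.pipeline_schema <- list(
  seed = "integer",
  synthetic = "list",
  inputs = "list",
  rwr = "list",
  enrichment = "list",
  crosstalk = "list",
  robustness = "list",
  repurpose = "list",
  crossdisease = "list"
)

.input_keys <- c("network", "evidence", "genesets", "drugs",
                 "disease_profiles", "tractability")

#' Assemble and validate a pipeline configuration
#'
#' Either pass a nested list (or a YAML file path) or rely on the defaults.
#' Unknown keys are rejected. Sub-sections mirror the stage parameter sets:
#' `synthetic` ([synthetic_config()] arguments), `inputs` (paths to
#' pre-existing input files; when present the generator is skipped), `rwr`
#' (restart, tol, max_iter), `enrichment` (query_fraction, tsea_n_perm,
#' weight_exponent), `crosstalk` (theta_quantile, n_perm, degree_bin_width,
#' exact_limit), `robustness` (k_min, k_max, convention), `repurpose`
#' (indication), `crossdisease` (radius, k_clusters, epochs).
#'
#' @param config list or YAML path; NULL = all defaults
#' @param seed optional override of the global seed
#' @return validated `pipeline_config` list with all defaults filled in
#' @export
pipeline_config <- function(config = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  config <- config %||% list()
  unknown <- setdiff(names(config), names(.pipeline_schema))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(config$inputs)) {
    bad <- setdiff(names(config$inputs), .input_keys)
    if (length(bad) > 0L) stop("unknown input key(s): ", paste(bad, collapse = ", "),
                               call. = FALSE)
  }
  defaults <- list(
    seed = 42L,
    synthetic = list(),
    inputs = NULL,
    rwr = list(restart = 0.75, tol = 1e-10, max_iter = 10000L),
    enrichment = list(query_fraction = 0.02, tsea_n_perm = 1000L,
                      weight_exponent = 1),
    crosstalk = list(theta_quantile = 0.98, n_perm = 100L,
                     degree_bin_width = 1L, exact_limit = 15L),
    robustness = list(k_min = 1L, k_max = 4L, convention = "exclude_removed"),
    repurpose = list(indication = NULL),
    crossdisease = list(radius = 3L, k_clusters = 4L, epochs = 40L)
  )
  for (k in names(defaults)) {
    if (is.null(config[[k]])) {
      config[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]]) && k != "inputs") {
      bad <- setdiff(names(config[[k]]), names(defaults[[k]]))
      if (k == "synthetic") bad <- setdiff(names(config[[k]]),
                                           names(formals(synthetic_config)))
      if (length(bad) > 0L) {
        stop("unknown key(s) in config$", k, ": ", paste(bad, collapse = ", "),
             call. = FALSE)
      }
      for (kk in names(defaults[[k]])) {
        if (is.null(config[[k]][[kk]]) && !is.null(defaults[[k]][[kk]])) {
          config[[k]][[kk]] <- defaults[[k]][[kk]]
        }
      }
    }
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  class(config) <- "pipeline_config"
  config
}

read_pipeline_inputs <- function(paths) {
  missing <- setdiff(.input_keys, names(paths))
  if (length(missing) > 0L) {
    stop("inputs config must name all of: ", paste(.input_keys, collapse = ", "),
         call. = FALSE)
  }
  for (k in .input_keys) {
    if (!file.exists(paths[[k]])) stop("input file missing: ", paths[[k]], call. = FALSE)
  }
  list(network = read_edge_list(paths$network),
       evidence = read_evidence(paths$evidence),
       genesets = read_gmt(paths$genesets),
       drugs = read_tsv(paths$drugs),
       disease_profiles = read_disease_matrix(paths$disease_profiles),
       tractability = read_tsv(paths$tractability),
       truth = NULL)
}

run_stage <- function(name, log, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  log$lines <- c(log$lines, sprintf("stage %-12s ok  %.2fs", name, elapsed))
  out
}

#' Run the full pipeline
#'
#' Stage order: simulate/read inputs, prioritize, gene-set enrichment (Fisher
#' on the top-rated query plus rank-based TSEA), crosstalk extraction with
#' permutation significance and the pathway-centric MST graph, drug
#' repurposing, removal/robustness analysis, and the supra-hexagonal
#' cross-disease comparison. All stage outputs are written under `outdir`
#' along with `summary.json` and a log of stage timings and seeds.
#'
#' @param config a [pipeline_config()], nested list, or YAML path
#' @param outdir output directory
#' @return (invisibly) the summary list; all artefacts are on disk
#' @export
run_pipeline <- function(config = NULL, outdir = tempfile("netprior_run_")) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- new.env()
  log$lines <- c(sprintf("netprior pipeline; global seed %d", cfg$seed))

  dat <- run_stage("simulate", log, {
    if (!is.null(cfg$inputs)) {
      read_pipeline_inputs(cfg$inputs)
    } else {
      syn <- cfg$synthetic
      syn$seed <- syn$seed %||% cfg$seed
      sim <- simulate_all(do.call(synthetic_config, syn))
      write_simulation(sim, file.path(outdir, "inputs"))
      sim
    }
  })
  genes <- igraph::V(dat$network)$name

  priority <- run_stage("prioritize", log, {
    params <- rwr_params(restart = cfg$rwr$restart, tol = cfg$rwr$tol,
                         max_iter = cfg$rwr$max_iter)
    prioritize(dat$network, dat$evidence, params)
  })
  write_tsv(priority, file.path(outdir, "priority.tsv"))

  enrich <- run_stage("enrich", log, {
    query <- top_fraction(priority, cfg$enrichment$query_fraction)
    fisher <- fisher_enrichment(query, dat$genesets, genes)
    set.seed(sub_seed(cfg$seed, 811L))
    ts <- tsea(priority, dat$genesets, n_perm = cfg$enrichment$tsea_n_perm,
               weight_exponent = cfg$enrichment$weight_exponent)
    list(query = query, fisher = fisher, tsea = ts)
  })
  write_tsv(enrich$fisher, file.path(outdir, "enrichment_fisher.tsv"))
  write_tsv(enrich$tsea, file.path(outdir, "tsea.tsv"))

  ct <- run_stage("crosstalk", log, {
    theta <- theta_from_quantile(priority, cfg$crosstalk$theta_quantile)
    scores <- score_nodes(priority, theta)
    params <- crosstalk_params(n_perm = cfg$crosstalk$n_perm,
                               degree_bin_width = cfg$crosstalk$degree_bin_width,
                               exact_limit = cfg$crosstalk$exact_limit,
                               seed = sub_seed(cfg$seed, 907L))
    module <- find_crosstalk(dat$network, scores, params)
    sig <- permutation_significance(dat$network, scores, module$total_score, params)
    module$p_perm <- sig$p_perm
    module$p_extrapolated <- sig$p_extrapolated
    module$perm_scores <- sig$perm_scores
    pg <- pathway_graph(module$genes, dat$genesets, genes)
    list(theta = theta, module = module, pathway_graph = pg)
  })
  pr_idx <- match(ct$module$genes, priority$gene)
  nodes_df <- data.frame(gene = ct$module$genes,
                         rating = priority$rating[pr_idx],
                         rank = priority$rank[pr_idx], stringsAsFactors = FALSE)
  nodes_df$label <- sprintf("%.2f@%d", nodes_df$rating, nodes_df$rank)
  write_tsv(nodes_df, file.path(outdir, "crosstalk_nodes.tsv"))
  write_edge_list(ct$module$subgraph, file.path(outdir, "crosstalk_edges.tsv"))
  write_tsv(ct$pathway_graph$edges, file.path(outdir, "pathway_graph.tsv"))

  rp <- run_stage("repurpose", log, {
    cats <- max_phase_targets(dat$drugs, genes = genes,
                              indication = cfg$repurpose$indication)
    enr <- category_enrichment(ct$module$genes, cats, genes)
    list(categories = cats, enrichment = enr)
  })
  write_tsv(rp$categories, file.path(outdir, "target_categories.tsv"))
  write_tsv(rp$enrichment, file.path(outdir, "category_enrichment.tsv"))

  rb <- run_stage("robustness", log, {
    module_net <- ct$module$subgraph
    targets <- rp$categories$gene[rp$categories$category != "none"]
    candidates <- intersect(ct$module$genes, targets)
    if (length(candidates) < 2L) candidates <- ct$module$genes
    k_max <- min(cfg$robustness$k_max, length(candidates),
                 igraph::vcount(module_net) - 1L)
    combos <- optimal_combination(module_net, candidates,
                                  k_min = min(cfg$robustness$k_min, k_max),
                                  k_max = k_max,
                                  convention = cfg$robustness$convention)
    pr_scores <- stats::setNames(priority$rating, priority$gene)[ct$module$genes]
    attack <- list(
      degree = targeted_attack(module_net, "degree",
                               convention = cfg$robustness$convention),
      priority = targeted_attack(module_net, "priority", score_vector = pr_scores,
                                 convention = cfg$robustness$convention))
    list(combos = combos, attack = attack)
  })
  write_tsv(rb$combos, file.path(outdir, "removal_optimal.tsv"))
  ac <- rbind(cbind(ordering = "degree", rb$attack$degree),
              cbind(ordering = "priority", rb$attack$priority))
  write_tsv(ac, file.path(outdir, "attack_curve.tsv"))

  cd <- run_stage("crossmap", log, {
    prof <- dat$disease_profiles
    keep <- intersect(ct$module$genes, rownames(prof))
    if (length(keep) < 5L) keep <- rownames(prof)
    prof <- prof[keep, , drop = FALSE]
    map <- build_map(cfg$crossdisease$radius)
    params <- som_params(epochs = cfg$crossdisease$epochs,
                         k_clusters = cfg$crossdisease$k_clusters,
                         seed = sub_seed(cfg$seed, 1013L))
    map <- suppressWarnings(train_som(map, prof, params))
    clusters <- cluster_map(map, cfg$crossdisease$k_clusters)
    overlay <- suppressWarnings(overlay_binary(map, dat$tractability, clusters))
    cors <- disease_correlations(prof)
    tr_enr <- tractability_enrichment(ct$module$genes, dat$tractability, genes)
    list(map = map, clusters = clusters, overlay = overlay, correlations = cors,
         tract_enrichment = tr_enr)
  })
  map_json <- list(
    radius = cd$map$radius,
    hexes = cd$map$hexes,
    codebook = as.data.frame(cd$map$codebook),
    bmu = as.list(cd$map$bmu),
    clusters = cd$clusters,
    qe = cd$map$qe)
  jsonlite::write_json(map_json, file.path(outdir, "map.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_tsv(cd$overlay$hexagons, file.path(outdir, "overlay_hexagons.tsv"))
  if (!is.null(cd$overlay$clusters)) {
    write_tsv(cd$overlay$clusters, file.path(outdir, "overlay_clusters.tsv"))
  }
  cor_df <- data.frame(disease = colnames(cd$correlations$r),
                       cd$correlations$r, check.names = FALSE)
  write_tsv(cor_df, file.path(outdir, "correlations.tsv"))

  summary <- list(
    seed = cfg$seed,
    n_genes = length(genes),
    n_edges = igraph::ecount(dat$network),
    top_query_size = length(enrich$query),
    n_enriched_fisher_fdr05 = sum(enrich$fisher$FDR < 0.05),
    crosstalk = list(n_genes = length(ct$module$genes),
                     total_score = ct$module$total_score,
                     theta = ct$theta,
                     p_perm = ct$module$p_perm,
                     p_extrapolated = ct$module$p_extrapolated),
    repurpose = list(n_approved = sum(rp$categories$category == "approved"),
                     n_phased = sum(rp$categories$category == "phased")),
    optimal_combinations = rb$combos,
    cluster_sizes = as.list(table(cd$clusters)),
    tractability_p = cd$tract_enrichment$p[1]
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log$lines, file.path(outdir, "log.txt"))
  invisible(summary)
}
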