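# Pathway-crosstalk discovery: a connected subnetwork of highly rated genes
# extracted from a (pathway-merged) interaction graph, its significance under
# a degree-preserving node-score permutation null, and the MST-filtered
# pathway-centric summary graph.

#' Crosstalk search parameters
#'
#' @param n_perm permutations for the significance test (default 100, >= 10)
#' @param degree_bin_width width of the degree bins used by the
#'   degree-preserving permutation (default 1 = exact-degree bins)
#' @param exact_limit node-count cutoff below which [find_crosstalk()] solves
#'   the maximum-score connected-subgraph problem exactly by enumeration;
#'   larger graphs use the greedy path-merging heuristic
#' @param seed optional RNG seed for the permutation stream
#' @return `crosstalk_params` list
#' @export
crosstalk_params <- function(n_perm = 100L, degree_bin_width = 1L,
                             exact_limit = 15L, seed = NULL) {
  stopifnot_scalar_number(n_perm, "n_perm", lower = 10)
  stopifnot_scalar_number(degree_bin_width, "degree_bin_width", lower = 1)
  stopifnot_scalar_number(exact_limit, "exact_limit", lower = 0, upper = 25)
  structure(list(n_perm = as.integer(n_perm),
                 degree_bin_width = as.integer(degree_bin_width),
                 exact_limit = as.integer(exact_limit), seed = seed),
            class = "crosstalk_params")
}

#' Node scores from priority ratings
#'
#' `score(g) = rating(g) - theta`: positive above the threshold, negative
#' below. The additive form lets a subnetwork's total score trade off strong
#' members against weak connectors.
#'
#' @param priority a `priority_table`
#' @param theta threshold on the 0-5 rating scale
#' @return named numeric vector over the priority table's genes
#' @export
score_nodes <- function(priority, theta) {
  stopifnot_scalar_number(theta, "theta", lower = 0, upper = 5)
  stats::setNames(priority$rating - theta, priority$gene)
}

#' Rating threshold at a quantile
#'
#' Convenience for the default crosstalk threshold: the rating at the
#' `q` quantile (default 0.98, i.e. the top-2% cut).
#'
#' @param priority a `priority_table`
#' @param q quantile in (0, 1)
#' @return scalar rating threshold
#' @export
theta_from_quantile <- function(priority, q = 0.98) {
  as.numeric(stats::quantile(priority$rating, q, type = 1))
}

# Exact maximum-score connected subgraph by bitmask enumeration.
# Feasible for n <= ~20; used for n <= exact_limit.
max_score_connected_exact <- function(network, scores) {
  nodes <- igraph::V(network)$name
  n <- length(nodes)
  s <- as.numeric(scores[nodes])
  adj_mask <- integer(n)
  el <- igraph::as_edgelist(network, names = FALSE)
  for (i in seq_len(nrow(el))) {
    u <- el[i, 1]; v <- el[i, 2]
    adj_mask[u] <- bitwOr(adj_mask[u], bitwShiftL(1L, v - 1L))
    adj_mask[v] <- bitwOr(adj_mask[v], bitwShiftL(1L, u - 1L))
  }
  bit_of <- bitwShiftL(1L, seq_len(n) - 1L)
  best_score <- -Inf
  best_mask <- 0L
  for (mask in seq_len(bitwShiftL(1L, n) - 1L)) {
    members <- which(bitwAnd(mask, bit_of) != 0L)
    # connectivity: BFS over the masked adjacency
    reached <- bit_of[members[1L]]
    repeat {
      nxt <- reached
      for (m in members) {
        if (bitwAnd(reached, bit_of[m]) != 0L) {
          nxt <- bitwOr(nxt, bitwAnd(adj_mask[m], mask))
        }
      }
      if (nxt == reached) break
      reached <- nxt
    }
    if (reached != mask) next
    sc <- sum(s[members])
    if (sc > best_score + 1e-12) {
      best_score <- sc
      best_mask <- mask
    }
  }
  nodes[which(bitwAnd(best_mask, bit_of) != 0L)]
}

# Greedy Steiner-style heuristic: contract positive-score components, then
# merge them in decreasing-score order through minimum-penalty paths
# (edge penalty = sum of endpoint negative-score magnitudes), keeping a merge
# only when the component's score outweighs the connector penalty; finally
# prune negative-score leaves.
max_score_connected_heuristic <- function(network, scores) {
  nodes <- igraph::V(network)$name
  s <- scores[nodes]
  pos <- nodes[s > 0]
  sub_pos <- igraph::induced_subgraph(network, pos)
  cmp <- igraph::components(sub_pos)
  comp_list <- split(igraph::V(sub_pos)$name, cmp$membership)
  comp_score <- vapply(comp_list, function(g) sum(s[g]), 0)
  ord <- order(-comp_score, vapply(comp_list, min, ""))
  comp_list <- comp_list[ord]
  comp_score <- comp_score[ord]

  pen <- pmax(-s, 0)  # -s first: pmax takes names from its first argument
  el <- igraph::as_edgelist(network, names = TRUE)
  ew <- pen[el[, 1]] + pen[el[, 2]] + 1e-9  # epsilon: prefer fewer hops

  tree <- comp_list[[1L]]
  if (length(comp_list) > 1L) {
    for (ci in seq(2L, length(comp_list))) {
      cn <- comp_list[[ci]]
      d <- igraph::distances(network, v = cn, to = tree, weights = ew)
      hit <- which(d == min(d), arr.ind = TRUE)[1L, , drop = TRUE]
      sp <- igraph::shortest_paths(network, from = cn[hit[1L]],
                                   to = tree[hit[2L]], weights = ew)$vpath[[1L]]
      path_nodes <- nodes[as.integer(sp)]
      new_nodes <- setdiff(union(cn, path_nodes), tree)
      if (sum(s[new_nodes]) > 0) tree <- union(tree, new_nodes)
    }
  }
  # prune negative leaves until stable
  repeat {
    sub <- igraph::induced_subgraph(network, tree)
    deg <- igraph::degree(sub)
    drop <- igraph::V(sub)$name[deg <= 1 & s[igraph::V(sub)$name] < 0]
    if (length(drop) == 0L || length(tree) - length(drop) < 1L) break
    tree <- setdiff(tree, drop)
  }
  tree
}

#' Find the maximum-score connected crosstalk subnetwork
#'
#' Searches for a connected subgraph maximizing the sum of node scores
#' (ratings minus threshold). Instances with at most `exact_limit` nodes are
#' solved exactly by enumeration over connected vertex subsets; larger graphs
#' use a greedy Steiner-style heuristic (positive components merged through
#' minimum-penalty connector paths, negative leaves pruned). The returned
#' total score is always at least the best single node's score.
#'
#' @param network igraph with vertex names
#' @param node_scores named numeric vector covering all vertices
#' @param params [crosstalk_params()]
#' @return `crosstalk_module` list: genes (sorted), subgraph (igraph),
#'   node_scores, total_score
#' @export
find_crosstalk <- function(network, node_scores, params = crosstalk_params()) {
  nodes <- igraph::V(network)$name
  if (!all(nodes %in% names(node_scores))) {
    stop("node_scores must cover all network vertices", call. = FALSE)
  }
  s <- node_scores[nodes]
  if (!any(s > 0)) stop("no signal above threshold", call. = FALSE)
  genes <- if (length(nodes) <= params$exact_limit) {
    max_score_connected_exact(network, s)
  } else {
    max_score_connected_heuristic(network, s)
  }
  genes <- sort(genes)
  sub <- igraph::induced_subgraph(network, genes)
  structure(list(genes = genes, subgraph = sub,
                 node_scores = s[genes], total_score = sum(s[genes])),
            class = "crosstalk_module")
}

#' Print a crosstalk module summary
#' @param x a `crosstalk_module`
#' @param ... unused
#' @method print crosstalk_module
#' @export
print.crosstalk_module <- function(x, ...) {
  cat(sprintf("crosstalk module: %d genes, %d edges, total score %.3f\n",
              length(x$genes), igraph::ecount(x$subgraph), x$total_score))
  if (!is.null(x$p_perm)) {
    cat(sprintf("  permutation p = %.4g (extrapolated %.4g, %d perms)\n",
                x$p_perm, x$p_extrapolated, length(x$perm_scores)))
  }
  invisible(x)
}

# Shuffle scores within degree bins; preserves the per-bin score multiset.
permute_scores_degree_preserving <- function(scores, degree, bin_width = 1L) {
  bins <- if (bin_width <= 1L) degree else ceiling(degree / bin_width)
  out <- scores
  for (b in unique(bins)) {
    idx <- which(bins == b)
    if (length(idx) > 1L) out[idx] <- scores[idx][sample.int(length(idx))]
  }
  out
}

#' Degree-preserving permutation significance of a crosstalk module
#'
#' Node scores are shuffled only among nodes of (approximately) equal degree
#' — preserving the score-degree relationship — and the crosstalk search is
#' re-run on each permuted score vector. The empirical p-value uses the +1
#' pseudocount, so its floor is `1/(1 + n_perm)`; a normal fit to the
#' permutation distribution provides the clearly-labelled extrapolated
#' p-value (the route by which p-values far below the empirical floor, e.g.
#' 3.2e-99 from 100 permutations, are reported).
#'
#' Singleton degree bins keep their score fixed (documented no-op, not an
#' error).
#'
#' @param network igraph with vertex names
#' @param node_scores named score vector (the observed one)
#' @param observed_total total score of the observed module from
#'   [find_crosstalk()] on the same inputs
#' @param params [crosstalk_params()]
#' @return list: p_perm (empirical), p_extrapolated (normal fit),
#'   perm_scores (numeric vector of permuted totals)
#' @export
permutation_significance <- function(network, node_scores, observed_total,
                                     params = crosstalk_params()) {
  if (!is.null(params$seed)) set.seed(params$seed)
  nodes <- igraph::V(network)$name
  s <- node_scores[nodes]
  deg <- igraph::degree(network)
  perm_scores <- vapply(seq_len(params$n_perm), function(i) {
    ps <- permute_scores_degree_preserving(s, deg, params$degree_bin_width)
    if (!any(ps > 0)) return(max(ps))
    find_crosstalk(network, ps, params)$total_score
  }, 0)
  p_emp <- (1 + sum(perm_scores >= observed_total - 1e-12)) / (1 + params$n_perm)
  mu <- mean(perm_scores); sdv <- stats::sd(perm_scores)
  p_ext <- if (is.finite(sdv) && sdv > 0) {
    stats::pnorm(observed_total, mean = mu, sd = sdv, lower.tail = FALSE)
  } else {
    1
  }
  list(p_perm = p_emp, p_extrapolated = p_ext, perm_scores = perm_scores)
}

#' MST-filtered pathway-centric crosstalk graph
#'
#' Pathways significantly over-represented in the crosstalk genes (one-sided
#' Fisher, BH FDR < `fdr_cutoff`) become nodes; candidate edges join pathway
#' pairs sharing at least one member gene, weighted by the shared count; the
#' minimum spanning tree on distance `1/shared_count` is computed per
#' connected component and only tree edges are flagged for display. Ties are
#' broken by lexicographic pathway-id order.
#'
#' @param crosstalk_genes character vector of module genes
#' @param pathway_sets `gene_set_collection`
#' @param universe background gene universe
#' @param fdr_cutoff significance cutoff for pathway nodes (default 0.05)
#' @return list: `nodes` (enrichment rows of significant pathways),
#'   `edges` (p1, p2, shared_count, mst_flag, shared_genes)
#' @export
pathway_graph <- function(crosstalk_genes, pathway_sets, universe,
                          fdr_cutoff = 0.05) {
  enr <- fisher_enrichment(intersect(crosstalk_genes, universe), pathway_sets, universe)
  nodes_df <- enr[enr$FDR < fdr_cutoff, , drop = FALSE]
  empty_edges <- data.frame(p1 = character(0), p2 = character(0),
                            shared_count = integer(0), mst_flag = logical(0),
                            shared_genes = character(0), stringsAsFactors = FALSE)
  if (nrow(nodes_df) < 2L) {
    warning("fewer than 2 significant pathways; pathway graph has no edges",
            call. = FALSE)
    return(list(nodes = nodes_df, edges = empty_edges))
  }
  ids <- sort(nodes_df$set_id)
  pairs <- utils::combn(ids, 2)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    shared <- sort(intersect(intersect(pathway_sets[[a]], universe),
                             intersect(pathway_sets[[b]], universe)))
    if (length(shared) >= 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        p1 = a, p2 = b, shared_count = length(shared),
        shared_genes = paste(shared, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    warning("no pathway pair shares a member gene", call. = FALSE)
    return(list(nodes = nodes_df, edges = empty_edges))
  }
  edges <- do.call(rbind, rows)
  edges <- edges[order(edges$p1, edges$p2), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges[, c("p1", "p2")], directed = FALSE,
                                     vertices = ids)
  igraph::E(g)$weight <- 1 / edges$shared_count
  tree <- igraph::mst(g, weights = igraph::E(g)$weight)
  tel <- igraph::as_edgelist(tree, names = TRUE)
  tkey <- paste(pmin(tel[, 1], tel[, 2]), pmax(tel[, 1], tel[, 2]))
  ekey <- paste(pmin(edges$p1, edges$p2), pmax(edges$p1, edges$p2))
  edges$mst_flag <- ekey %in% tkey
  edges <- edges[, c("p1", "p2", "shared_count", "mst_flag", "shared_genes")]
  rownames(edges) <- NULL
  list(nodes = nodes_df, edges = edges)
}
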