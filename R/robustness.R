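# Network tolerance to node removal: single/combinatorial removal effects,
# exhaustive optimal drug-combination selection, and targeted-attack curves.
#
# The effect statistic is the fraction of nodes disconnected from the largest
# remaining component (LCC) after removal, with the ORIGINAL node count N as
# denominator throughout (integer-consistent with fractions like 10/53 =
# 18.9% and 12/53 = 22.6% on a 53-node module). Two conventions are offered:
# exclude_removed counts only surviving nodes stranded outside the LCC;
# include_removed additionally counts the removed nodes themselves.

#' Effect of removing a node set
#'
#' @param network igraph with vertex names
#' @param remove_set character vector of nodes to delete (may be empty; must
#'   not be all nodes)
#' @param convention "exclude_removed" (default) or "include_removed"
#' @return `removal_result` list: removed, fraction_disconnected, convention,
#'   n_disconnected, lcc (members of the largest remaining component; size
#'   ties broken by smallest lexicographic member)
#' @export
removal_effect <- function(network, remove_set = character(0),
                           convention = c("exclude_removed", "include_removed")) {
  convention <- match.arg(convention)
  nodes <- igraph::V(network)$name
  n <- length(nodes)
  remove_set <- unique(remove_set)
  if (!all(remove_set %in% nodes)) {
    stop("remove_set contains nodes absent from the network", call. = FALSE)
  }
  if (length(remove_set) >= n) stop("cannot remove all nodes", call. = FALSE)
  g2 <- igraph::delete_vertices(network, remove_set)
  cmp <- igraph::components(g2)
  max_size <- max(cmp$csize)
  cand <- which(cmp$csize == max_size)
  if (length(cand) > 1L) {
    firsts <- vapply(cand, function(ci) min(igraph::V(g2)$name[cmp$membership == ci]), "")
    cand <- cand[order(firsts)][1L]
  }
  lcc <- sort(igraph::V(g2)$name[cmp$membership == cand])
  stranded <- igraph::vcount(g2) - max_size
  n_disc <- if (convention == "include_removed") stranded + length(remove_set) else stranded
  structure(list(removed = sort(remove_set),
                 fraction_disconnected = n_disc / n,
                 n_disconnected = n_disc, n = n,
                 convention = convention, lcc = lcc),
            class = "removal_result")
}

#' Exhaustive optimal combinatorial removal
#'
#' Enumerates every size-k subset of `candidates` for k in
#' `[k_min, k_max]` and reports, per k, the subset(s) maximizing the
#' disconnected fraction (all ties reported). Enumeration is guarded at 1e6
#' combinations; beyond that an error suggests narrowing candidates.
#'
#' @param network igraph with vertex names
#' @param candidates candidate removal nodes (e.g. druggable targets)
#' @param k_min,k_max combination size range
#' @param convention as in [removal_effect()]
#' @return data frame: k, removed (pipe-joined, sorted), fraction_disconnected
#'   — only the optimal row(s) per k
#' @export
optimal_combination <- function(network, candidates, k_min = 1L, k_max = 4L,
                                convention = c("exclude_removed", "include_removed")) {
  convention <- match.arg(convention)
  candidates <- sort(unique(candidates))
  if (k_max > length(candidates)) stop("k_max exceeds candidate count", call. = FALSE)
  if (k_min < 1L || k_min > k_max) stop("need 1 <= k_min <= k_max", call. = FALSE)
  total <- sum(vapply(seq(k_min, k_max), function(k) choose(length(candidates), k), 0))
  if (total > 1e6) {
    stop("combination budget exceeded (", format(total, big.mark = ","),
         " > 1e6); narrow the candidate set or use a beam search", call. = FALSE)
  }
  out <- list()
  for (k in seq(k_min, k_max)) {
    combos <- utils::combn(candidates, k)
    fr <- vapply(seq_len(ncol(combos)), function(j) {
      removal_effect(network, combos[, j], convention)$fraction_disconnected
    }, 0)
    best <- max(fr)
    ties <- which(abs(fr - best) < 1e-12)
    out[[length(out) + 1L]] <- data.frame(
      k = k,
      removed = vapply(ties, function(j) paste(combos[, j], collapse = "|"), ""),
      fraction_disconnected = best,
      convention = convention,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$k, res$removed), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Targeted-attack curve
#'
#' Nodes are pre-ordered once (statically) by descending degree, betweenness
#' or a supplied priority score — ties broken by gene symbol — then removed
#' one at a time; after each removal the disconnected fraction is recorded.
#' The last point removes all but one node.
#'
#' @param network igraph with vertex names
#' @param ordering "degree", "betweenness" or "priority"
#' @param score_vector named scores, required when `ordering = "priority"`
#' @param convention as in [removal_effect()]
#' @return `attack_curve` data frame: step, removed_gene, fraction_removed,
#'   fraction_disconnected
#' @export
targeted_attack <- function(network,
                            ordering = c("degree", "betweenness", "priority"),
                            score_vector = NULL,
                            convention = c("exclude_removed", "include_removed")) {
  ordering <- match.arg(ordering)
  convention <- match.arg(convention)
  nodes <- igraph::V(network)$name
  n <- length(nodes)
  stat <- switch(ordering,
    degree = igraph::degree(network),
    betweenness = igraph::betweenness(network, weights = NA),
    priority = {
      if (is.null(score_vector)) stop("priority ordering needs score_vector", call. = FALSE)
      if (!all(nodes %in% names(score_vector))) {
        stop("score_vector must cover all nodes", call. = FALSE)
      }
      score_vector[nodes]
    })
  ord <- nodes[order(-as.numeric(stat), nodes)]
  res <- data.frame(step = seq_len(n - 1L), removed_gene = ord[seq_len(n - 1L)],
                    fraction_removed = seq_len(n - 1L) / n,
                    fraction_disconnected = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n - 1L)) {
    res$fraction_disconnected[i] <-
      removal_effect(network, ord[seq_len(i)], convention)$fraction_disconnected
  }
  attr(res, "ordering") <- ordering
  attr(res, "convention") <- convention
  class(res) <- c("attack_curve", "data.frame")
  res
}
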