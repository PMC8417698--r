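# Evidence-seeded network propagation and the 0-5 priority rating.
#
# Seeds are a weighted combination of non-negative evidence layers (genomic
# proximity, eQTL, chromatin conformation, ...), normalized to a probability
# vector; a random walk with restart over the interaction network spreads
# seed mass to interaction neighbours; the stationary affinity is converted to
# a rank-based rating on the bounded 0-5 scale.

#' Random-walk-with-restart parameters
#'
#' @param restart restart probability r in (0, 1]. r = 1 reproduces the seeds
#'   exactly; smaller r diffuses further. Default 0.75 (conservative:
#'   affinities stay close to the genetic evidence).
#' @param tol L1 convergence tolerance (default 1e-10)
#' @param max_iter iteration cap; hitting it flags non-convergence but is not
#'   an error
#' @param weights optional named non-negative layer weights for
#'   [combine_evidence()]; default all 1
#' @return an `rwr_params` list
#' @export
rwr_params <- function(restart = 0.75, tol = 1e-10, max_iter = 10000L,
                       weights = NULL) {
  stopifnot_scalar_number(restart, "restart", lower = 1e-12, upper = 1)
  stopifnot_scalar_number(tol, "tol", lower = 1e-300)
  stopifnot_scalar_number(max_iter, "max_iter", lower = 1)
  if (!is.null(weights) && any(weights < 0)) {
    stop("layer weights must be non-negative", call. = FALSE)
  }
  structure(list(restart = restart, tol = tol, max_iter = as.integer(max_iter),
                 weights = weights), class = "rwr_params")
}

#' Combine evidence layers into a seed-score vector
#'
#' Per-gene seed = weighted sum of layer scores, normalized to sum to one.
#' With all-zero evidence the seeds degenerate to the uniform vector 1/N
#' (propagation then reports pure network centrality).
#'
#' @param evidence evidence data frame (`gene` + numeric layer columns)
#' @param weights named non-negative weights covering every layer present;
#'   NULL = all layers weight 1
#' @return named numeric vector summing to 1
#' @export
combine_evidence <- function(evidence, weights = NULL) {
  evidence <- validate_evidence(evidence)
  layers <- setdiff(names(evidence), "gene")
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(layers)), layers)
  if (any(weights < 0)) stop("layer weights must be non-negative", call. = FALSE)
  missing <- setdiff(layers, names(weights))
  if (length(missing) > 0L) {
    stop("weights missing for layer(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(evidence[, layers, drop = FALSE])
  seeds <- as.numeric(m %*% weights[layers])
  names(seeds) <- evidence$gene
  tot <- sum(seeds)
  if (tot <= 0) {
    seeds[] <- 1 / length(seeds)
  } else {
    seeds <- seeds / tot
  }
  seeds
}

#' Propagate seeds over the network by random walk with restart
#'
#' Power iteration of the fixed point `p = (1 - r) W p + r p0`, with `W` the
#' column-normalized (degree-normalized) adjacency matrix. Mass is conserved
#' at every iteration, so the result sums to 1.  Disconnected networks are
#' propagated per component with each component's seed mass preserved;
#' isolated nodes keep their seed mass untouched.
#'
#' @param network igraph with vertex names
#' @param seeds named non-negative vector over all vertices, summing to 1
#' @param params [rwr_params()]
#' @return named affinity vector summing to 1; attributes `converged`
#'   (logical) and `iterations`
#' @export
propagate <- function(network, seeds, params = rwr_params()) {
  nodes <- igraph::V(network)$name
  if (!setequal(names(seeds), nodes)) {
    stop("seeds must be named for exactly the network's vertices", call. = FALSE)
  }
  seeds <- seeds[nodes]
  if (any(seeds < 0) || abs(sum(seeds) - 1) > 1e-6) {
    stop("seeds must be non-negative and sum to 1", call. = FALSE)
  }
  r <- params$restart
  A <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  deg <- Matrix::colSums(A)
  n <- length(nodes)
  p <- p0 <- as.numeric(seeds)
  W <- A %*% Matrix::Diagonal(n, x = ifelse(deg > 0, 1 / deg, 0))
  # Isolated nodes have an all-zero column in W; adding back r would leak
  # their mass, so pin it: their fixed point is p_i = p0_i (walker restarts
  # forever). Handled naturally because W drops their mass and we re-inject
  # it below.
  iso <- deg == 0
  converged <- FALSE
  iters <- 0L
  for (i in seq_len(params$max_iter)) {
    iters <- i
    p_new <- (1 - r) * as.numeric(W %*% p) + r * p0
    if (any(iso)) p_new[iso] <- p0[iso]
    if (sum(abs(p_new - p)) < params$tol) {
      p <- p_new
      converged <- TRUE
      break
    }
    p <- p_new
  }
  names(p) <- nodes
  if (!converged) {
    warning(sprintf("propagation did not converge in %d iterations", params$max_iter),
            call. = FALSE)
  }
  attr(p, "converged") <- converged
  attr(p, "iterations") <- iters
  p
}

#' Convert affinities to the 0-5 priority rating
#'
#' Rating is rank-based: `5 * (N - rank + 1) / N` using average ranks of the
#' affinity (ties share a rating). The reported integer `rank` column breaks
#' ties deterministically by gene symbol and is a permutation of 1..N. Output
#' is sorted by rank (top gene first).
#'
#' @param affinity named non-negative numeric vector
#' @return `priority_table` data frame: gene, rating, rank, affinity
#' @export
rate_genes <- function(affinity) {
  if (anyNA(affinity) || any(!is.finite(affinity)) || any(affinity < 0)) {
    stop("affinity must be finite and non-negative", call. = FALSE)
  }
  n <- length(affinity)
  genes <- names(affinity)
  avg_rank <- rank(-affinity, ties.method = "average")
  rating <- 5 * (n - avg_rank + 1) / n
  ord <- order(-affinity, genes)
  out <- data.frame(gene = genes[ord], rating = rating[ord],
                    rank = seq_len(n), affinity = as.numeric(affinity)[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("priority_table", "data.frame")
  out
}

#' Top fraction of prioritized genes
#'
#' Returns the `round(fraction * N)` highest-ranked genes, rounding half away
#' from zero (top 1% of 12,466 genes = 125). Boundary ties were already
#' resolved deterministically (by gene symbol) in [rate_genes()].
#'
#' @param priority a `priority_table`
#' @param fraction in (0, 1]
#' @return character vector of gene symbols
#' @export
top_fraction <- function(priority, fraction) {
  stopifnot_scalar_number(fraction, "fraction", lower = 1e-12, upper = 1)
  n <- nrow(priority)
  m <- round_half_up(fraction * n)
  if (m < 1L) stop("fraction selects zero genes", call. = FALSE)
  priority$gene[seq_len(min(m, n))]
}

#' One-call prioritization: combine, propagate, rate
#'
#' @param network igraph with vertex names
#' @param evidence evidence data frame covering the network's genes
#' @param params [rwr_params()]
#' @return `priority_table`; the propagation convergence flag is carried in
#'   `attr(, "converged")`
#' @export
prioritize <- function(network, evidence, params = rwr_params()) {
  nodes <- igraph::V(network)$name
  evidence <- evidence[match(nodes, evidence$gene), , drop = FALSE]
  if (anyNA(evidence$gene)) stop("evidence table does not cover all network genes", call. = FALSE)
  seeds <- combine_evidence(evidence, params$weights)
  aff <- propagate(network, seeds, params)
  out <- rate_genes(aff)
  attr(out, "converged") <- attr(aff, "converged")
  out
}

#' One-step interaction neighbours of a gene set
#'
#' All direct network neighbours of `genes`, excluding the genes themselves.
#' Used e.g. to test whether neighbours of a curated set (inflammasome-style)
#' are enriched among top-prioritized genes even when the set itself is not.
#'
#' @param network igraph with vertex names
#' @param genes gene symbols (silently intersected with the network)
#' @return sorted character vector
#' @export
neighbor_set <- function(network, genes) {
  genes <- intersect(genes, igraph::V(network)$name)
  if (length(genes) == 0L) return(character(0))
  nodes <- igraph::V(network)$name
  nb <- igraph::adjacent_vertices(network, genes)
  nb <- unique(nodes[unlist(lapply(nb, as.integer))])
  sort(setdiff(nb, genes))
}
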