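# Independent oracles: deliberately different algorithms/routes from the
# package implementations they check.

# Upper-tail hypergeometric by explicit mass summation with choose().
oracle_hyper_tail <- function(k, K, N, n) {
  if (K == 0L) return(1)
  ks <- seq(k, min(n, K))
  if (length(ks) == 0L || k > min(n, K)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# From-scratch Benjamini-Hochberg step-up with monotone enforcement.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive maximum-score connected subgraph by recursive enumeration of
# connected vertex subsets (each subset visited once: subsets containing
# vertex v but no vertex < v). Distinct route from the package's bitmask scan.
oracle_best_connected <- function(graph, scores) {
  nodes <- igraph::V(graph)$name
  n <- length(nodes)
  adj <- lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
  s <- as.numeric(scores[nodes])
  best <- new.env()
  best$score <- -Inf
  recurse <- function(set, frontier, banned) {
    sc <- sum(s[set])
    if (sc > best$score) {
      best$score <- sc
      best$set <- set
    }
    while (length(frontier) > 0L) {
      u <- frontier[1L]
      frontier <- frontier[-1L]
      new_front <- union(frontier, setdiff(adj[[u]], c(set, banned, u)))
      recurse(c(set, u), new_front, banned)
      banned <- c(banned, u)
    }
  }
  for (v in seq_len(n)) {
    recurse(v, setdiff(adj[[v]], seq_len(v)), seq_len(v - 1L))
  }
  list(score = best$score, genes = sort(nodes[best$set]))
}

# Independent recursive subset enumerator for combinatorial removal
# (depth-first, no utils::combn).
oracle_best_removal <- function(network, candidates, k, convention) {
  best <- new.env(); best$fr <- -1
  recurse <- function(chosen, rest) {
    if (length(chosen) == k) {
      fr <- removal_effect(network, chosen, convention)$fraction_disconnected
      if (fr > best$fr) best$fr <- fr
      return(invisible())
    }
    if (length(chosen) + length(rest) < k) return(invisible())
    recurse(c(chosen, rest[1L]), rest[-1L])
    recurse(chosen, rest[-1L])
  }
  recurse(character(0), candidates)
  best$fr
}

# Brute-force minimum spanning tree total weight: try all |V|-1 edge subsets.
oracle_mst_weight <- function(edges_df) {
  verts <- sort(unique(c(edges_df$p1, edges_df$p2)))
  nv <- length(verts)
  ne <- nrow(edges_df)
  w <- 1 / edges_df$shared_count
  best <- Inf
  for (idx in utils::combn(ne, nv - 1L, simplify = FALSE)) {
    g <- igraph::graph_from_data_frame(edges_df[idx, c("p1", "p2")],
                                       directed = FALSE, vertices = verts)
    if (igraph::is_connected(g)) best <- min(best, sum(w[idx]))
  }
  best
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Random connected simple graph with named vertices.
rand_connected_graph <- function(n, p = 0.3) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# Four well-separated disease-profile blocks (one per cluster), 15 genes each.
block_profiles <- function(seed, n_per = 15, noise = 0.3) {
  set.seed(seed)
  blocks <- diag(4) * 4.5 + 0.5
  prof <- do.call(rbind, lapply(1:4, function(b) {
    matrix(rep(blocks[b, ], each = n_per), n_per) +
      matrix(rnorm(n_per * 4, 0, noise), n_per)
  }))
  prof <- pmax(prof, 0)
  rownames(prof) <- sprintf("g%02d", seq_len(nrow(prof)))
  colnames(prof) <- paste0("D", 1:4)
  prof
}

# Priority table straight from an affinity-like vector.
toy_priority <- function(values, genes = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_along(values))
  rate_genes(stats::setNames(values, genes))
}
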