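# Gene-set enrichment: one-sided Fisher over-representation (hypergeometric
# upper tail) and rank-based target set enrichment (GSEA-style running sum on
# the priority-rating ranking) with leading-prioritization extraction.

#' One-sided Fisher (hypergeometric) over-representation test
#'
#' For each set, with overlap k, query size n, set size K (inside the
#' universe) and universe size N, reports the upper-tail p-value
#' `P(X >= k)` of Hypergeometric(N, K, n); the odds ratio of the 2x2 table
#' (Haldane 0.5 correction when any cell is zero) with a log-normal 95% CI;
#' a z-score standardizing k by the hypergeometric mean and sd; and a BH FDR
#' across the collection.
#'
#' Sets are intersected with the universe before testing. Query genes outside
#' the universe are an error (they would silently bias n).
#'
#' @param query character vector of query genes (subset of universe)
#' @param sets `gene_set_collection` or named list of character vectors
#' @param universe character vector, the annotation/background universe
#' @return data frame: set_id, k, n, K, N, Z, OR, CI_low, CI_high, p, FDR;
#'   sorted by p then set_id
#' @export
fisher_enrichment <- function(query, sets, universe) {
  query <- unique(query)
  universe <- unique(universe)
  off <- setdiff(query, universe)
  if (length(off) > 0L) {
    stop("query genes outside universe: ", paste(utils::head(off, 10), collapse = ", "),
         call. = FALSE)
  }
  N <- length(universe)
  n <- length(query)
  res <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]], universe)
    K <- length(members)
    k <- length(intersect(query, members))
    p <- if (K == 0L) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    a <- k; b <- n - k; c_ <- K - k; d <- N - n - K + k
    if (min(a, b, c_, d) == 0) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
    or <- (a * d) / (b * c_)
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    mean_k <- n * K / N
    sd_k <- sqrt(n * (K / N) * (1 - K / N) * ((N - n) / max(N - 1, 1)))
    z <- if (sd_k > 0) (k - mean_k) / sd_k else 0
    data.frame(set_id = id, k = k, n = n, K = K, N = N, Z = z, OR = or,
               CI_low = exp(log(or) - 1.96 * se),
               CI_high = exp(log(or) + 1.96 * se),
               p = min(p, 1), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$FDR <- bh_adjust(out$p)
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Running-sum walk over the rating-ranked list. Hits contribute
# rating^weight_exponent (normalized over the set's hits); misses contribute
# -1/(N - K). Returns the cumulative sum.
tsea_walk <- function(ratings_ranked, hit, weight_exponent) {
  n <- length(ratings_ranked)
  K <- sum(hit)
  w <- if (weight_exponent == 0) rep(1, n) else abs(ratings_ranked)^weight_exponent
  hit_w <- w * hit
  tot <- sum(hit_w)
  if (tot <= 0) hit_w[hit] <- 1 / K else hit_w <- hit_w / tot
  step <- ifelse(hit, hit_w, -1 / (n - K))
  cumsum(step)
}

#' Rank-based target set enrichment analysis
#'
#' Conceptually a gene-set enrichment analysis run on the priority-rating
#' ranking: walking down the rating-sorted gene list, the running sum rises
#' by a rating-weighted increment at each set member ("hit") and falls by
#' `1/(N-K)` otherwise. The enrichment score ES is the maximum positive
#' deviation (prioritization is one-tailed by construction); NES divides ES
#' by its mean under gene-label permutations, and the permutation p-value
#' uses the standard +1 pseudocount. FDR is BH across sets.
#'
#' Set members missing from the priority table are dropped with a warning;
#' sets with fewer than 2 ranked members are skipped with a warning.
#'
#' @param priority a `priority_table` from [rate_genes()]
#' @param sets `gene_set_collection`
#' @param n_perm number of gene-label permutations (default 1000)
#' @param weight_exponent exponent on the rating weight (0 = classic
#'   Kolmogorov-Smirnov walk; default 1)
#' @param seed optional seed for the permutation stream
#' @return data frame: set_id, size, ES, NES, p_perm, FDR, leading_n,
#'   leading_genes (comma-joined); sorted by p then set_id
#' @export
tsea <- function(priority, sets, n_perm = 1000L, weight_exponent = 1,
                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ranked_genes <- priority$gene
  ratings <- priority$rating
  n <- length(ranked_genes)
  res <- list()
  for (id in names(sets)) {
    members <- sets[[id]]
    missing <- setdiff(members, ranked_genes)
    if (length(missing) > 0L) {
      warning(sprintf("set %s: %d member(s) missing from priority table, dropped",
                      id, length(missing)), call. = FALSE)
      members <- setdiff(members, missing)
    }
    K <- length(members)
    if (K < 2L || K >= n) {
      warning(sprintf("set %s skipped (needs 2..N-1 ranked members, has %d)", id, K),
              call. = FALSE)
      next
    }
    hit <- ranked_genes %in% members
    walk <- tsea_walk(ratings, hit, weight_exponent)
    es <- max(walk)
    peak <- which.max(walk)
    leading <- ranked_genes[seq_len(peak)][hit[seq_len(peak)]]
    perm_es <- vapply(seq_len(n_perm), function(i) {
      ph <- logical(n)
      ph[sample.int(n, K)] <- TRUE
      max(tsea_walk(ratings, ph, weight_exponent))
    }, 0)
    nes <- if (mean(perm_es) > 0) es / mean(perm_es) else NA_real_
    p <- (1 + sum(perm_es >= es)) / (1 + n_perm)
    res[[id]] <- data.frame(set_id = id, size = K, ES = es, NES = nes,
                            p_perm = p, leading_n = length(leading),
                            leading_genes = paste(leading, collapse = ","),
                            stringsAsFactors = FALSE)
  }
  if (length(res) == 0L) {
    return(data.frame(set_id = character(0), size = integer(0), ES = numeric(0),
                      NES = numeric(0), p_perm = numeric(0), FDR = numeric(0),
                      leading_n = integer(0), leading_genes = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out$FDR <- bh_adjust(out$p_perm)
  out <- out[order(out$p_perm, out$set_id),
             c("set_id", "size", "ES", "NES", "p_perm", "FDR", "leading_n", "leading_genes")]
  rownames(out) <- NULL
  out
}

#' Leading prioritization of a gene set
#'
#' The core subset of a set that accounts for its enrichment signal: the
#' members ranked at or before the position of the running-sum peak (the
#' left-most region ahead of the peak), analogous to a GSEA leading edge.
#'
#' @param priority a `priority_table`
#' @param set_members character vector of member genes
#' @param weight_exponent as in [tsea()]
#' @return character vector of leading genes, in rank order
#' @export
leading_prioritization <- function(priority, set_members, weight_exponent = 1) {
  ranked_genes <- priority$gene
  members <- intersect(set_members, ranked_genes)
  hit <- ranked_genes %in% members
  if (!any(hit)) return(character(0))
  walk <- tsea_walk(priority$rating, hit, weight_exponent)
  peak <- which.max(walk)
  ranked_genes[seq_len(peak)][hit[seq_len(peak)]]
}
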