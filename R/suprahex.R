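# Cross-disease comparison on a supra-hexagonal self-organizing map: a
# hexagon-of-hexagons lattice (1 + 6(r-1) ring growth; 19 hexagons at radius
# 3) whose codebook vectors are trained on gene x disease priority profiles,
# partitioned into contiguous clusters, and overlaid with binary tractability.

hex_directions <- matrix(c(1, 0, 1, -1, 0, -1, -1, 0, -1, 1, 0, 1),
                         ncol = 2, byrow = TRUE)

#' Hex-grid distance between axial coordinates
#' @param a,b length-2 axial coordinates (q, r) or matrices with 2 columns
#' @return integer grid distance(s)
#' @export
hex_distance <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 2)
  if (is.null(dim(b))) b <- matrix(b, ncol = 2)
  dq <- a[, 1] - b[, 1]
  dr <- a[, 2] - b[, 2]
  (abs(dq) + abs(dr) + abs(dq + dr)) / 2
}

#' Build an (untrained) supra-hexagonal map
#'
#' Hexagons are laid out on an axial-coordinate lattice and indexed H1, H2,
#' ... spiralling outward from the centre; ring i (i >= 1) holds 6i hexagons,
#' so the count is `1 + sum(6 * 1:(radius-1))` — 19 at radius 3.
#'
#' @param radius supra-hexagon radius (>= 1); radius 1 is a single hexagon
#' @return `suprahex_map` list: `hexes` (index, label, q, r, ring),
#'   `coords` (axial matrix), `radius`; codebook NULL until trained
#' @export
build_map <- function(radius = 3L) {
  stopifnot_scalar_number(radius, "radius", lower = 1)
  radius <- as.integer(radius)
  coords <- matrix(0, nrow = 1, ncol = 2)
  if (radius > 1L) {
    for (k in seq_len(radius - 1L)) {
      hex <- k * hex_directions[5, ]
      for (side in 1:6) {
        for (step in seq_len(k)) {
          coords <- rbind(coords, hex)
          hex <- hex + hex_directions[side, ]
        }
      }
    }
  }
  nhex <- nrow(coords)
  hexes <- data.frame(index = seq_len(nhex), label = paste0("H", seq_len(nhex)),
                      q = coords[, 1], r = coords[, 2],
                      ring = hex_distance(coords, c(0, 0)),
                      stringsAsFactors = FALSE)
  structure(list(hexes = hexes, coords = coords, radius = radius,
                 codebook = NULL, bmu = NULL, qe = NULL, clusters = NULL),
            class = "suprahex_map")
}

# nhex x nhex grid-distance matrix
map_grid_distances <- function(map) {
  nhex <- nrow(map$coords)
  outer(seq_len(nhex), seq_len(nhex),
        Vectorize(function(i, j) hex_distance(map$coords[i, ], map$coords[j, ])))
}

#' Hex adjacency (unit grid distance) of a map
#' @param map `suprahex_map`
#' @return logical adjacency matrix
#' @export
map_adjacency <- function(map) {
  map_grid_distances(map) == 1
}

#' SOM training parameters
#'
#' Two-phase schedule: a rough phase (first half of the epochs) with the
#' neighbourhood radius decaying from `sigma0` (default: map radius) to 1,
#' then a fine phase at sigma 1; the learning rate decays from `alpha0`
#' to 0.01 across all epochs (linearly by default).
#'
#' @param epochs total training epochs (default 40)
#' @param alpha0 initial learning rate in (0, 1] (default 0.5)
#' @param sigma0 initial neighbourhood radius (> 0); NULL = map radius
#' @param schedule "linear" or "exponential" decay
#' @param k_clusters default cluster count for [cluster_map()] (default 4)
#' @param batch use batch (per-epoch) updates instead of sequential ones
#' @param seed RNG seed for per-epoch presentation order (and the random
#'   codebook fallback)
#' @return `som_params` list
#' @export
som_params <- function(epochs = 40L, alpha0 = 0.5, sigma0 = NULL,
                       schedule = c("linear", "exponential"), k_clusters = 4L,
                       batch = FALSE, seed = NULL) {
  schedule <- match.arg(schedule)
  stopifnot_scalar_number(epochs, "epochs", lower = 1)
  stopifnot_scalar_number(alpha0, "alpha0", lower = 1e-9, upper = 1)
  if (!is.null(sigma0)) stopifnot_scalar_number(sigma0, "sigma0", lower = 1e-9)
  structure(list(epochs = as.integer(epochs), alpha0 = alpha0, sigma0 = sigma0,
                 schedule = schedule, k_clusters = as.integer(k_clusters),
                 batch = isTRUE(batch), seed = seed), class = "som_params")
}

som_schedule <- function(params, sigma0, t) {
  T <- params$epochs
  frac <- if (T > 1L) (t - 1) / (T - 1) else 0
  alpha <- if (params$schedule == "linear") {
    params$alpha0 + (0.01 - params$alpha0) * frac
  } else {
    params$alpha0 * (0.01 / params$alpha0)^frac
  }
  t_rough <- ceiling(T / 2)
  sigma <- if (t <= t_rough) {
    if (t_rough > 1L) sigma0 + (1 - sigma0) * (t - 1) / (t_rough - 1) else sigma0
  } else {
    1
  }
  list(alpha = alpha, sigma = max(sigma, 1e-9))
}

# Deterministic codebook init: linear interpolation of the profile matrix's
# first two principal directions across the hex plane; seeded random jitter
# around the mean for degenerate rank.
init_codebook <- function(map, profiles) {
  nhex <- nrow(map$coords)
  d <- ncol(profiles)
  mu <- colMeans(profiles)
  x <- map$coords[, 1] + map$coords[, 2] / 2
  y <- map$coords[, 2] * sqrt(3) / 2
  scale_xy <- function(v) if (max(abs(v)) > 0) v / max(abs(v)) else v
  pc <- tryCatch(stats::prcomp(profiles, center = TRUE, scale. = FALSE),
                 error = function(e) NULL)
  ok <- !is.null(pc) && ncol(pc$rotation) >= 2 && pc$sdev[1] > 1e-12
  if (ok) {
    s2 <- if (pc$sdev[2] > 1e-12) pc$sdev[2] else pc$sdev[1]
    cb <- matrix(mu, nhex, d, byrow = TRUE) +
      outer(scale_xy(x), pc$rotation[, 1] * pc$sdev[1]) +
      outer(scale_xy(y), pc$rotation[, 2] * s2)
  } else {
    cb <- matrix(mu, nhex, d, byrow = TRUE) +
      matrix(stats::rnorm(nhex * d, 0, 0.01), nhex, d)
  }
  dimnames(cb) <- list(paste0("H", seq_len(nhex)), colnames(profiles))
  cb
}

som_bmu <- function(codebook, x) {
  which.min(colSums((t(codebook) - x)^2))
}

quantization_error <- function(codebook, profiles) {
  mean(vapply(seq_len(nrow(profiles)), function(i) {
    x <- profiles[i, ]
    sqrt(min(colSums((t(codebook) - x)^2)))
  }, 0))
}

#' Train the supra-hexagonal map
#'
#' Sequential best-matching-unit learning: each gene profile pulls its BMU
#' and (Gaussian-weighted by hex-grid distance) neighbourhood towards itself,
#' `m <- m + alpha(t) * h(bmu, m; sigma(t)) * (x - m)`, with presentation
#' order reshuffled each epoch. The per-epoch quantization error (mean
#' gene-to-BMU Euclidean distance) is recorded. A batch variant (all BMUs
#' assigned first, codebook replaced by neighbourhood-weighted means) is
#' available via `som_params(batch = TRUE)`.
#'
#' @param map a [build_map()] result
#' @param profiles numeric gene x disease matrix (rownames = genes); at
#'   least 2 disease columns; fewer genes than hexagons triggers a warning
#' @param params [som_params()]
#' @return the map with `codebook`, `bmu` (named per-gene hexagon index) and
#'   `qe` (per-epoch quantization error) filled in
#' @export
train_som <- function(map, profiles, params = som_params()) {
  profiles <- as.matrix(profiles)
  if (anyNA(profiles) || any(!is.finite(profiles))) {
    stop("profiles must be finite", call. = FALSE)
  }
  if (ncol(profiles) < 2L) stop("need at least 2 diseases", call. = FALSE)
  nhex <- nrow(map$coords)
  if (nrow(profiles) < nhex) {
    warning("fewer genes than hexagons; some hexagons will be empty", call. = FALSE)
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  sigma0 <- params$sigma0 %||% map$radius
  gridd <- map_grid_distances(map)
  cb <- init_codebook(map, profiles)
  qe <- numeric(params$epochs)
  ng <- nrow(profiles)
  for (t in seq_len(params$epochs)) {
    sched <- som_schedule(params, sigma0, t)
    h_all <- exp(-gridd^2 / (2 * sched$sigma^2))
    ord <- sample.int(ng)
    if (params$batch) {
      bmus <- vapply(seq_len(ng), function(i) som_bmu(cb, profiles[i, ]), 0L)
      Hw <- h_all[bmus, , drop = FALSE]          # gene x hex weights
      denom <- colSums(Hw)
      num <- t(Hw) %*% profiles
      upd <- denom > 1e-12
      cb[upd, ] <- num[upd, , drop = FALSE] / denom[upd]
    } else {
      for (i in ord) {
        x <- profiles[i, ]
        b <- som_bmu(cb, x)
        h <- sched$alpha * h_all[b, ]
        cb <- cb + h * (matrix(x, nhex, ncol(cb), byrow = TRUE) - cb)
      }
    }
    qe[t] <- quantization_error(cb, profiles)
  }
  bmu <- vapply(seq_len(ng), function(i) som_bmu(cb, profiles[i, ]), 0L)
  names(bmu) <- rownames(profiles)
  map$codebook <- cb
  map$bmu <- bmu
  map$qe <- qe
  map$params <- params
  map
}

#' Partition the trained map into contiguous clusters
#'
#' Average-linkage hierarchical clustering of the codebook vectors into `k`
#' groups, followed by contiguity repair: while any cluster is split into
#' several regions under hex adjacency, its smallest fragment is reassigned
#' to the adjacent cluster with the nearest mean codebook. Cluster labels
#' C1..Ck are ordered by each cluster's smallest hexagon index.
#'
#' @param map trained `suprahex_map`
#' @param k number of clusters (1..hexagon count)
#' @return character vector of per-hexagon labels ("C1".."Ck"); also stored
#'   in `map$clusters` if you reassign the result of `cluster_map` via
#'   `map$clusters <- ...`
#' @export
cluster_map <- function(map, k = 4L) {
  if (is.null(map$codebook)) stop("map is untrained", call. = FALSE)
  nhex <- nrow(map$coords)
  if (k < 1L || k > nhex) stop("k must be in 1..hexagon count", call. = FALSE)
  memb <- if (k == 1L) {
    rep(1L, nhex)
  } else {
    hc <- stats::hclust(stats::dist(map$codebook), method = "average")
    stats::cutree(hc, k = k)
  }
  adj <- map_adjacency(map)
  hex_regions <- function(memb, cl) {
    idx <- which(memb == cl)
    seen <- logical(length(idx))
    regions <- list()
    while (any(!seen)) {
      start <- idx[which(!seen)[1]]
      comp <- start
      repeat {
        grow <- which(apply(adj[comp, , drop = FALSE], 2, any) & memb == cl)
        grow <- setdiff(grow, comp)
        if (length(grow) == 0L) break
        comp <- c(comp, grow)
      }
      regions[[length(regions) + 1L]] <- sort(comp)
      seen[match(comp, idx)] <- TRUE
    }
    regions
  }
  for (iter in seq_len(5L * nhex)) {
    frags <- list()
    for (cl in sort(unique(memb))) {
      reg <- hex_regions(memb, cl)
      if (length(reg) > 1L) {
        sizes <- vapply(reg, length, 0L)
        frags[[length(frags) + 1L]] <- reg[[order(sizes)[1]]]
      }
    }
    if (length(frags) == 0L) break
    frag <- frags[[order(vapply(frags, length, 0L))[1]]]
    nb_hex <- which(apply(adj[frag, , drop = FALSE], 2, any))
    nb_hex <- setdiff(nb_hex, frag)
    nb_cl <- setdiff(unique(memb[nb_hex]), unique(memb[frag]))
    if (length(nb_cl) == 0L) break
    frag_mean <- colMeans(map$codebook[frag, , drop = FALSE])
    dists <- vapply(nb_cl, function(cl) {
      sum((colMeans(map$codebook[memb == cl, , drop = FALSE]) - frag_mean)^2)
    }, 0)
    memb[frag] <- nb_cl[which.min(dists)]
  }
  first_idx <- vapply(sort(unique(memb)), function(cl) min(which(memb == cl)), 0L)
  relabel <- stats::setNames(order(order(first_idx)), sort(unique(memb)))
  paste0("C", relabel[as.character(memb)])
}

#' Overlay binary tractability on a trained map
#'
#' Per-hexagon probability = tractable / mapped gene count (NA for empty
#' hexagons); per-cluster percentage = pooled ratio over the cluster's
#' hexagons (equivalently the mapped-count-weighted mean of member-hexagon
#' probabilities).
#'
#' @param map trained `suprahex_map`
#' @param tract tractability table: gene, tractable (0/1); mapped genes
#'   missing from it are excluded with a warning
#' @param clusters optional per-hexagon cluster labels from [cluster_map()]
#' @return list: `hexagons` (index, n_genes, n_tractable, probability),
#'   `clusters` (cluster, n_genes, n_tractable, percentage; NULL when no
#'   clusters given)
#' @export
overlay_binary <- function(map, tract, clusters = NULL) {
  if (is.null(map$bmu)) stop("map is untrained", call. = FALSE)
  genes <- names(map$bmu)
  known <- genes %in% tract$gene
  if (any(!known)) {
    warning(sum(!known), " mapped gene(s) missing from tractability table, excluded",
            call. = FALSE)
  }
  tr <- stats::setNames(tract$tractable, tract$gene)[genes[known]]
  bmu <- map$bmu[known]
  nhex <- nrow(map$coords)
  n_genes <- tabulate(bmu, nbins = nhex)
  n_tract <- vapply(seq_len(nhex), function(h) sum(tr[bmu == h]), 0)
  hexdf <- data.frame(index = seq_len(nhex), label = paste0("H", seq_len(nhex)),
                      n_genes = n_genes, n_tractable = n_tract,
                      probability = ifelse(n_genes > 0, n_tract / n_genes, NA_real_),
                      stringsAsFactors = FALSE)
  cldf <- NULL
  if (!is.null(clusters)) {
    cl_levels <- sort(unique(clusters))
    cldf <- do.call(rbind, lapply(cl_levels, function(cl) {
      hx <- which(clusters == cl)
      ng <- sum(n_genes[hx]); nt <- sum(n_tract[hx])
      data.frame(cluster = cl, n_genes = ng, n_tractable = nt,
                 percentage = if (ng > 0) 100 * nt / ng else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  list(hexagons = hexdf, clusters = cldf)
}

#' Pairwise Pearson correlations between disease profiles
#'
#' Two-sided p-values from the t statistic `r * sqrt((n-2)/(1-r^2))` on
#' n - 2 degrees of freedom. Zero-variance profiles give NA with a warning.
#'
#' @param profiles numeric gene x disease matrix with >= 3 genes
#' @return list: `r` (correlation matrix), `p` (p-value matrix)
#' @export
disease_correlations <- function(profiles) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < 3L) stop("need at least 3 genes for correlation", call. = FALSE)
  sds <- apply(profiles, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance profile(s): ",
            paste(colnames(profiles)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(profiles))
  r[, sds == 0] <- NA; r[sds == 0, ] <- NA
  diag(r)[sds > 0] <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA
  list(r = r, p = p)
}

#' Enrichment of a gene subset for tractable genes
#'
#' One-sided Fisher test of the subset against the tractable gene set.
#'
#' @param subset character vector (e.g. crosstalk genes), subset of universe
#' @param tract tractability table (gene, tractable)
#' @param universe background universe
#' @return single-row enrichment data frame
#' @export
tractability_enrichment <- function(subset, tract, universe) {
  tractable <- tract$gene[tract$tractable == 1]
  fisher_enrichment(intersect(subset, universe),
                    list(tractable = tractable), universe)
}

#' Order diseases by similarity of their map representation
#'
#' Reporting helper for the disease-landscape frame: hierarchical clustering
#' of the codebook columns (one per disease), returning a display order in
#' which similar prioritization profiles sit next to each other.
#'
#' @param map trained `suprahex_map`
#' @return character vector of disease names in display order
#' @export
disease_order <- function(map) {
  if (is.null(map$codebook)) stop("map is untrained", call. = FALSE)
  if (ncol(map$codebook) < 3L) return(colnames(map$codebook))
  hc <- stats::hclust(stats::dist(t(map$codebook)), method = "average")
  colnames(map$codebook)[hc$order]
}
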