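# Drug repurposing: join genes to drug annotations, keep each gene's drugs at
# its maximum development phase, categorize approved (phase IV) vs phased
# (phase I-III) targets, and test whether crosstalk genes are enriched for
# either category.

#' Per-gene maximum development phase and target category
#'
#' For each gene the maximum phase across all its drug rows is taken and every
#' drug attaining that phase is kept as support. Categories: `approved` iff
#' max phase 4, `phased` iff max phase 1-3, `none` for genes with only
#' phase-0 (preclinical) rows or absent from the table. Invariant to row
#' order and row duplication.
#'
#' @param drugs drug table: gene, drug, phase (0-4), indication, moa
#' @param genes optional gene universe; genes absent from the table are
#'   reported with category "none"
#' @param indication optional: restrict rows to one indication before the
#'   max-phase selection (the per-indication variant)
#' @return data frame: gene, category, max_phase, drugs (comma-joined
#'   supporting drugs at the max phase)
#' @export
max_phase_targets <- function(drugs, genes = NULL, indication = NULL) {
  if (!all(c("gene", "drug", "phase") %in% names(drugs))) {
    stop("drug table needs gene, drug, phase columns", call. = FALSE)
  }
  if (!all(drugs$phase %in% 0:4)) stop("phases must be integers 0..4", call. = FALSE)
  if (!is.null(indication)) drugs <- drugs[drugs$indication == indication, , drop = FALSE]
  drugs <- unique(drugs[, c("gene", "drug", "phase")])
  per_gene <- split(drugs, drugs$gene)
  rows <- lapply(per_gene, function(d) {
    mp <- max(d$phase)
    sup <- sort(unique(d$drug[d$phase == mp]))
    data.frame(gene = d$gene[1], max_phase = mp,
               drugs = paste(sup, collapse = ","), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), max_phase = integer(0),
                      drugs = character(0), stringsAsFactors = FALSE)
  }
  if (!is.null(genes)) {
    absent <- setdiff(genes, out$gene)
    if (length(absent) > 0L) {
      out <- rbind(out, data.frame(gene = absent, max_phase = 0L, drugs = "",
                                   stringsAsFactors = FALSE))
    }
  }
  out$category <- ifelse(out$max_phase == 4L, "approved",
                         ifelse(out$max_phase >= 1L, "phased", "none"))
  out <- out[order(out$gene), c("gene", "category", "max_phase", "drugs")]
  rownames(out) <- NULL
  out
}

#' Enrichment of crosstalk genes for approved / phased drug targets
#'
#' One one-sided Fisher test per category (approved, phased) treating each
#' category's target genes as a gene set, with BH adjustment across the two
#' tests. An empty category yields p = 1 with a warning.
#'
#' @param crosstalk_genes character vector (subset of `universe`)
#' @param categories result of [max_phase_targets()]
#' @param universe background gene universe (default: genes in `categories`)
#' @return enrichment data frame as from [fisher_enrichment()], one row per
#'   category
#' @export
category_enrichment <- function(crosstalk_genes, categories, universe = NULL) {
  if (is.null(universe)) universe <- categories$gene
  sets <- list(
    approved = categories$gene[categories$category == "approved"],
    phased = categories$gene[categories$category == "phased"])
  for (nm in names(sets)) {
    if (length(sets[[nm]]) == 0L) {
      warning("category `", nm, "` is empty; its p-value is 1", call. = FALSE)
      sets[[nm]] <- character(0)
    }
  }
  keep <- vapply(sets, length, 0L) > 0L
  if (!any(keep)) {
    return(data.frame(set_id = names(sets), k = 0L, n = length(crosstalk_genes),
                      K = 0L, N = length(unique(universe)), Z = 0, OR = NA_real_,
                      CI_low = NA_real_, CI_high = NA_real_, p = 1, FDR = 1,
                      stringsAsFactors = FALSE))
  }
  res <- fisher_enrichment(intersect(crosstalk_genes, universe), sets[keep], universe)
  if (any(!keep)) {
    empty <- data.frame(set_id = names(sets)[!keep], k = 0L,
                        n = length(intersect(crosstalk_genes, universe)), K = 0L,
                        N = length(unique(universe)), Z = 0, OR = NA_real_,
                        CI_low = NA_real_, CI_high = NA_real_, p = 1, FDR = 1,
                        stringsAsFactors = FALSE)
    res <- rbind(res, empty)
    res$FDR <- bh_adjust(res$p)
  }
  res[order(res$set_id), , drop = FALSE]
}
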