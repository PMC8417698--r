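# File formats: tab-separated tables everywhere (UTF-8, '.' decimal, NA as
# empty field), GMT for gene sets, JSON for truth/summary.  All writers emit a
# deterministic row order so reruns diff cleanly.

#' Read a gene-interaction network from an edge-list TSV
#'
#' Expects two or more tab-separated columns: the two endpoint gene symbols
#' and, optionally, an evidence tag (e.g. "experiments"/"databases" as in
#' STRING high-confidence extracts). A header row is sniffed: if the first
#' line's first two fields reappear nowhere as node names and look like
#' column labels ("gene_a"/"from"/...), it is dropped.
#'
#' Self-loops and duplicate edges (in either orientation) are dropped with a
#' warning that counts them. Malformed rows (fewer than 2 non-empty fields)
#' raise an error naming the line.
#'
#' @param path TSV file path
#' @return an undirected simple [igraph::graph] with vertex `name` and edge
#'   attribute `evidence` (NA when the file has no third column)
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty edge list: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header_labels <- c("gene_a", "gene_b", "from", "to", "source", "target",
                     "gene1", "gene2", "node1", "node2")
  start <- 1L
  f1 <- tolower(trimws(fields[[1]][1:2]))
  if (all(f1 %in% header_labels)) start <- 2L
  if (start > length(lines)) stop("edge list has a header but no rows: ", path, call. = FALSE)

  n_self <- 0L
  n_dup <- 0L
  a <- character(0); b <- character(0); ev <- character(0)
  for (i in seq(start, length(fields))) {
    f <- trimws(fields[[i]])
    f <- f[nzchar(f)]
    if (length(f) < 2L) {
      stop(sprintf("malformed edge-list row at line %d of %s", i, path), call. = FALSE)
    }
    a <- c(a, f[1]); b <- c(b, f[2])
    ev <- c(ev, if (length(f) >= 3L) f[3] else NA_character_)
  }
  self <- a == b
  n_self <- sum(self)
  a2 <- pmin(a[!self], b[!self])
  b2 <- pmax(a[!self], b[!self])
  ev2 <- ev[!self]
  key <- paste(a2, b2, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  if (n_self > 0L) warning(sprintf("dropped %d self-loop row(s)", n_self), call. = FALSE)
  if (n_dup > 0L) warning(sprintf("dropped %d duplicate edge row(s)", n_dup), call. = FALSE)
  el <- cbind(a2[!dup], b2[!dup])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$evidence <- ev2[!dup]
  g
}

#' Write a network as a canonical edge-list TSV
#'
#' Canonical form: endpoints sorted within each row, rows sorted
#' lexicographically, so that `write_edge_list()` then [read_edge_list()]
#' is the identity on the underlying simple graph.
#'
#' @param net igraph network with vertex names
#' @param path output path
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  ev <- if ("evidence" %in% igraph::edge_attr_names(net)) {
    igraph::E(net)$evidence
  } else rep(NA_character_, nrow(el))
  a <- pmin(el[, 1], el[, 2])
  b <- pmax(el[, 1], el[, 2])
  o <- order(a, b)
  df <- data.frame(gene_a = a[o], gene_b = b[o], evidence = ev[o],
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' GMT: one set per line, `set_id TAB description TAB member1 TAB member2 ...`.
#' Duplicate members within a set are deduplicated; an empty set (no members)
#' or a duplicated set id is an error.
#'
#' @param path GMT file path
#' @return a `gene_set_collection`: named list of character vectors with a
#'   `description` attribute per set
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate set id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(fields, function(f) {
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L) stop("empty gene set in GMT", call. = FALSE)
    members
  })
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(
    vapply(fields, function(f) if (length(f) >= 2L) f[2] else "", ""), ids)
  class(sets) <- "gene_set_collection"
  sets
}

#' Write a gene-set collection to GMT
#' @param sets named list of character vectors (or `gene_set_collection`)
#' @param path output path
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  ids <- sort(names(sets))
  lines <- vapply(ids, function(id) {
    d <- if (!is.null(desc) && id %in% names(desc)) desc[[id]] else "na"
    paste(c(id, d, sort(unique(sets[[id]]))), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a data frame as TSV (deterministic, NA as empty field)
#' @param df data frame
#' @param path output path
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by this package
#' @param path file path
#' @return data frame
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    na.strings = "", stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

#' Read an evidence table (gene + named non-negative layer columns)
#'
#' @param path TSV with a `gene` column and one column per evidence layer
#'   (canonically nGene, eGene, cGene).
#' @return validated data frame
#' @export
read_evidence <- function(path) {
  df <- read_tsv(path)
  validate_evidence(df)
}

#' Validate an evidence table
#' @param df data frame with `gene` plus numeric layer columns
#' @return the data frame, invisibly checked
#' @export
validate_evidence <- function(df) {
  if (!"gene" %in% names(df)) stop("evidence table needs a `gene` column", call. = FALSE)
  if (anyDuplicated(df$gene)) stop("duplicate genes in evidence table", call. = FALSE)
  layers <- setdiff(names(df), "gene")
  if (length(layers) == 0L) stop("evidence table has no layer columns", call. = FALSE)
  for (l in layers) {
    v <- df[[l]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)) || any(v < 0)) {
      stop(sprintf("evidence layer `%s` must be finite and >= 0", l), call. = FALSE)
    }
  }
  df
}

#' Read a disease-profile matrix TSV (genes x diseases)
#' @param path TSV with `gene` column then one numeric column per disease
#' @return numeric matrix with gene rownames
#' @export
read_disease_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  rownames(m) <- df$gene
  storage.mode(m) <- "double"
  m
}

#' Write a disease-profile matrix TSV
#' @param m numeric matrix, gene rownames
#' @param path output path
#' @export
write_disease_matrix <- function(m, path) {
  o <- order(rownames(m))
  df <- data.frame(gene = rownames(m)[o], m[o, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}
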