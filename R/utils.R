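# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial rounding: 0.5 always rounds up in magnitude (base R's `round()`
#' rounds half to even). Used when converting a fraction of genes to a count,
#' e.g. the top 1% of 12,466 genes is 125.
#'
#' @param x numeric vector
#' @return integer vector
#' @keywords internal
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

# Deterministic sub-seed derivation: one global run seed, fixed offsets per
# component so changing one generator's draws does not reshuffle the others.
# Offsets are small; seed + offset stays well below .Machine$integer.max for
# any sane run seed.
sub_seed <- function(seed, offset) {
  s <- (as.double(seed) + as.double(offset)) %% 2147483647
  as.integer(s)
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over [stats::p.adjust()] kept as a named surface so every
#' module adjusts p-values identically; the step-up construction is
#' oracle-tested against a from-scratch implementation in the test suite.
#'
#' @param p numeric vector of p-values
#' @return adjusted p-values (FDR), same order as input
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

is_gene_vector <- function(x) is.character(x) && !anyNA(x) && all(nzchar(x))
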