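#' Derive a child random seed from a master seed and a stage tag
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' seed and a short stage name, so stages are reproducible independently of
#' the order in which they run. The result always fits a 32-bit R integer.
#'
#' @param seed master seed (integer).
#' @param tag character stage name, e.g. `"parents"`.
#' @return a positive integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# split "A/G" genotype strings into a 2-column allele matrix (NA rows for
# missing calls)
split_geno <- function(g) {
  out <- matrix(NA_character_, length(g), 2L)
  ok <- !is.na(g) & g != "./." & g != "."
  if (any(ok)) {
    parts <- strsplit(g[ok], "/", fixed = TRUE)
    out[ok, 1L] <- vapply(parts, `[`, "", 1L)
    out[ok, 2L] <- vapply(parts, `[`, "", 2L)
  }
  out
}

# canonical unphased genotype string: alleles sorted, "/" separated
join_geno <- function(a1, a2) {
  ifelse(is.na(a1) | is.na(a2), NA_character_,
         paste(pmin(a1, a2), pmax(a1, a2), sep = "/"))
}

is_het <- function(g) {
  al <- split_geno(g)
  !is.na(al[, 1L]) & al[, 1L] != al[, 2L]
}
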