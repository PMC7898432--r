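# Shared helpers and independent oracles for the test suite.
# Oracles are deliberately written as brute force / closed forms that never
# share code with the implementation paths they check.

# build a raw_transmission-shaped object from a label matrix (1/2/NA):
# label 1 encodes allele "A", label 2 allele "G", on one linkage group
make_raw <- function(z, bp = seq_len(nrow(z)) * 1000, lg = "LG01",
                     parent = "maternal") {
  m <- nrow(z)
  al <- matrix(NA_character_, m, ncol(z),
               dimnames = list(sprintf("%s_%d", lg, bp),
                               colnames(z) %||% sprintf("H%03d", seq_len(ncol(z)))))
  al[z == 1L] <- "A"
  al[z == 2L] <- "G"
  mk <- data.frame(marker = rownames(al), lg = lg, bp = bp,
                   a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  list(markers = mk, alleles = al,
       mendel_error = matrix(FALSE, m, ncol(z)), parent = parent)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive minimal-recombination phasing: try every orientation of
# markers 2..m (marker 1 fixed), count label switches between consecutive
# non-missing markers per individual, return the minimum total
exhaustive_min_recomb <- function(z) {
  m <- nrow(z)
  best <- Inf
  for (mask in 0:(2^(m - 1) - 1)) {
    flips <- c(FALSE, as.logical(bitwAnd(mask, 2^(0:(m - 2)))))
    zz <- z
    zz[flips, ] <- 3L - zz[flips, , drop = FALSE]
    tot <- 0L
    for (i in seq_len(ncol(zz))) {
      v <- zz[, i]; v <- v[!is.na(v)]
      if (length(v) > 1L) tot <- tot + sum(diff(v) != 0L)
    }
    best <- min(best, tot)
  }
  as.integer(best)
}

# one-way ANOVA F by explicit sum-of-squares decomposition
anova_F_oracle <- function(values, groups) {
  groups <- as.character(groups)
  gm <- tapply(values, groups, mean)
  ng <- tapply(values, groups, length)
  grand <- mean(values)
  ss_between <- sum(ng * (gm - grand)^2)
  ss_within <- sum((values - gm[groups])^2)
  df1 <- length(gm) - 1L
  df2 <- length(values) - length(gm)
  F <- (ss_between / df1) / (ss_within / df2)
  list(F = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# all permutations of seq_len(n) by filtering the n^n tuple grid
# (clearly independent of the package's recursive generator; small n only)
perms_oracle <- function(n) {
  g <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  g[apply(g, 1L, function(r) length(unique(r)) == n), , drop = FALSE]
}

# small complete-data phasing instance: random true phase + crossovers-free
# labels with optional noise, returned as a 1/2 label matrix
random_label_matrix <- function(m, n, p_flip = 0.25) {
  truth <- matrix(sample(1:2, n, replace = TRUE), m, n, byrow = TRUE)
  noise <- matrix(runif(m * n) < p_flip, m, n)
  z <- ifelse(noise, 3L - truth, truth)
  storage.mode(z) <- "integer"
  z
}

# quick small population for reuse across tests
small_pop <- function(seed = 7, n_lg = 2, markers_per_lg = 80,
                      n_progeny = 60, error = 0, missing = 0,
                      qtls = list(qtl_spec("LG01", 8.2e6,
                                           c(M1P1 = -50, M1P2 = 0,
                                             M2P1 = -71, M2P2 = 99))),
                      noise_sd = 80) {
  cfg <- sim_config(n_lg = n_lg, markers_per_lg = markers_per_lg,
                    n_progeny = n_progeny, genotype_error_rate = error,
                    missing_rate = missing, seed = seed)
  simulate_population(cfg, qtls = qtls, noise_sd = noise_sd)
}
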