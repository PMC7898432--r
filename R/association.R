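#' Single-marker quantitative trait association (OLS Wald test)
#'
#' Ordinary least-squares regression of the trait on a per-marker predictor
#' (a 0/1 transmitted-haplotype indicator, or an allele dosage). Returns
#' the slope, Wald t statistic and asymptotic p from the t distribution
#' with n-2 degrees of freedom. Pairs with a missing trait or predictor are
#' dropped marker-wise. A constant predictor yields statistic 0, p = 1 and
#' a flag. For a binary predictor this is algebraically the two-sample
#' equal-variance t-test.
#'
#' @param trait numeric response vector.
#' @param predictor numeric vector of the same length.
#' @return one-row data frame `slope`, `t`, `p`, `n`, `flag`.
#' @export
qassoc <- function(trait, predictor) {
  stopifnot(length(trait) == length(predictor))
  res <- ols_scan(trait, matrix(predictor, ncol = 1L))
  data.frame(slope = res$slope, t = res$t, p = res$p, n = res$n,
             flag = res$flag)
}

# vectorised marker-wise OLS: Y response (length n), X n x m predictor
# matrix with NAs; returns per-column slope, t, p, n, flag
ols_scan <- function(Y, X) {
  M <- !is.na(X) & !is.na(Y)
  Xz <- X; Xz[!M] <- 0
  Yz <- Y; Yz[is.na(Yz)] <- 0
  n <- colSums(M)
  Sx <- colSums(Xz)
  Sy <- as.vector(crossprod(M, Yz))
  Sxx <- colSums(Xz^2)
  Syy <- as.vector(crossprod(M, Yz^2))
  Sxy <- as.vector(crossprod(Xz, Yz))
  vx <- Sxx - Sx^2 / n
  vy <- Syy - Sy^2 / n
  cxy <- Sxy - Sx * Sy / n
  const <- !is.na(vx) & (vx <= 1e-12 * pmax(Sxx, 1))
  low_n <- n < 3L
  vx[const | low_n] <- NA
  slope <- cxy / vx
  ssr <- pmax(vy - cxy^2 / vx, 0)
  df <- n - 2L
  se <- sqrt(ssr / df / vx)
  t <- slope / se
  zero_se <- !is.na(se) & se == 0
  t[zero_se] <- sign(slope[zero_se]) * Inf
  t[zero_se & slope == 0] <- 0          # constant trait: no association
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  slope[const] <- 0; t[const] <- 0; p[const] <- 1
  slope[low_n] <- NA; t[low_n] <- NA; p[low_n] <- NA
  list(slope = slope, t = t, p = p, n = as.integer(n),
       flag = ifelse(low_n, "too_few", ifelse(const, "constant", "ok")))
}

#' Empirical permutation p-value for one marker
#'
#' Shuffles the predictor labels across individuals and recomputes the
#' association statistic; the empirical p-value is
#' `(1 + #\{permuted |t| >= observed |t|\}) / (n_perm + 1)` (add-one
#' correction, so p is never 0 and never below `1/(n_perm+1)`). With
#' `exact = TRUE` all `n!` label permutations are enumerated instead and
#' the p-value is the exact fraction (the identity permutation counts, so
#' p >= 1/n!).
#'
#' @param trait,predictor as in [qassoc()] (complete cases are used).
#' @param n_perm number of random permutations.
#' @param seed optional seed for the permutation stream.
#' @param exact enumerate all permutations (only feasible for small n).
#' @return empirical p-value.
#' @export
permute_p <- function(trait, predictor, n_perm = 999L, seed = NULL,
                      exact = FALSE) {
  ok <- !is.na(trait) & !is.na(predictor)
  y <- trait[ok]; x <- predictor[ok]
  obs <- abs(qassoc(y, x)$t)
  eps <- 1e-9
  if (exact) {
    perms <- all_permutations(length(x))
    ts <- apply(perms, 1L, function(p) abs(qassoc(y, x[p])$t))
    return(sum(ts >= obs - eps) / nrow(perms))
  }
  stopifnot(n_perm >= 1L)
  if (!is.null(seed)) set.seed(seed)
  cnt <- 0L
  for (r in seq_len(n_perm)) {
    tp <- abs(qassoc(y, sample(x))$t)
    if (!is.na(tp) && tp >= obs - eps) cnt <- cnt + 1L
  }
  (1 + cnt) / (n_perm + 1)
}

# all permutations of 1..n as a n! x n matrix (recursive; small n only)
all_permutations <- function(n) {
  if (n > 8L) stop("exact enumeration limited to n <= 8")
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

#' Genome scan: association of a trait with transmitted haplotypes
#'
#' Runs the single-marker OLS test at every informative marker of a
#' transmission matrix (predictor: indicator of transmitting haplotype 2)
#' and attaches pointwise empirical permutation p-values. Permutations
#' shuffle the phenotype across individuals, which induces the same
#' permutation distribution as shuffling each marker's predictor, and lets
#' all markers share one set of permutations (computed as one matrix
#' product per scan).
#'
#' @param pheno phenotype data frame (`individual`, `trait`).
#' @param tmx a `transmission_matrix` (or a plain predictor matrix
#'   individuals x markers with a `markers` attribute-free data frame via
#'   `markers=`).
#' @param n_perm permutations for the empirical p (default 999; the
#'   smallest attainable p is then 0.001).
#' @param seed seed for the permutation stream.
#' @param markers optional marker metadata when `tmx` is a plain matrix.
#' @return data frame `marker`, `lg`, `bp`, `parent`, `slope`, `t`,
#'   `p_asym`, `p_perm`, `n`, `flag`.
#' @export
assoc_scan <- function(pheno, tmx, n_perm = 999L, seed = NULL,
                       markers = NULL) {
  if (inherits(tmx, "transmission_matrix")) {
    X <- t(tmx$tm) - 1     # individuals x markers, 0/1 indicator
    markers <- tmx$markers
    parent <- tmx$parent
  } else {
    X <- tmx
    parent <- NA_character_
    if (is.null(markers)) stop("markers metadata required for a plain matrix")
  }
  ids <- intersect(pheno$individual, rownames(X))
  y <- pheno$trait[match(ids, pheno$individual)]
  keep <- !is.na(y)
  ids <- ids[keep]; y <- y[keep]
  X <- X[ids, , drop = FALSE]
  obs <- ols_scan(y, X)
  res <- data.frame(marker = markers$marker, lg = markers$lg,
                    bp = markers$bp, parent = parent,
                    slope = obs$slope, t = obs$t, p_asym = obs$p,
                    p_perm = NA_real_, n = obs$n, flag = obs$flag,
                    stringsAsFactors = FALSE)
  if (n_perm >= 1L) {
    if (!is.null(seed)) set.seed(seed)
    res$p_perm <- perm_scan_p(y, X, abs(obs$t), n_perm)
  }
  res
}

# empirical p for all markers at once: permute the phenotype, recompute all
# t statistics by matrix products
perm_scan_p <- function(y, X, obs_abs_t, n_perm) {
  n_ind <- length(y)
  M <- !is.na(X)
  Xz <- X; Xz[!M] <- 0
  n <- colSums(M)
  Sx <- colSums(Xz)
  Sxx <- colSums(Xz^2)
  vx <- Sxx - Sx^2 / n
  df <- n - 2L
  Yp <- vapply(seq_len(n_perm), function(r) y[sample.int(n_ind)],
               numeric(n_ind))
  SY <- crossprod(M, Yp)        # m x n_perm
  SYY <- crossprod(M, Yp^2)
  SXY <- crossprod(Xz, Yp)
  vy <- SYY - SY^2 / n
  cxy <- SXY - Sx * SY / n
  tstat <- matrix(NA_real_, nrow(SY), n_perm)
  ok <- which(vx > 1e-12 * pmax(Sxx, 1) & df > 0)
  if (length(ok)) {
    ssr <- pmax(vy[ok, , drop = FALSE] -
                  cxy[ok, , drop = FALSE]^2 / vx[ok], 0)
    se2 <- ssr / df[ok] / vx[ok]
    tsub <- abs(cxy[ok, , drop = FALSE] / vx[ok]) / sqrt(se2)
    tsub[se2 == 0] <- Inf
    tstat[ok, ] <- tsub
  }
  eps <- 1e-9
  cnt <- rowSums(tstat >= (obs_abs_t - eps), na.rm = TRUE)
  p <- (1 + cnt) / (n_perm + 1)
  p[is.na(obs_abs_t)] <- NA_real_
  p
}

#' Define QTL regions from significant markers
#'
#' Markers with p at or below `threshold` are merged into regions: a run of
#' significant markers on the same linkage group is extended while
#' consecutive significant markers are at most `max_gap_bp` apart. Region
#' bounds are the min/max bp of member markers. An empty significant set
#' yields an empty region table.
#'
#' @param assoc association results (from [assoc_scan()] or rbind of
#'   several scans).
#' @param threshold p-value cutoff defining significance (default 0.001).
#' @param max_gap_bp maximum gap between consecutive significant markers in
#'   one region (default 1 Mb).
#' @param p_col which p-value column to threshold (default `"p_perm"`).
#' @return data frame of class `qtl_regions`: `region_id`, `lg`,
#'   `start_bp`, `end_bp`, `n_snps`, `min_p`, `markers`
#'   (comma-separated member ids).
#' @export
define_regions <- function(assoc, threshold = 0.001, max_gap_bp = 1e6,
                           p_col = "p_perm") {
  p <- assoc[[p_col]]
  sig <- assoc[!is.na(p) & p <= threshold, , drop = FALSE]
  empty <- data.frame(region_id = character(), lg = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), min_p = numeric(),
                      markers = character(), stringsAsFactors = FALSE)
  class(empty) <- c("qtl_regions", "data.frame")
  if (!nrow(sig)) return(empty)
  # a marker significant in both parental scans counts once
  sig <- sig[!duplicated(sig$marker), , drop = FALSE]
  sig <- sig[order(sig$lg, sig$bp), , drop = FALSE]
  new_grp <- c(TRUE, sig$lg[-1] != sig$lg[-nrow(sig)] |
                 diff(sig$bp) > max_gap_bp)
  grp <- cumsum(new_grp)
  out <- do.call(rbind, lapply(split(sig, grp), function(s) {
    data.frame(lg = s$lg[1L], start_bp = min(s$bp), end_bp = max(s$bp),
               n_snps = nrow(s), min_p = min(s[[p_col]]),
               markers = paste(s$marker, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$lg, out$start_bp), , drop = FALSE]
  out$region_id <- sprintf("%s:%d-%d", out$lg, out$start_bp, out$end_bp)
  rownames(out) <- NULL
  out <- out[, c("region_id", "lg", "start_bp", "end_bp", "n_snps",
                 "min_p", "markers")]
  class(out) <- c("qtl_regions", "data.frame")
  out
}
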