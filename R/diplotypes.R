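DIPLO_STATES <- c("M1P1", "M1P2", "M2P1", "M2P2", "RECOMBINANT", "UNKNOWN")

# summarise one parent's transmissions over region markers for every
# individual: the unique observed haplotype label, or RECOMBINANT (>1
# label) or UNKNOWN (informative fraction below min_info_frac). Labels are
# smoothed lg-wide first (runs shorter than min_run masked), consistent
# with breakpoint calling, so an isolated miscall is not read as a
# double recombinant.
region_parent_hap <- function(tmx, region, min_info_frac, min_run = 3L) {
  if (min_run > 1L) {
    lg_rows <- which(tmx$markers$lg == region$lg)
    sm <- apply(tmx$tm[lg_rows, , drop = FALSE], 2L, mask_short_runs,
                min_run = min_run)
    tmx$tm[lg_rows, ] <- sm
  }
  idx <- which(tmx$markers$lg == region$lg &
                 tmx$markers$bp >= region$start_bp &
                 tmx$markers$bp <= region$end_bp)
  n_ind <- ncol(tmx$tm)
  if (!length(idx)) {
    warning("region ", region$region_id %||% region$lg,
            " has no informative markers for the ", tmx$parent, " parent")
    return(list(hap = rep(NA_integer_, n_ind),
                state = rep("UNKNOWN", n_ind),
                frac = rep(0, n_ind)))
  }
  sub <- tmx$tm[idx, , drop = FALSE]
  frac <- colSums(!is.na(sub)) / length(idx)
  hap <- rep(NA_integer_, n_ind)
  state <- rep("UNKNOWN", n_ind)
  for (i in seq_len(n_ind)) {
    u <- unique(sub[!is.na(sub[, i]), i])
    if (length(u) > 1L) {
      state[i] <- "RECOMBINANT"
    } else if (frac[i] >= min_info_frac && length(u) == 1L) {
      state[i] <- "CALLED"; hap[i] <- u
    }
  }
  list(hap = hap, state = state, frac = frac)
}

#' Call region-level diplotypes
#'
#' For each individual and each parent, the haplotype labels transmitted at
#' the region's informative markers are collected. Observing both labels
#' from one parent is evidence of a recombination event inside the region
#' (`RECOMBINANT`); too few non-missing labels gives `UNKNOWN`; otherwise
#' the parent contributes its unique observed haplotype and the diplotype
#' is the maternal/paternal pair, one of `M1P1`, `M1P2`, `M2P1`, `M2P2`
#' (rendered with user prefixes, e.g. `TA2KP1`).
#'
#' @param tm_mother,tm_father `transmission_matrix` objects for the two
#'   parents.
#' @param region one region (single row of a `qtl_regions` table, or any
#'   list with `lg`, `start_bp`, `end_bp`).
#' @param min_info_frac minimum fraction of a parent's region markers that
#'   must be non-missing to call that parent's haplotype (default 0.5).
#' @param prefixes length-2 character: maternal and paternal label
#'   prefixes (default `c("M", "P")`; use e.g. `c("TA", "KP")` to render
#'   the conventional cultivar-style names).
#' @param min_run smoothing window shared with [detect_breakpoints()]:
#'   haplotype-label runs shorter than this are masked before the region is
#'   summarised, so isolated miscalls do not fake a double recombination
#'   (default 3; use 1 for error-free data).
#' @return data frame `individual`, `region_id`, `call`, `maternal_hap`,
#'   `paternal_hap`, `maternal_frac`, `paternal_frac`.
#' @export
call_region_diplotype <- function(tm_mother, tm_father, region,
                                  min_info_frac = 0.5,
                                  prefixes = c("M", "P"), min_run = 3L) {
  stopifnot(inherits(tm_mother, "transmission_matrix"),
            inherits(tm_father, "transmission_matrix"),
            length(prefixes) == 2L, min_info_frac >= 0, min_info_frac <= 1)
  ids <- colnames(tm_mother$tm)
  stopifnot(identical(ids, colnames(tm_father$tm)))
  m <- region_parent_hap(tm_mother, region, min_info_frac, min_run)
  p <- region_parent_hap(tm_father, region, min_info_frac, min_run)
  call <- ifelse(m$state == "RECOMBINANT" | p$state == "RECOMBINANT",
                 "RECOMBINANT",
          ifelse(m$state == "UNKNOWN" | p$state == "UNKNOWN", "UNKNOWN",
                 paste0(prefixes[1L], m$hap, prefixes[2L], p$hap)))
  data.frame(individual = ids,
             region_id = region$region_id %||%
               sprintf("%s:%s-%s", region$lg, region$start_bp, region$end_bp),
             call = call,
             maternal_hap = m$hap, paternal_hap = p$hap,
             maternal_frac = m$frac, paternal_frac = p$frac,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Test diplotype effects on a quantitative trait (ANOVA + Tukey HSD)
#'
#' One-way fixed-effects ANOVA of the trait on the diplotype group, after
#' excluding `RECOMBINANT` and `UNKNOWN` individuals (recombinants are
#' reported but never enter the test), followed by Tukey's honest
#' significant difference post hoc comparison of all group pairs via the
#' studentized range distribution. Requires at least two groups with at
#' least two members each; otherwise the report carries `NULL` test fields
#' and a reason.
#'
#' @param calls output of [call_region_diplotype()].
#' @param pheno phenotype data frame (`individual`, `trait`).
#' @param welch use Welch's heteroscedastic one-way test for the global
#'   comparison instead of the classical ANOVA F (Tukey table still based
#'   on the homoscedastic fit).
#' @return an object of class `diplotype_effect_report`: list with
#'   `groups` (n, mean, sd per diplotype), `anova` (`F`, `df1`, `df2`,
#'   `p`), `tukey` (pair, diff, lwr, upr, p_adj), `n_recombinant`,
#'   `n_unknown`, `reason` (non-`NULL` when the test could not run).
#' @export
diplotype_effect_test <- function(calls, pheno, welch = FALSE) {
  df <- merge(calls, pheno, by = "individual")
  n_rec <- sum(df$call == "RECOMBINANT")
  n_unk <- sum(df$call == "UNKNOWN")
  use <- df[!df$call %in% c("RECOMBINANT", "UNKNOWN") & !is.na(df$trait), ]
  grp_stats <- if (nrow(use)) {
    agg <- split(use$trait, use$call)
    data.frame(diplotype = names(agg),
               n = vapply(agg, length, 0L),
               mean = vapply(agg, mean, 0),
               sd = vapply(agg, stats::sd, 0),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(diplotype = character(), n = integer(), mean = numeric(),
               sd = numeric())
  }
  rep0 <- structure(list(groups = grp_stats, anova = NULL, tukey = NULL,
                         n_recombinant = n_rec, n_unknown = n_unk,
                         method = if (welch) "welch" else "anova",
                         reason = NULL),
                    class = "diplotype_effect_report")
  big <- grp_stats$n >= 2L
  if (sum(big) < 2L) {
    rep0$reason <- "fewer than 2 diplotype groups with >= 2 members"
    return(rep0)
  }
  use$call <- factor(use$call)
  fit <- stats::aov(trait ~ call, data = use)
  # a trait with no variance at all gives 0/0 mean squares; report it as
  # "no signal" (F = 0, p = 1) rather than NaN
  degenerate <- stats::var(use$trait) < .Machine$double.eps
  if (welch) {
    w <- suppressWarnings(
      stats::oneway.test(trait ~ call, data = use, var.equal = FALSE))
    rep0$anova <- list(F = unname(w$statistic), df1 = unname(w$parameter[1L]),
                       df2 = unname(w$parameter[2L]), p = w$p.value)
  } else {
    an <- suppressWarnings(stats::anova(fit))
    rep0$anova <- list(F = an$`F value`[1L], df1 = an$Df[1L],
                       df2 = an$Df[2L], p = an$`Pr(>F)`[1L])
  }
  if (degenerate || !is.finite(rep0$anova$F)) {
    rep0$anova$F <- if (degenerate) 0 else rep0$anova$F
    rep0$anova$p <- if (degenerate) 1 else rep0$anova$p
  }
  tk <- suppressWarnings(stats::TukeyHSD(fit))$call
  rep0$tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                           lwr = tk[, "lwr"], upr = tk[, "upr"],
                           p_adj = tk[, "p adj"], row.names = NULL,
                           stringsAsFactors = FALSE)
  if (degenerate) rep0$tukey$p_adj <- 1
  rep0
}

#' @export
print.diplotype_effect_report <- function(x, ...) {
  cat("Diplotype effect report\n")
  print(x$groups)
  cat(sprintf("excluded: %d recombinant, %d unknown\n",
              x$n_recombinant, x$n_unknown))
  if (!is.null(x$reason)) {
    cat("test not run:", x$reason, "\n")
  } else {
    cat(sprintf("%s: F(%d, %d) = %.3f, p = %.4g\n",
                toupper(x$method), x$anova$df1, x$anova$df2, x$anova$F,
                x$anova$p))
    print(x$tukey, digits = 4)
  }
  invisible(x)
}

#' Diplotype agreement of a reduced SNP panel
#'
#' Re-calls region diplotypes using only a panel of k markers and reports
#' the agreement rate against the full-region calls — the quantity that
#' matters when designing a small marker panel for seedling-stage
#' marker-assisted selection.
#'
#' @param tm_mother,tm_father `transmission_matrix` objects.
#' @param region region as in [call_region_diplotype()].
#' @param panel character vector of marker ids; must be a non-empty subset
#'   of the region's informative markers (of either parent).
#' @param min_info_frac,prefixes,min_run passed to
#'   [call_region_diplotype()].
#' @return list with `agreement` (fraction of individuals whose panel call
#'   equals the full-region call), `calls_panel`, `calls_full`.
#' @export
predict_diplotype_from_snp_panel <- function(tm_mother, tm_father, region,
                                             panel, min_info_frac = 0.5,
                                             prefixes = c("M", "P"),
                                             min_run = 3L) {
  if (!length(panel)) stop("panel must contain at least one marker")
  region_markers <- c(
    with(tm_mother$markers, marker[lg == region$lg & bp >= region$start_bp &
                                     bp <= region$end_bp]),
    with(tm_father$markers, marker[lg == region$lg & bp >= region$start_bp &
                                     bp <= region$end_bp]))
  if (!all(panel %in% region_markers)) {
    stop("panel must be a subset of the region's informative markers")
  }
  sub_tm <- function(tmx) {
    keep <- tmx$markers$marker %in% panel |
      !(tmx$markers$lg == region$lg & tmx$markers$bp >= region$start_bp &
          tmx$markers$bp <= region$end_bp)
    structure(list(markers = tmx$markers[keep, , drop = FALSE],
                   tm = tmx$tm[keep, , drop = FALSE], parent = tmx$parent),
              class = "transmission_matrix")
  }
  full <- call_region_diplotype(tm_mother, tm_father, region,
                                min_info_frac, prefixes, min_run)
  red <- suppressWarnings(
    call_region_diplotype(sub_tm(tm_mother), sub_tm(tm_father), region,
                          min_info_frac, prefixes, min_run))
  list(agreement = mean(red$call == full$call),
       calls_panel = red, calls_full = full)
}

#' Evenly spaced marker panel within a region
#'
#' @param tmx a `transmission_matrix`.
#' @param region region (`lg`, `start_bp`, `end_bp`).
#' @param k panel size.
#' @return character vector of up to `k` marker ids.
#' @export
evenly_spaced_panel <- function(tmx, region, k) {
  mk <- tmx$markers
  idx <- which(mk$lg == region$lg & mk$bp >= region$start_bp &
                 mk$bp <= region$end_bp)
  if (!length(idx)) return(character())
  take <- unique(round(seq(1L, length(idx), length.out = min(k, length(idx)))))
  mk$marker[idx[take]]
}
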