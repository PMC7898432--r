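#' Configuration for a synthetic pseudo-testcross population
#'
#' Describes an F1 population of two heterozygous outcrossing parents
#' genotyped at mapped SNPs, in the style of a skim-sequenced mapping
#' population. Defaults mirror a mango-sized design: 20 linkage groups,
#' ~16.4 Mb per pseudomolecule, 104 progeny, and low-coverage genotyping
#' noise (miscalls and missing calls).
#'
#' Marker informativeness classes follow the pseudo-testcross criterion:
#' a maternal-informative marker is heterozygous in the mother and
#' homozygous in the father (and symmetrically for paternal); the remainder
#' are both-het or uninformative.
#'
#' @param n_lg number of linkage groups.
#' @param markers_per_lg SNP markers per linkage group.
#' @param lg_length_bp physical length of each linkage group (bp).
#' @param lg_length_cM map length of each linkage group (centiMorgans).
#' @param n_progeny number of F1 progeny.
#' @param frac_maternal_informative,frac_paternal_informative,frac_both_het
#'   expected marker-class proportions; must each lie in \[0,1\] and sum to
#'   at most 1 (the remainder is uninformative).
#' @param missing_rate per-call probability that a progeny genotype is
#'   missing (applied after genotyping error).
#' @param genotype_error_rate per-call probability that one allele of a
#'   progeny genotype is flipped to a random other base.
#' @param seed master seed; all child streams are derived from it.
#' @return an object of class `sim_config`.
#' @seealso [simulate_population()]
#' @export
sim_config <- function(n_lg = 20L, markers_per_lg = 200L,
                       lg_length_bp = 16400000, lg_length_cM = 100,
                       n_progeny = 104L,
                       frac_maternal_informative = 0.4,
                       frac_paternal_informative = 0.4,
                       frac_both_het = 0.1,
                       missing_rate = 0.1,
                       genotype_error_rate = 0.01,
                       seed = 1L) {
  counts <- c(n_lg = n_lg, markers_per_lg = markers_per_lg,
              n_progeny = n_progeny)
  if (any(counts < 1)) stop("counts must be >= 1")
  props <- c(frac_maternal_informative, frac_paternal_informative,
             frac_both_het, missing_rate, genotype_error_rate)
  if (any(props < 0) || any(props > 1)) {
    stop("proportions must lie in [0, 1]")
  }
  if (frac_maternal_informative + frac_paternal_informative +
      frac_both_het > 1 + 1e-12) {
    stop("marker class fractions must sum to at most 1")
  }
  if (lg_length_bp < markers_per_lg) stop("lg_length_bp too small for marker count")
  if (lg_length_cM < 0) stop("lg_length_cM must be >= 0")
  structure(list(
    n_lg = as.integer(n_lg), markers_per_lg = as.integer(markers_per_lg),
    lg_length_bp = lg_length_bp, lg_length_cM = lg_length_cM,
    n_progeny = as.integer(n_progeny),
    frac_maternal_informative = frac_maternal_informative,
    frac_paternal_informative = frac_paternal_informative,
    frac_both_het = frac_both_het,
    missing_rate = missing_rate,
    genotype_error_rate = genotype_error_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

BASES <- c("A", "C", "G", "T")
MARKER_CLASSES <- c("MATERNAL_INFORMATIVE", "PATERNAL_INFORMATIVE",
                    "BOTH_HET", "UNINFORMATIVE", "UNUSABLE")

lg_name <- function(i) sprintf("LG%02d", i)

#' Simulate the two parental genomes
#'
#' Draws marker positions and phased parental allele pairs. The ordered
#' allele pair of each parent defines the true haplotype phase (`hap1`,
#' `hap2`); the assigned informativeness class of every marker is recorded
#' so recovery can be checked downstream.
#'
#' @param config a [sim_config()].
#' @return an object of class `parent_genomes`: a list with `markers`
#'   (data frame: marker, lg, bp, cM, class), `p1` and `p2` (markers x 2
#'   character matrices of phased alleles, mother and father), and the
#'   config.
#' @export
simulate_parents <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "parents"))
  fr <- c(config$frac_maternal_informative, config$frac_paternal_informative,
          config$frac_both_het)
  fr <- c(fr, max(0, 1 - sum(fr)))
  mk <- vector("list", config$n_lg)
  for (i in seq_len(config$n_lg)) {
    bp <- sort(sample.int(config$lg_length_bp, config$markers_per_lg))
    cls <- sample(MARKER_CLASSES[1:4], config$markers_per_lg,
                  replace = TRUE, prob = fr)
    mk[[i]] <- data.frame(
      marker = sprintf("%s_%d", lg_name(i), bp),
      lg = lg_name(i), bp = bp,
      cM = bp / config$lg_length_bp * config$lg_length_cM,
      class = cls, stringsAsFactors = FALSE)
  }
  markers <- do.call(rbind, mk)
  m <- nrow(markers)
  # two distinct alleles per marker; class decides which parent is het
  ref <- character(m); alt <- character(m)
  for (j in seq_len(m)) {
    ab <- sample(BASES, 2L)
    ref[j] <- ab[1L]; alt[j] <- ab[2L]
  }
  p1 <- matrix(NA_character_, m, 2L)
  p2 <- matrix(NA_character_, m, 2L)
  for (j in seq_len(m)) {
    het <- sample(c(ref[j], alt[j]))          # random phase orientation
    hom <- rep(sample(c(ref[j], alt[j]), 1L), 2L)
    switch(markers$class[j],
      MATERNAL_INFORMATIVE = { p1[j, ] <- het; p2[j, ] <- hom },
      PATERNAL_INFORMATIVE = { p1[j, ] <- hom; p2[j, ] <- het },
      BOTH_HET = { p1[j, ] <- sample(c(ref[j], alt[j]))
                   p2[j, ] <- sample(c(ref[j], alt[j])) },
      UNINFORMATIVE = { p1[j, ] <- rep(sample(c(ref[j], alt[j]), 1L), 2L)
                        p2[j, ] <- rep(sample(c(ref[j], alt[j]), 1L), 2L) })
  }
  structure(list(markers = markers, p1 = p1, p2 = p2, config = config),
            class = "parent_genomes")
}

# Core meiosis draw on one linkage group: Poisson crossover count with mean
# lg_length_cM/100 (Haldane: no interference), positions uniform on the map.
# The cM axis is taken proportional to bp (uniform recombination rate), so
# positions are drawn uniformly on (0, lg_length_bp).
meiosis_draw <- function(lg_length_bp, lg_length_cM) {
  n_xo <- stats::rpois(1L, lg_length_cM / 100)
  xo <- sort(stats::runif(n_xo, 0, lg_length_bp))
  start <- sample(1:2, 1L)
  list(xo_bp = xo, start = start)
}

# transmitted haplotype label (1/2) at positions bp for a gamete
gamete_labels <- function(bp, xo_bp, start) {
  parity <- findInterval(bp, xo_bp) %% 2L
  ifelse(parity == 0L, start, 3L - start)
}

#' Simulate one meiosis for a parent on one linkage group
#'
#' Crossover count is Poisson with mean `lg_length_cM / 100` (Haldane model,
#' no interference); crossover positions are uniform on the map; the gamete
#' starts from a random haplotype and alternates at each crossover.
#'
#' @param parents a `parent_genomes` object.
#' @param parent `"mother"` or `"father"`.
#' @param lg linkage group id (e.g. `"LG01"`).
#' @return list with `alleles` (transmitted allele at each marker of the
#'   lg), `labels` (transmitted haplotype 1/2), `xo_bp` (crossover
#'   positions), `start` (haplotype at position 0).
#' @export
simulate_meiosis <- function(parents, parent = c("mother", "father"), lg) {
  stopifnot(inherits(parents, "parent_genomes"))
  parent <- match.arg(parent)
  idx <- which(parents$markers$lg == lg)
  if (!length(idx)) stop("unknown linkage group: ", lg)
  cfg <- parents$config
  g <- meiosis_draw(cfg$lg_length_bp, cfg$lg_length_cM)
  lab <- gamete_labels(parents$markers$bp[idx], g$xo_bp, g$start)
  hap <- if (parent == "mother") parents$p1 else parents$p2
  alleles <- hap[cbind(idx, lab)]
  list(alleles = alleles, labels = lab, xo_bp = g$xo_bp, start = g$start)
}

#' Simulate F1 progeny genotypes and the truth set
#'
#' Each progeny genotype is the union of one maternal and one paternal
#' gamete. Genotyping error flips one allele of a call to a random other
#' base with probability `genotype_error_rate`; missingness is applied
#' afterwards at `missing_rate`. The returned truth set records, per
#' progeny, parent and linkage group, the gamete's starting haplotype and
#' crossover positions, plus the implied transmission label at every
#' marker, so inference can be scored exactly.
#'
#' @param parents a `parent_genomes` object.
#' @param config the same [sim_config()] used for the parents.
#' @return list with `geno` (a `geno_matrix`, parents included as columns)
#'   and `truth` (a `truth_set`).
#' @export
simulate_progeny <- function(parents, config = parents$config) {
  stopifnot(inherits(parents, "parent_genomes"))
  set.seed(derive_seed(config$seed, "progeny"))
  mk <- parents$markers
  m <- nrow(mk); n <- config$n_progeny
  ids <- sprintf("H%03d", seq_len(n))
  lgs <- unique(mk$lg)

  tm_m <- matrix(NA_integer_, m, n, dimnames = list(mk$marker, ids))
  tm_p <- matrix(NA_integer_, m, n, dimnames = list(mk$marker, ids))
  a_m <- matrix(NA_character_, m, n)
  a_p <- matrix(NA_character_, m, n)
  xo_rec <- list(); starts <- list(); k <- 0L
  for (i in seq_len(n)) {
    for (lg in lgs) {
      idx <- which(mk$lg == lg)
      for (par in c("mother", "father")) {
        g <- meiosis_draw(config$lg_length_bp, config$lg_length_cM)
        lab <- gamete_labels(mk$bp[idx], g$xo_bp, g$start)
        hap <- if (par == "mother") parents$p1 else parents$p2
        if (par == "mother") {
          tm_m[idx, i] <- lab; a_m[idx, i] <- hap[cbind(idx, lab)]
        } else {
          tm_p[idx, i] <- lab; a_p[idx, i] <- hap[cbind(idx, lab)]
        }
        k <- k + 1L
        starts[[k]] <- data.frame(individual = ids[i], parent = par, lg = lg,
                                  start = g$start, stringsAsFactors = FALSE)
        if (length(g$xo_bp)) {
          xo_rec[[k]] <- data.frame(individual = ids[i], parent = par,
                                    lg = lg, xo_bp = g$xo_bp,
                                    stringsAsFactors = FALSE)
        }
      }
    }
  }
  xo <- if (length(xo_rec)) do.call(rbind, xo_rec) else
    data.frame(individual = character(), parent = character(),
               lg = character(), xo_bp = numeric())
  starts <- do.call(rbind, starts)

  geno <- matrix(join_geno(a_m, a_p), m, n, dimnames = list(mk$marker, ids))
  # genotyping error: flip one allele of the call to a random other base
  err <- which(matrix(stats::runif(m * n) < config$genotype_error_rate, m, n))
  if (length(err)) {
    al <- split_geno(geno[err])
    which_al <- sample(1:2, length(err), replace = TRUE)
    for (j in seq_along(err)) {
      old <- al[j, which_al[j]]
      if (is.na(old)) next
      al[j, which_al[j]] <- sample(setdiff(BASES, old), 1L)
    }
    geno[err] <- join_geno(al[, 1L], al[, 2L])
  }
  geno[matrix(stats::runif(m * n) < config$missing_rate, m, n)] <- NA

  # parents observed without error (treated as known, deeply genotyped)
  gm_mother <- join_geno(parents$p1[, 1L], parents$p1[, 2L])
  gm_father <- join_geno(parents$p2[, 1L], parents$p2[, 2L])
  full <- cbind(TA = gm_mother, KP = gm_father, geno)
  rownames(full) <- mk$marker

  gm <- geno_matrix(markers = mk[, c("marker", "lg", "bp")], geno = full,
                    mother = "TA", father = "KP")
  truth <- structure(list(
    tm_mother = tm_m, tm_father = tm_p, xo = xo, starts = starts,
    markers = mk, config = config), class = "truth_set")
  list(geno = gm, truth = truth)
}

#' True transmitted haplotype at an arbitrary position
#'
#' @param truth a `truth_set`.
#' @param individual,parent,lg,bp gamete coordinates; `parent` is
#'   `"mother"` or `"father"`.
#' @return haplotype label 1 or 2.
#' @export
true_hap_at <- function(truth, individual, parent, lg, bp) {
  st <- truth$starts
  s <- st$start[st$individual == individual & st$parent == parent & st$lg == lg]
  if (!length(s)) stop("no gamete recorded for ", individual, "/", parent, "/", lg)
  xo <- truth$xo
  xos <- xo$xo_bp[xo$individual == individual & xo$parent == parent & xo$lg == lg]
  gamete_labels(bp, sort(xos), s)
}

#' Specify a QTL with diplotype-specific effects
#'
#' Effects are additive shifts (in trait units, e.g. grams) applied
#' according to the true diplotype an individual carries at the QTL
#' position, one value per diplotype class `M1P1`, `M1P2`, `M2P1`, `M2P2`
#' (maternal haplotype x paternal haplotype).
#'
#' @param lg linkage group id.
#' @param position_bp QTL position (bp).
#' @param effects named numeric of length 4; names must be exactly the four
#'   diplotype classes.
#' @return an object of class `qtl_spec`.
#' @export
qtl_spec <- function(lg, position_bp, effects) {
  need <- c("M1P1", "M1P2", "M2P1", "M2P2")
  if (!setequal(names(effects), need) || length(effects) != 4L) {
    stop("effects must be named exactly ", paste(need, collapse = ", "))
  }
  structure(list(lg = lg, position_bp = position_bp,
                 effects = effects[need]), class = "qtl_spec")
}

#' Default QTL architecture emulating the mango fruit-weight study
#'
#' Two QTLs with diplotype effects chosen so that group means reproduce the
#' reported diplotype means: on the LG4-like region the lowest group sits
#' ~71 g below and the highest ~99 g above baseline (329 g vs 499 g around
#' ~400 g), and on the LG7-like region the maternal haplotype drives a
#' smaller split (means ~352/359/450/468 g).
#'
#' @param lg_length_bp linkage group length, to place QTLs mid-arm.
#' @return list of two [qtl_spec()] objects.
#' @export
default_qtls <- function(lg_length_bp = 16400000) {
  list(
    qtl_spec("LG04", round(lg_length_bp * 0.51),
             c(M1P1 = -50, M1P2 = 0, M2P1 = -71, M2P2 = 99)),
    qtl_spec("LG07", round(lg_length_bp * 0.24),
             c(M1P1 = -48, M1P2 = -41, M2P1 = 50, M2P2 = 68))
  )
}

#' True diplotype of every progeny at a QTL position
#'
#' @param truth a `truth_set`.
#' @param qtl a [qtl_spec()].
#' @return named character vector (`"M1P1"` ... per individual).
#' @export
true_diplotypes <- function(truth, qtl) {
  ids <- colnames(truth$tm_mother)
  out <- vapply(ids, function(i) {
    hm <- true_hap_at(truth, i, "mother", qtl$lg, qtl$position_bp)
    hp <- true_hap_at(truth, i, "father", qtl$lg, qtl$position_bp)
    sprintf("M%dP%d", hm, hp)
  }, "")
  out
}

#' Simulate a quantitative trait from QTL diplotypes
#'
#' `trait_i = baseline + sum_q effects_q[diplotype_i(q)] + N(0, noise_sd)`.
#' The diplotype at each QTL is the pair of truly transmitted haplotypes at
#' the QTL position itself, so individuals recombinant across the
#' surrounding region still receive a well-defined effect.
#'
#' @param truth a `truth_set`.
#' @param qtls list of [qtl_spec()] objects (those on simulated linkage
#'   groups; others are ignored with a warning).
#' @param baseline trait baseline (g).
#' @param noise_sd residual standard deviation (g).
#' @param seed seed for the noise stream (defaults to a stream derived from
#'   the simulation master seed).
#' @return data frame with columns `individual`, `trait`.
#' @export
simulate_trait <- function(truth, qtls, baseline = 400, noise_sd = 80,
                           seed = derive_seed(truth$config$seed, "trait")) {
  stopifnot(inherits(truth, "truth_set"))
  if (inherits(qtls, "qtl_spec")) qtls <- list(qtls)
  set.seed(seed)
  ids <- colnames(truth$tm_mother)
  tot <- rep(baseline, length(ids))
  for (q in qtls) {
    if (!q$lg %in% truth$markers$lg) {
      warning("QTL on ", q$lg, " ignored: linkage group not simulated")
      next
    }
    d <- true_diplotypes(truth, q)
    tot <- tot + unname(q$effects[d])
  }
  data.frame(individual = ids,
             trait = tot + stats::rnorm(length(ids), 0, noise_sd),
             stringsAsFactors = FALSE)
}

#' Simulate a full pseudo-testcross population
#'
#' Convenience wrapper: parents, progeny genotypes, truth set and trait in
#' one call. Optional subsetting knobs emulate a study in which not every
#' individual was both phenotyped and genotyped.
#'
#' @param config a [sim_config()].
#' @param qtls list of [qtl_spec()] (default [default_qtls()]).
#' @param baseline,noise_sd trait model parameters (g).
#' @param n_phenotyped,n_genotyped optionally keep only the first k progeny
#'   in the phenotype table / genotype matrix.
#' @return list with `parents`, `geno`, `truth`, `pheno`, `qtls`, `config`.
#' @export
simulate_population <- function(config = sim_config(),
                                qtls = default_qtls(config$lg_length_bp),
                                baseline = 400, noise_sd = 80,
                                n_phenotyped = NULL, n_genotyped = NULL) {
  parents <- simulate_parents(config)
  pg <- simulate_progeny(parents, config)
  pheno <- simulate_trait(pg$truth, qtls, baseline, noise_sd)
  if (!is.null(n_phenotyped)) pheno <- pheno[seq_len(n_phenotyped), ]
  geno <- pg$geno
  if (!is.null(n_genotyped)) {
    keep <- c(geno$mother, geno$father,
              setdiff(geno$individuals, c(geno$mother, geno$father))[
                seq_len(n_genotyped)])
    geno <- geno_matrix(geno$markers, geno$geno[, keep, drop = FALSE],
                        geno$mother, geno$father)
  }
  list(parents = parents, geno = geno, truth = pg$truth, pheno = pheno,
       qtls = qtls, config = config)
}
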