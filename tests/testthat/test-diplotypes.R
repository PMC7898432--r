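# build a transmission_matrix from a label matrix on one lg
toy_tm <- function(lab, parent, bp = seq_len(nrow(lab)) * 1000) {
  ids <- colnames(lab) %||% sprintf("H%03d", seq_len(ncol(lab)))
  colnames(lab) <- ids
  structure(list(
    markers = data.frame(marker = sprintf("LG01_%d", bp), lg = "LG01",
                         bp = bp, hap1_allele = "A",
                         low_confidence = FALSE),
    tm = lab, parent = parent), class = "transmission_matrix")
}
reg1 <- list(region_id = "LG01:1000-5000", lg = "LG01",
             start_bp = 1000, end_bp = 5000)

test_that("region diplotype calls: pure, recombinant and unknown states", {
  lab_m <- matrix(c(2L, 2L, 2L, 2L, 2L,   # pure hap 2
                    1L, 1L, 2L, 2L, 2L,   # recombinant
                    NA, NA, NA, NA, NA),  # unknown
                  5, 3)
  lab_p <- matrix(2L, 5, 3)
  calls <- call_region_diplotype(toy_tm(lab_m, "maternal"),
                                 toy_tm(lab_p, "paternal"), reg1,
                                 prefixes = c("TA", "KP"), min_run = 1)
  expect_identical(calls$call, c("TA2KP2", "RECOMBINANT", "UNKNOWN"))
})

test_that("run smoothing keeps an isolated miscall from faking a recombinant", {
  lab_m <- matrix(c(1L, 1L, 1L, 2L, 1L, 1L, 1L, 1L, 1L, 1L), 10, 1)
  lab_p <- matrix(1L, 10, 1)
  reg <- list(region_id = "r", lg = "LG01", start_bp = 1000, end_bp = 10000)
  raw_call <- call_region_diplotype(toy_tm(lab_m, "maternal"),
                                    toy_tm(lab_p, "paternal"), reg,
                                    min_run = 1)
  smooth_call <- call_region_diplotype(toy_tm(lab_m, "maternal"),
                                       toy_tm(lab_p, "paternal"), reg,
                                       min_run = 3)
  expect_identical(raw_call$call, "RECOMBINANT")
  expect_identical(smooth_call$call, "M1P1")
})

test_that("exactly four non-degenerate diplotype classes exist", {
  lab_m <- matrix(rep(c(1L, 1L, 2L, 2L), each = 4), 4, 4)
  lab_p <- matrix(rep(c(1L, 2L, 1L, 2L), each = 4), 4, 4)
  calls <- call_region_diplotype(toy_tm(lab_m, "maternal"),
                                 toy_tm(lab_p, "paternal"), reg1)
  expect_setequal(calls$call, c("M1P1", "M1P2", "M2P1", "M2P2"))
})

test_that("a parent with no region markers yields UNKNOWN with a warning", {
  far <- list(region_id = "LG01:9e6-9.5e6", lg = "LG01",
              start_bp = 9e6, end_bp = 9.5e6)
  lab <- matrix(1L, 3, 2)
  expect_warning(expect_warning(
    calls <- call_region_diplotype(toy_tm(lab, "maternal"),
                                   toy_tm(lab, "paternal"), far),
    "no informative markers"), "no informative markers")
  expect_true(all(calls$call == "UNKNOWN"))
})

test_that("zero-error diplotype calls equal truth, recombinants counted exactly", {
  pop <- small_pop(seed = 23, n_lg = 1, markers_per_lg = 150,
                   error = 0, missing = 0)
  cl <- classify_markers(pop$geno)
  tmm <- phase_parent(raw_transmission(pop$geno, cl, "maternal"))
  tmp <- phase_parent(raw_transmission(pop$geno, cl, "paternal"))
  reg <- list(region_id = "r", lg = "LG01", start_bp = 6e6, end_bp = 9e6)
  calls <- call_region_diplotype(tmm, tmp, reg, min_run = 1)  # error-free data

  # truth: haplotypes at the region's informative markers
  truth_state <- vapply(calls$individual, function(i) {
    lab <- list()
    for (p in c("mother", "father")) {
      tru <- if (p == "mother") pop$truth$tm_mother else pop$truth$tm_father
      mk <- if (p == "mother") tmm$markers else tmp$markers
      rows <- mk$marker[mk$bp >= reg$start_bp & mk$bp <= reg$end_bp]
      u <- unique(tru[rows, i])
      if (length(u) > 1) return("RECOMBINANT")
      lab[[p]] <- u
    }
    sprintf("M%dP%d", lab$mother, lab$father)
  }, "")
  rec_true <- truth_state == "RECOMBINANT"
  expect_identical(calls$call == "RECOMBINANT", unname(rec_true))
  # pure calls equal truth up to a per-parent label switch
  relabel <- function(x, flip_m, flip_p) {
    mh <- as.integer(substr(x, 2, 2)); ph <- as.integer(substr(x, 4, 4))
    if (flip_m) mh <- 3L - mh
    if (flip_p) ph <- 3L - ph
    sprintf("M%dP%d", mh, ph)
  }
  ok <- FALSE
  for (fm in c(FALSE, TRUE)) for (fp in c(FALSE, TRUE)) {
    ok <- ok || identical(unname(calls$call[!rec_true]),
                          unname(relabel(truth_state[!rec_true], fm, fp)))
  }
  expect_true(ok)
})

test_that("ANOVA F matches the sum-of-squares oracle to 1e-10", {
  vals <- c(12.1, 14.3, 11.8, 19.5, 20.2, 18.9, 25.0, 24.1, 26.3, 23.8)
  grp <- rep(c("M1P1", "M1P2", "M2P2"), c(3, 3, 4))
  calls <- data.frame(individual = sprintf("H%03d", 1:10), region_id = "r",
                      call = grp)
  ph <- data.frame(individual = sprintf("H%03d", 1:10), trait = vals)
  rep <- diplotype_effect_test(calls, ph)
  orc <- anova_F_oracle(vals, grp)
  expect_equal(rep$anova$F, orc$F, tolerance = 1e-10)
  expect_equal(rep$anova$p, orc$p, tolerance = 1e-10)
  expect_identical(rep$anova$df1, orc$df1)
  expect_identical(rep$anova$df2, orc$df2)
  expect_identical(nrow(rep$tukey), 3L)   # C(3,2) pairs
  expect_equal(sum(rep$groups$n), 10L)
})

test_that("identical groups give F = 0 and p = 1", {
  calls <- data.frame(individual = sprintf("H%03d", 1:8), region_id = "r",
                      call = rep(c("M1P1", "M2P2"), each = 4))
  ph <- data.frame(individual = sprintf("H%03d", 1:8), trait = rep(7, 8))
  rep <- diplotype_effect_test(calls, ph)
  expect_equal(rep$anova$F, 0)
  expect_equal(rep$anova$p, 1)
})

test_that("with two groups the Tukey adjusted p equals the ANOVA p", {
  set.seed(2)
  calls <- data.frame(individual = sprintf("H%03d", 1:20), region_id = "r",
                      call = rep(c("M1P1", "M2P2"), each = 10))
  ph <- data.frame(individual = sprintf("H%03d", 1:20),
                   trait = rnorm(20, rep(c(0, 1), each = 10)))
  rep <- diplotype_effect_test(calls, ph)
  expect_equal(rep$tukey$p_adj, rep$anova$p, tolerance = 1e-8)
})

test_that("recombinants and unknowns are excluded but reported", {
  calls <- data.frame(individual = sprintf("H%03d", 1:10), region_id = "r",
                      call = c(rep("M1P1", 4), rep("M2P2", 3),
                               "RECOMBINANT", "RECOMBINANT", "UNKNOWN"))
  ph <- data.frame(individual = sprintf("H%03d", 1:10),
                   trait = c(rnorm(7), 1000, 1000, 1000))
  rep <- diplotype_effect_test(calls, ph)
  expect_identical(rep$n_recombinant, 2L)
  expect_identical(rep$n_unknown, 1L)
  expect_equal(sum(rep$groups$n), 7L)
  expect_true(all(rep$groups$mean < 100))   # outliers never entered
})

test_that("the effect test degrades gracefully below two usable groups", {
  calls <- data.frame(individual = sprintf("H%03d", 1:4), region_id = "r",
                      call = c("M1P1", "M1P1", "M1P1", "M2P2"))
  ph <- data.frame(individual = sprintf("H%03d", 1:4), trait = rnorm(4))
  rep <- diplotype_effect_test(calls, ph)
  expect_null(rep$anova)
  expect_match(rep$reason, "fewer than 2")
})

test_that("panel prediction: identity at full panel, degradation at k = 1", {
  pop <- small_pop(seed = 61, n_lg = 1, markers_per_lg = 150,
                   error = 0.01, missing = 0.05)
  cl <- classify_markers(pop$geno)
  tmm <- phase_parent(raw_transmission(pop$geno, cl, "maternal"))
  tmp <- phase_parent(raw_transmission(pop$geno, cl, "paternal"))
  reg <- list(region_id = "r", lg = "LG01", start_bp = 6e6, end_bp = 9.5e6)
  all_mk <- c(evenly_spaced_panel(tmm, reg, 1e9),
              evenly_spaced_panel(tmp, reg, 1e9))
  full <- predict_diplotype_from_snp_panel(tmm, tmp, reg, all_mk)
  expect_equal(full$agreement, 1.0)

  p24 <- c(evenly_spaced_panel(tmm, reg, 12), evenly_spaced_panel(tmp, reg, 12))
  a24 <- predict_diplotype_from_snp_panel(tmm, tmp, reg, p24)$agreement
  expect_gte(a24, 0.95)

  p1 <- c(evenly_spaced_panel(tmm, reg, 1), evenly_spaced_panel(tmp, reg, 1))
  a1 <- predict_diplotype_from_snp_panel(tmm, tmp, reg, p1)$agreement
  expect_lte(a1, a24)

  expect_error(predict_diplotype_from_snp_panel(tmm, tmp, reg, character()),
               "at least one")
  expect_error(predict_diplotype_from_snp_panel(tmm, tmp, reg, "nope"),
               "subset")
})
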