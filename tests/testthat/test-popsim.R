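test_that("config validation rejects impossible designs", {
  expect_error(sim_config(n_lg = 0), "counts")
  expect_error(sim_config(missing_rate = 1.2), "proportions")
  expect_error(sim_config(frac_maternal_informative = 0.7,
                          frac_paternal_informative = 0.7), "sum")
})

test_that("parent simulation honours marker classes and the seed", {
  cfg <- sim_config(n_lg = 2, markers_per_lg = 50, n_progeny = 4,
                    frac_maternal_informative = 1,
                    frac_paternal_informative = 0, frac_both_het = 0,
                    seed = 11)
  par <- simulate_parents(cfg)
  expect_true(all(par$markers$class == "MATERNAL_INFORMATIVE"))
  expect_true(all(par$p1[, 1] != par$p1[, 2]))   # mother het everywhere
  expect_true(all(par$p2[, 1] == par$p2[, 2]))   # father hom everywhere

  cfg20 <- sim_config(n_lg = 20, markers_per_lg = 10, n_progeny = 2, seed = 3)
  expect_length(unique(simulate_parents(cfg20)$markers$lg), 20L)

  again <- simulate_parents(cfg)
  expect_identical(par$markers, again$markers)
  expect_identical(par$p1, again$p1)
  expect_identical(par$p2, again$p2)
})

test_that("marker bp positions are strictly increasing within each lg", {
  par <- simulate_parents(sim_config(n_lg = 3, markers_per_lg = 100,
                                     n_progeny = 2, seed = 5))
  for (lg in unique(par$markers$lg)) {
    expect_true(all(diff(par$markers$bp[par$markers$lg == lg]) > 0))
  }
})

test_that("meiosis follows the Haldane crossover model", {
  cfg0 <- sim_config(n_lg = 1, markers_per_lg = 10, n_progeny = 2,
                     lg_length_cM = 0, seed = 2)
  par0 <- simulate_parents(cfg0)
  set.seed(1)
  for (i in 1:20) {
    g <- simulate_meiosis(par0, "mother", "LG01")
    expect_length(g$xo_bp, 0L)
    expect_true(all(g$labels == g$labels[1L]))   # one intact haplotype
  }

  # mean crossover count at 100 cM is 1 within 3 standard errors
  set.seed(42)
  counts <- replicate(10000, length(ptxqtl:::meiosis_draw(1e6, 100)$xo_bp))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 1), 3 * se)

  # a single crossover yields exactly two label runs
  set.seed(9)
  repeat {
    g <- ptxqtl:::meiosis_draw(1e6, 100)
    if (length(g$xo_bp) == 1L) break
  }
  lab <- ptxqtl:::gamete_labels(seq(1, 1e6, length.out = 50), g$xo_bp, g$start)
  expect_identical(length(rle(lab)$lengths), 2L)
})

test_that("progeny are Mendelian-consistent with the true gametes at zero error", {
  pop <- small_pop(seed = 21, error = 0, missing = 0)
  gm <- pop$geno; truth <- pop$truth
  prog <- progeny_ids(gm)
  mk <- truth$markers
  p1 <- pop$parents$p1; p2 <- pop$parents$p2
  exp_m <- p1[cbind(rep(seq_len(nrow(mk)), length(prog)),
                    as.vector(truth$tm_mother[, prog]))]
  exp_p <- p2[cbind(rep(seq_len(nrow(mk)), length(prog)),
                    as.vector(truth$tm_father[, prog]))]
  expected <- matrix(ptxqtl:::join_geno(exp_m, exp_p), nrow(mk))
  expect_identical(unname(gm$geno[, prog]), expected)
})

test_that("missingness and full-missing limits behave as configured", {
  cfg <- sim_config(n_lg = 1, markers_per_lg = 100, n_progeny = 1000,
                    missing_rate = 1, genotype_error_rate = 0, seed = 8)
  pop <- simulate_progeny(simulate_parents(cfg), cfg)
  expect_true(all(is.na(pop$geno$geno[, progeny_ids(pop$geno)])))

  cfg2 <- sim_config(n_lg = 1, markers_per_lg = 100, n_progeny = 1000,
                     missing_rate = 0.1, genotype_error_rate = 0, seed = 8)
  pop2 <- simulate_progeny(simulate_parents(cfg2), cfg2)
  ncalls <- 100 * 1000
  obs <- sum(is.na(pop2$geno$geno[, progeny_ids(pop2$geno)]))
  ci <- qbinom(c(0.005, 0.995), ncalls, 0.1)
  expect_gte(obs, ci[1]); expect_lte(obs, ci[2])
})

test_that("trait equals baseline plus diplotype effect when noise is zero", {
  q <- qtl_spec("LG01", 8.2e6,
                c(M1P1 = -50, M1P2 = 0, M2P1 = -40, M2P2 = 99))
  pop <- small_pop(seed = 13, qtls = list(q), noise_sd = 0)
  d <- true_diplotypes(pop$truth, q)
  expect_equal(pop$pheno$trait, unname(400 + q$effects[d]))

  # transgressive segregation: progeny means span far beyond both parents
  pop2 <- small_pop(seed = 14, n_progeny = 200, qtls = list(q), noise_sd = 80)
  expect_lt(min(pop2$pheno$trait), 350)
  expect_gt(max(pop2$pheno$trait), 460)
})

test_that("group means recover diplotype effects at large n (CLT check)", {
  q <- qtl_spec("LG01", 8.2e6,
                c(M1P1 = -50, M1P2 = 0, M2P1 = -40, M2P2 = 99))
  cfg <- sim_config(n_lg = 1, markers_per_lg = 12, n_progeny = 4000,
                    genotype_error_rate = 0, missing_rate = 0, seed = 17)
  pop <- simulate_population(cfg, qtls = list(q), noise_sd = 80)
  d <- true_diplotypes(pop$truth, q)
  means <- tapply(pop$pheno$trait, d, mean)
  ns <- tapply(pop$pheno$trait, d, length)
  for (g in names(q$effects)) {
    expect_lt(abs(means[[g]] - (400 + q$effects[[g]])),
              3 * 80 / sqrt(ns[[g]]))
  }
})

test_that("qtl_spec rejects malformed effect sets and unknown lgs warn", {
  expect_error(qtl_spec("LG01", 1e6, c(M1P1 = 1, M1P2 = 2, M2P1 = 3)),
               "effects")
  pop <- small_pop(seed = 3, n_lg = 1)
  badq <- qtl_spec("LG09", 1e6, c(M1P1 = 0, M1P2 = 0, M2P1 = 0, M2P2 = 0))
  expect_warning(simulate_trait(pop$truth, list(badq)), "not simulated")
})

test_that("the whole simulation is byte-deterministic under a fixed seed", {
  a <- small_pop(seed = 99, error = 0.02, missing = 0.1)
  b <- small_pop(seed = 99, error = 0.02, missing = 0.1)
  expect_identical(a$geno$geno, b$geno$geno)
  expect_identical(a$truth$xo, b$truth$xo)
  expect_identical(a$pheno, b$pheno)
})

test_that("transmission labels change only at recorded crossovers", {
  pop <- small_pop(seed = 31, n_lg = 1, markers_per_lg = 120)
  truth <- pop$truth
  mk <- truth$markers
  for (i in sample(colnames(truth$tm_mother), 10)) {
    xo <- sort(truth$xo$xo_bp[truth$xo$individual == i &
                                truth$xo$parent == "mother" &
                                truth$xo$lg == "LG01"])
    lab <- truth$tm_mother[, i]
    sw <- which(diff(lab) != 0L)
    for (s in sw) {
      expect_true(any(xo > mk$bp[s] & xo < mk$bp[s + 1L]))
    }
  }
})
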