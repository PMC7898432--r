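#!/usr/bin/env Rscript
# Stage 4 — region diplotypes and their effect on fruit weight.
#
# For every QTL region: call each progeny's diplotype (TA haplotype x KP
# haplotype), exclude individuals with evidence of recombination inside
# the region, and test group differences by one-way ANOVA with Tukey HSD.

suppressMessages(library(ptxqtl))
out <- "results/mango_emulation"

geno <- read_genotypes_vcf(file.path(out, "genotypes.vcf"), "TA", "KP")
pheno <- read_phenotypes(file.path(out, "phenotypes.tsv"), geno)
tmm <- read_transmissions(file.path(out, "transmissions_maternal.tsv"),
                          "maternal")
tmp <- read_transmissions(file.path(out, "transmissions_paternal.tsv"),
                          "paternal")
regions <- read.delim(file.path(out, "regions.tsv"))

for (i in seq_len(nrow(regions))) {
  reg <- regions[i, ]
  calls <- suppressWarnings(
    call_region_diplotype(tmm, tmp, reg, prefixes = c("TA", "KP")))
  safe <- gsub("[^A-Za-z0-9]+", "_", reg$region_id)
  write.table(calls, file.path(out, sprintf("diplotypes_%s.tsv", safe)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  rep <- diplotype_effect_test(calls, pheno)
  cat("\n==", reg$region_id, "==\n")
  print(rep)
}
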