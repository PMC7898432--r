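#!/usr/bin/env Rscript
# Stage 1 — simulate the mapping population.
#
# Emulates a 'Tommy Atkins' x 'Kensington Pride'-style outcrossing F1
# design: 20 linkage groups, 104 progeny, skim-sequencing noise (1%
# miscalls, 10% missing), and two QTLs whose diplotype effects mirror the
# reported fruit-weight architecture (an LG4-like locus where the paternal
# haplotype splits ~170 g, and a weaker LG7-like locus acting through the
# maternal haplotype). Writes the genotype VCF, phenotype table and truth
# files that the later stages consume.

suppressMessages(library(ptxqtl))
out <- "results/mango_emulation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 104L)   # defaults: 20 LGs, 200 SNPs/LG, 104 progeny
pop <- simulate_population(cfg)

write_genotypes_vcf(pop$geno, file.path(out, "genotypes.vcf"))
write_phenotypes(pop$pheno, file.path(out, "phenotypes.tsv"))
write.table(pop$truth$xo, file.path(out, "true_crossovers.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d markers x %d individuals on %d linkage groups\n",
            nrow(pop$geno$markers), length(pop$geno$individuals),
            cfg$n_lg))
cat(sprintf("progeny fruit weight: %.0f-%.0f g (parents 400/410 g) -- transgressive segregation\n",
            min(pop$pheno$trait), max(pop$pheno$trait)))
cat(sprintf("true crossovers recorded: %d\n", nrow(pop$truth$xo)))
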