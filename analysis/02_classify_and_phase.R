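#!/usr/bin/env Rscript
# Stage 2 — marker classification, parental phasing, breakpoints.
#
# Reads the stage-1 VCF, keeps the pseudo-testcross-informative SNPs
# (heterozygous in exactly one parent), phases each parent's two
# haplotypes from progeny co-segregation, and calls per-progeny
# recombination breakpoints with run-length smoothing (min_run = 3).

suppressMessages(library(ptxqtl))
out <- "results/mango_emulation"

geno <- read_genotypes_vcf(file.path(out, "genotypes.vcf"), "TA", "KP")
classes <- classify_markers(geno)
write.table(classes, file.path(out, "markers.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("marker classes:\n")
print(table(classes$class))

bks <- list()
for (p in c("maternal", "paternal")) {
  tmx <- phase_parent(raw_transmission(geno, classes, p))
  write_transmissions(tmx, file.path(out, sprintf("transmissions_%s.tsv", p)))
  bks[[p]] <- detect_breakpoints(tmx, min_run = 3)
  cat(sprintf("%s: %d informative markers phased, %d low-confidence, %d breakpoints\n",
              p, nrow(tmx$tm), sum(tmx$markers$low_confidence),
              nrow(bks[[p]])))
}
bk <- rbind(bks$maternal, bks$paternal)
write.table(bk, file.path(out, "breakpoints.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("mean breakpoints per progeny per parent: %.2f (Haldane expectation ~%.1f per 100 cM LG)\n",
            nrow(bk) / (2 * (length(geno$individuals) - 2)), 20 * 1.0))
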