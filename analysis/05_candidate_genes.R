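#!/usr/bin/env Rscript
# Stage 5 — candidate genes in the fruit-weight QTL regions.
#
# Queries the bundled candidate-gene table (one bp position per gene, as
# published for the mango fruit-weight study) against the published LG4
# and LG7 region bounds, and against the regions mapped in stage 3 when
# they overlap those linkage groups.

suppressMessages(library(ptxqtl))
out <- "results/mango_emulation"

genes <- read_gene_table(fruit_weight_gene_table())
regs <- fruit_weight_regions()
for (i in seq_len(nrow(regs))) {
  r <- regs[i, ]
  hit <- genes_in_region(genes, r, rule = "start-in-region")
  safe <- gsub("[^A-Za-z0-9]+", "_", r$region_id)
  write.table(hit, file.path(out, sprintf("genes_%s.tsv", safe)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d genes\n", r$region_id, nrow(hit)))
  cat(paste0("  ", utils::head(hit$annotation, 3), "\n"), sep = "")
  if (nrow(hit) > 3) cat(sprintf("  ... and %d more\n", nrow(hit) - 3))
}
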