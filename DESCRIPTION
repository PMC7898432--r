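Package: ptxqtl
Title: Pseudo-Testcross QTL Mapping for Outcrossing F1 Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative trait locus (QTL) mapping in F1 hybrid
    populations of two heterozygous, outcrossing parents using the
    pseudo-testcross strategy. Classifies SNPs by parental informativeness,
    phases each parent's haplotypes from progeny co-segregation, infers
    per-progeny transmitted haplotypes and recombination breakpoints,
    performs single-marker association with permutation p-values, defines
    QTL regions by threshold-and-merge, calls region-level diplotypes with
    recombinant exclusion, tests diplotype effects by ANOVA with Tukey HSD,
    and extracts candidate genes from an annotation. Includes a meiosis
    simulator (Poisson crossovers, no interference) that generates synthetic
    populations with truth files so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    rtracklayer,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
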