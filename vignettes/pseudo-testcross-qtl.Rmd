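---
title: "Pseudo-testcross QTL mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-testcross QTL mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptxqtl)
```

## The mapping problem

Commercial fruit trees such as mango are highly heterozygous outcrossers:
there are no inbred lines, and an F1 family from two heterozygous parents
segregates at every locus where either parent is heterozygous. The
*pseudo-testcross* strategy turns this into two ordinary backcross-like
analyses. A SNP that is heterozygous in exactly one parent and homozygous
in the other segregates 1:1 in the progeny, and each progeny genotype
reveals which of the informative parent's two haplotypes was transmitted.
Maternal-informative and paternal-informative markers therefore map the
maternal and paternal genomes separately.

`ptxqtl` implements the full chain used to dissect a quantitative trait
(the motivating case is mean fruit weight, in grams, of a 'Tommy Atkins' x
'Kensington Pride' mango family):

1. classify SNPs by parental informativeness;
2. phase each parent's informative markers into haplotypes 1/2 from
   progeny co-segregation;
3. infer per-progeny transmissions and recombination breakpoints;
4. scan markers for trait association with permutation p-values and merge
   significant markers into QTL regions;
5. call each progeny's region *diplotype* (the maternal/paternal haplotype
   pair, e.g. TA2KP1), excluding recombinants, and test diplotype effects
   by one-way ANOVA with Tukey HSD;
6. list candidate genes inside the region bounds from an annotation.

A meiosis simulator generates synthetic populations with truth files so
every stage is testable without any external data.

## The simulator

`simulate_population()` draws two phased parental genomes, meioses, progeny
genotypes and a quantitative trait.

**Meiosis model.** Crossover counts per gamete and linkage group are
Poisson with mean `lg_length_cM / 100` and positions are uniform on the
map (Haldane model, no crossover interference). The recombination rate is
uniform along the physical axis, so centiMorgan positions are proportional
to bp. Interference-free meiosis slightly over-produces close double
crossovers relative to real chiasma data; the consequences for breakpoint
detection are discussed below.

**Trait model.** `trait = baseline + sum over QTLs of
effect[diplotype at the QTL position] + N(0, noise_sd)`. Effects are
attached to the *diplotype* (one of M1P1, M1P2, M2P1, M2P2), not to an
allele dosage, which is what produces transgressive segregation from
similar parents: each parent is heterozygous for a high and a low
haplotype, so progeny can stack two highs or two lows. The default
architecture (`default_qtls()`) places one locus on LG04 with effects
(-50, 0, -71, +99) g around a 400 g baseline — so the lowest and highest
diplotype means sit near 329 g and 499 g — and a weaker locus on LG07
with effects (-48, -41, +50, +68) g, mirroring the reported fruit-weight
architecture. Residual noise defaults to `noise_sd = 80` g, the scale
needed for ~400 g parents to yield progeny means spanning roughly
165–970 g. A Gaussian residual admits physically implausible extremes at
the tails of a 104-progeny draw; the simulator makes no attempt to
truncate them.

**Genotyping noise.** Skim sequencing (~5x) is emulated at the call level,
not the read level: with probability `genotype_error_rate` (default 0.01)
one allele of a call is flipped to a random other base, then calls are
masked with probability `missing_rate` (default 0.1). Roughly two thirds
of flips at informative markers create Mendelian-impossible calls (caught
and set to unknown); the remaining third silently switch the inferred
haplotype label, which is exactly the error mode the run-length smoothing
downstream is designed for. Parental genotypes are treated as known:
in practice the parents of a mapping population are genotyped far more
deeply than the progeny, and classification errors in parents are a
different failure mode from progeny miscalls.

**Dimensions.** Defaults follow the motivating study: 20 linkage groups,
104 progeny, ~16.4 Mb and 100 cM per linkage group. Marker density
defaults to 200 SNPs per linkage group — a deliberate desk-scale stand-in
for the ~3.3 M SNPs of a real skim-sequencing map; density mainly sets the
resolution of breakpoint intervals and region bounds, not the logic of any
stage. `n_phenotyped` / `n_genotyped` expose the fact that real studies
phenotype and genotype overlapping but unequal subsets (99 and 87 of 104
here); no particular overlap is assumed.

Class fractions default to 0.4/0.4/0.1 (maternal-informative,
paternal-informative, both-het): heavily heterozygous parents share a
minority of heterozygous sites, and the informative classes dominate.

## Phasing and breakpoints

`phase_parent()` orients each informative marker's two alleles onto
haplotype labels 1/2 greedily along the linkage group: marker 1 is
arbitrary, and each subsequent marker takes the orientation that agrees
with the previous oriented marker in the majority of progeny (pairs with
both calls present). With complete data the total apparent-recombination
count decomposes over adjacent marker pairs, so the greedy pass attains
the global minimum-recombination phase; the test suite checks this
against an exhaustive search over all orientations on small instances.
Ties (including no informative overlap) keep the current orientation and
flag the marker low-confidence. Phase is identifiable only up to a per-LG
label switch; every downstream quantity (breakpoints, association
p-values, ANOVA F) is invariant under that switch, and the tests assert
it.

`detect_breakpoints()` first masks haplotype-label runs shorter than
`min_run` (default 3), then reports a breakpoint at every remaining 1–2
switch between consecutive non-missing markers, as an interval between
informative-marker positions — never a point estimate, since the data
cannot localise a crossover more finely.

Two numerical details of the smoothing deserve explanation:

* An *interior* short run is flanked on both sides by the other
  haplotype. At a ~1% miscall rate an isolated wrong label is far more
  likely than a genuine double crossover within one or two marker
  intervals, so interior short runs are masked.
* A short run at either *end* of the informative span is different: a
  late (or early) real crossover produces exactly this pattern, and at 1%
  error a terminal-gap crossover is about as likely as an edge miscall.
  Masking edge runs would make end-of-chromosome crossovers undetectable
  by construction, so breakpoint detection keeps them. Diplotype calling
  (below) makes the opposite choice, because its risk is asymmetric in
  the other direction.

**Detectability limits.** Some true crossovers are invisible to any
method at any coverage: an even number of crossovers falling between the
same two adjacent informative markers produces no observable switch, and
crossovers outside the span of a parent's informative markers have no
flanking pair. Recovery statements in the tests are therefore phrased
over *detectable* crossovers (odd parity within an informative-marker
gap, inside the span); with error-free data those are recovered exactly,
and with 1% error and `min_run = 3` about 96% are recovered within one
flanking-marker interval on 200-marker transmission matrices.

## Association and QTL regions

`qassoc()` is ordinary least squares of the trait on a per-marker
predictor with a Wald t-test (n-2 df) — for the 0/1
transmitted-haplotype indicator this is algebraically the equal-variance
two-sample t-test. Two scans are run, maternal and paternal, because the
pseudo-testcross map is phased per parent; allele-dosage coding is also
available for unphased genotype matrices. Individuals with unknown
transmission are dropped marker-wise; a constant predictor yields
statistic 0 and p 1 with a flag, and a constant trait yields slope 0 and
p 1.

Empirical p-values come from permutations:
`p = (1 + #{permuted |t| >= observed |t|}) / (n_perm + 1)`, the add-one
form whose smallest attainable value is `1/(n_perm + 1)`. The default
`n_perm = 999` makes the floor exactly the region-defining threshold
0.001, matching the convention of thresholding permuted p at 0.001. The
scan engine permutes the phenotype vector once per permutation and
recomputes every marker's statistic with matrix products; since a trait
permutation is the inverse of a predictor permutation, the null
distribution is identical to per-marker predictor shuffling (asserted
distributionally in the tests, and exactly by full enumeration at n = 4).
P-values are pointwise (per marker), as in the original validation; no
family-wise max-T correction is applied, and a Bonferroni count is left
to the reader — the region-merge step is intentionally faithful to the
published procedure rather than conservative.

`define_regions()` merges markers with `p <= threshold` (default 0.001)
into regions while consecutive significant markers are at most
`max_gap_bp` apart (default 1 Mb — a configurable choice; the original
merge rule is not documented). Region bounds are the min/max bp of member
markers, so bounds are granular at the marker spacing; lowering the
threshold can only shrink member sets (asserted as a property test). At
desk-scale density with a strong simulated QTL, merged regions can grow
to several Mb — with millions of SNPs and a weaker real signal the same
rule produces the compact published regions.

## Diplotypes and effect testing

`call_region_diplotype()` collects, per parent, the haplotype labels
transmitted at the region's informative markers. Observing both labels
from one parent is treated as evidence of recombination inside the
region, and the individual is excluded from the effect test (strict
uniqueness, matching the published definition of a region recombination
event; majority-vote assignment was the alternative and is deliberately
not used). Fewer than `min_info_frac` (default 0.5) non-missing labels
gives UNKNOWN. Labels are smoothed lg-wide with the same run-length rule
as breakpoint detection before the region is summarised — without this,
a single silent miscall inside the region fakes a recombinant, and at 1%
error the recombinant class absorbs a large share of the family. Here
short *edge* runs are masked too: for a purity call the asymmetric risk
is declaring false recombinants, not missing terminal crossovers. With
`min_run = 1` the smoothing is off, which is the correct setting for
error-free data and is what the truth-recovery tests use.

`diplotype_effect_test()` is one-way fixed-effects ANOVA on the called
groups (recombinants and unknowns excluded but reported) followed by
Tukey's HSD via the studentized range; with exactly two groups the Tukey
adjusted p equals the ANOVA p. Groups are assumed homoscedastic Gaussian,
as in the original analysis; a Welch variant is available behind
`welch = TRUE` for the global test. A trait with no variance at all is
reported as F = 0, p = 1 rather than NaN. Fewer than two groups with two
members yields a report whose test fields are `NULL` with a reason — not
an error, since small families with many recombinants genuinely produce
this.

`predict_diplotype_from_snp_panel()` re-calls diplotypes from a marker
subset and reports agreement with the full-region calls — the relevant
quantity when designing a small seedling-screening panel; with ~24
well-spaced SNPs per region, agreement stays above 95% under default
noise.

## Candidate genes

`genes_in_region()` returns genes whose start position lies inside the
region (1-based, boundaries inclusive) — the natural rule for annotation
tables that list one bp position per gene, and the default; an `overlap`
rule is available for full GFF3 annotations (read via `rtracklayer`,
with an optional seqid-to-linkage-group map). The bundled table
`fruit_weight_gene_table()` transcribes the published candidate-gene
positions for the two mango fruit-weight regions (28 genes on LG4, 7 on
LG7) and is queried by the acceptance checks against the published region
bounds.

## Determinism and problem sizes

All randomness flows from one master seed through `derive_seed(seed,
tag)` per stage, so any stage can be reproduced in isolation and a full
`run_pipeline()` run is byte-identical under a fixed configuration. The
test suite and acceptance script run at deliberately reduced sizes chosen
as the package's own desk-scale conventions: 4-marker x 6-progeny
instances for the exhaustive phasing oracle (the search is exponential in
markers), a 5-LG x 200-marker x 100-progeny population for exact
zero-error recovery, 100-replicate families for the stochastic QTL- and
effect-recovery rates, and 500–1000 replicates for permutation
calibration.

## What passing tests do and do not show

The simulator emulates call-level genotypes of a pseudo-testcross family
with additive diplotype effects. It does not model read depth or
allele-specific dropout, linked assembly errors, segregation distortion,
marker-order errors (marker order is taken as given from assembly
positions), epistasis or dominance decomposition, genotype-by-year
variation in the phenotype, or crossover interference. Passing recovery
tests therefore show that the inference chain is correct under its own
stated error model at realistic rates — not that any particular real
dataset meets those assumptions. Interval mapping, mixed-model
association with kinship, and map-order estimation are out of scope by
design.
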