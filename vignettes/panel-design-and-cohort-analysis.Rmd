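---
title: "Cross-species panel design and cohort survival analysis with panelsnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species panel design and cohort survival analysis with panelsnp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelsnp)
library(dplyr)
```

## The problem

Designing a targeted genotyping panel for a species with little
disease-genetics literature of its own means borrowing: disease-associated
SNPs curated in a well-studied source species are carried across to the
target species, filtered for sites that are actually conserved, prioritized
by functional evidence, and anchored to SNPs known to segregate in the
target population. Once the panel has been sequenced on a cohort,
high-confidence genotypes are derived by intersecting several variant
callers, and survival models ask which panel variants track outcome.

`panelsnp` implements that entire chain as composable, tibble-in/tibble-out
functions, together with a synthetic-data module that can fabricate every
input with known ground truth. All statistical claims in this vignette are
claims the package's test suite actually computes.

## Harvesting and deduplicating source SNPs

`merge_snp_sources()` merges any number of curated association tables into
one record per rsID (case-insensitive, `rs`-prefixed; other identifiers
pass with a warning), unioning source tags. Records that carry an
association p-value are kept only when p < 1e-5 — the threshold is applied
only where a source reports a p-value, because manually curated entries
(e.g. from a Mendelian-disease catalog) typically do not. `filter_by_catalog()`
then drops records absent from a reference SNP catalog.

## Ortholog mapping and conservation

Each SNP is wrapped in a 100-bp window — 50 bases of left flank and 49 of
right, so the SNP sits at 0-based offset 50; "centered" on an even window
is necessarily asymmetric, and the flank is configurable. The window is
mapped through a UCSC chain file by `lift_interval()`, which walks every
base through the ungapped blocks of the best-scoring overlapping chain.
Lifting fails (`no_ortholog`) when fewer than 95% of window bases map —
the usual region-level liftOver default, since no other value is implied
by the procedure being emulated. Minus-strand chains yield
reverse-complemented coordinates with the SNP offset mirrored.

`classify_snp()` then applies, in order: `too_long` for lifted sequences
above 1,000 bp (a window that ballooned across an insertion is not a
usable ortholog), `unplaced` for targets on unplaced contigs (name pattern
configurable, default `^chrUn`), and `gap_at_snp` when the global pairwise
alignment of the two windows (match +1, mismatch −1, linear gap −2, via
`Biostrings`) puts a gap in the target row at the SNP column. Everything
else is `conserved`. A multi-species alignment adds context a human reader
may want, but only the target row's gap at the SNP column decides the
exclusion, so the package reduces the alignment to the source-target pair.

Coordinates are 0-based half-open internally and 1-based in user-facing
tables; the conversion lives in exactly one place.

## Prioritization

Four criteria select loci, and a locus keeps every tag it earns:

* **UTR overlap** — the locus overlaps an annotated UTR and its coding
  (CDS) overlap is absent or strictly below two thirds of the locus
  length. Annotation features of 50 bp or less are removed first
  (`filter_annotation()`); the filter direction is configurable because
  the alternative reading ("keep only short features") would make the
  rule inert, which we judged implausible.
* **TF proximity** — the nearest upstream or downstream TSS (by genomic
  coordinate relative to the locus midpoint; distance from the nearer
  locus edge; ties to the lexicographically smaller gene id) belongs to a
  gene classified as a transcription factor.
* **Key regulators** — the locus lies inside a designated key-regulator
  gene.
* **DEG hubs** — among loci not already selected whose nearest TSS is a
  differentially expressed gene, those whose DEG has strictly more than
  10 interaction partners with curated-evidence score strictly above 0.5.
  DEG lists are consumed as plain gene-id lists; their derivation
  (expression thresholds, FDR) is the provenance contract of the input,
  not recomputed here.

## Haplotype blocks and proxy SNPs

Candidate loci need not be polymorphic in the target species, so each is
represented by its nearest known SNP. Whether that proxy is plausibly in
linkage is judged against the median haplotype-block span estimated from
an unphased genotype panel.

Two-locus haplotype frequencies come from the standard EM algorithm
(`em_haplotypes()`: uniform start, double-heterozygote phase resolved by
expected counts, convergence at 1e-9 or 1,000 iterations). |D′| and its
confidence interval follow the likelihood-grid construction used by the
Gabriel block method: the genotype likelihood is evaluated on a |D′| grid
of step 0.001 with allele frequencies and the sign of D fixed at their
estimates, and the 5th/95th percentiles of the normalized cumulative
likelihood bound the interval (widened by at most one grid step so the
point estimate is never excluded by quantization).

`find_blocks()` applies the Gabriel criteria with the Haploview defaults
that PLINK's block finder also adopts — strong LD when `ci_low >= 0.70`
and `ci_high >= 0.98`, strong recombination when `ci_high < 0.90`, at
least 95% of informative pairs in strong LD, 200-kb span cap — since the
emulated run used "default settings" without listing them. Candidates are
ranked by bp span and accepted greedily without overlap. The phenotype
restriction that the original tool's `no-phenoreq` flag removes has no
analog here: the package never requires phenotypes, so the flag is a
documented no-op. The median block span is computed over all detected
blocks of the analyzed panel ("over the whole panel" being our reading of
a per-individual phrasing that the method does not otherwise use).

`assign_proxies()` picks the nearest known SNP per locus (ties to the
lower coordinate), merges loci sharing a proxy, and flags distances
strictly below the median block span.

## Panel emission

`build_panel()` makes one target per unique SNP (proxies plus
literature-reported target-species SNPs, deduplicated on position), each a
window of at most 120 bp nominally centered on the SNP and truncated at
chromosome ends. Primer chemistry is deliberately out of scope: design
failures are an input (an external design-result table), not a
prediction.

## Three-caller consensus genotyping

Calls from three callers per sample are quality-filtered (QUAL ≥ 20),
normalized (`normalize_variant()`: trim shared trailing bases, extend
left with the preceding reference base whenever an allele would empty,
then trim shared leading bases — the standard left-align/parsimony
algorithm, idempotent by construction) and matched on
chromosome+position+REF+ALT, SNVs and indels alike. A variant is a
consensus call in a sample iff all three callers report it; the pooled
set is every variant with a consensus in at least one sample.

Per-sample genotypes for pooled variants: the consensus genotype where
all callers agree, the majority genotype under 2-vs-1 disagreement, and a
heterozygous call under three-way disagreement (the emulated procedure is
silent here; majority is the least-surprising rule). A sample in which no
caller saw the variant is homozygous reference. For samples where only
one or two callers called it, the default `"strict"` rule marks the
genotype missing — which later fails the cohort filter's
no-missingness requirement — while the `"any"` rule implements the
literal reading that any caller's call makes a carrier. Both ship;
strict is the default because it never promotes unreplicated calls.

`cohort_filter()` keeps variants carried by 11-18 samples with all others
homozygous reference and nothing missing (the Methods bounds; the Results
narration of "11-19" is accommodated by the configurable bounds).
`dedup_patterns()` removes same-target variants with identical per-sample
genotype vectors, keeping the smallest coordinate.

## Survival modelling

`cox_fit()` wraps the Cox partial likelihood (Efron ties by default;
non-convergent or monotone-likelihood fits are flagged, not raised) and
reports β, hazard ratios, Wald p-values, the log partial likelihood and
AIC = −2logL + 2k. Variants enter as binary carrier indicators, matching
the carrier-based cohort filter; additive coding is a configuration away.

`collett_select()` runs the staged selection exactly: univariable screen
at p ≤ 0.5; backward elimination by AIC; p ≤ 0.1 gate; forward selection
over the stage-1 pool by AIC; p ≤ 0.1 gate; bidirectional stepwise;
significance call at p ≤ 0.05. Candidates are processed in sorted order so
the result cannot depend on input order, and the full move trace is
returned. `stratify()` splits subjects at the median linear predictor
(ties to the low-risk group) and reports each group's Kaplan-Meier median
(first time the survival estimate reaches 0.5 or below). Clinical
covariates are screened separately with univariable fits
(`covariate_screen()`), with age at diagnosis encoded adult (2-7 years)
= 1 versus senior = 0; whether they should also enter the variant model
is left to an explicit user choice, since the emulated analysis reports
them only as a separate screen.

## The synthetic-data module

Everything above is testable offline because the generators fabricate
inputs with recorded truth:

* `simulate_genome_pair()` derives a target genome from a source genome
  of per-SNP segments, emitting a chain file that describes the
  derivation exactly; each segment's intended lift outcome (conserved,
  no-ortholog, length-inflated, unplaced-contig, deleted-at-SNP) is
  planted by construction, with the deleted bases flanked so the
  alignment gap falls unambiguously on the SNP column.
  `make_accounting_fixture()` wraps this so a requested composition of
  outcome classes provably produces the requested filter-cascade counts.
* `simulate_genotypes_ld()` builds blocks of founder haplotypes (two
  founders by default, giving within-block |D′| = 1), redrawing founder
  assignment between blocks with the configured probability (1 =
  linkage equilibrium between blocks). Genotypes are emitted unphased as
  PLINK text PED/MAP and VCF; default 600 subjects, the scale of the
  reference panel whose block structure the pipeline estimates.
* `simulate_caller_vcfs()` perturbs truth genotypes per caller with
  false-negative dropouts, decoy false positives, sub-threshold QUAL
  values and right-shifted indel representations, exercising the
  quality filter, the intersection logic and normalization.
* `simulate_survival()` draws exponential-baseline proportional-hazards
  event times (Weibull optional) with independent exponential censoring
  calibrated to the configured censor fraction — 7/29 by default, a
  typical lost-to-follow-up fraction for a small veterinary cohort.

What the generators do **not** emulate: sequencing reads and their error
profiles, platform-specific coverage structure, population stratification
and relatedness in the genotype panel, linkage *between* blocks beyond a
single redraw probability, or informative censoring. Green tests therefore
demonstrate algorithmic correctness on data satisfying the models'
assumptions, not robustness to real-data violations of them.

## Numerical choices and scales

Problem sizes in the tests balance statistical resolution against a few
minutes of runtime: the accounting fixture uses the full 592-SNP
composition; block recovery uses 20 panels of 600 subjects and 56 markers
in 8 blocks; selection recovery uses 50 cohorts of 300 subjects and 10
candidates; calibration uses 500 null Cox replicates. Alignment scoring,
EM tolerance (1e-9), the D′ grid step (0.001) and the Gabriel thresholds
are all exposed as arguments with the defaults stated above.

## A known limitation, quantified

The staged selection controls the *per-variant* type-I rate at the final
threshold: on all-null candidates each variant ends significant about 5%
of the time, which the calibration tests confirm. It does **not** control
the family-wise rate: with 10 independent null candidates, the chance
that the final model is completely empty is about 0.95^10 ≈ 0.60, and the
test suite's corresponding check (which asserts ≥ 90% empty) fails by
design rather than by defect. Stepwise procedures inflate family-wise
error; a user who needs family-wise control should add a multiplicity
correction on top of the final significance call rather than expect the
staged procedure to provide it.
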