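# panelsnp

Design a targeted genotyping panel for a poorly characterized species by
transferring disease-associated SNPs from a well-studied one — then analyze
the cohort you sequence with it. `panelsnp` is aimed at comparative
genomics and veterinary-oncology groups building small, cheap panels
(~100 loci) from the literature of a related, better-studied disease, and
at anyone who wants the downstream consensus-genotyping and survival
machinery as reusable parts.

The pipeline, end to end:

1. **Harvest** — merge curated SNP association tables into one record per
   rsID, applying the association threshold *p* < 10⁻⁵ where a source
   reports a p-value, and drop records absent from a reference SNP
   catalog.
2. **Ortholog mapping & conservation** — lift a 100-bp window centered on
   each SNP through a UCSC chain file (per-base mapping through the
   best-scoring chain; ≥95% of bases must map). Windows whose lifted
   sequence exceeds 1,000 bp, land on unplaced contigs, or align with a
   gap at the SNP column (global alignment, match +1 / mismatch −1 /
   gap −2) are excluded; the rest are conserved.
3. **Prioritization** — keep loci in UTRs (coding overlap < 2/3 of locus
   length), loci whose nearest up/downstream TSS is a transcription
   factor, loci in designated key-regulator genes, and loci whose nearest
   TSS is a differentially expressed gene acting as a network hub
   (> 10 partners with curated score > 0.5).
4. **Haplotype blocks & proxies** — estimate blocks from unphased
   genotypes with the Gabriel |D′| confidence-interval criteria
   (two-locus EM + likelihood-grid CI; strong LD: CI ∈ [0.70, 0.98+];
   recombination: upper CI < 0.90), then represent each locus by its
   nearest known SNP, merging loci that share one.
5. **Panel emission** — one ≤120-bp design window per unique SNP.
6. **Consensus genotyping** — per sample, a variant counts only if all
   three callers report it at QUAL ≥ 20 after left-align/parsimony
   normalization; pooled variants are consensus in ≥1 sample. Cohort
   filter: carried by 11–18 samples, everyone else homozygous reference;
   same-target duplicate genotype patterns removed.
7. **Survival modelling** — staged Cox variable selection
   (univariable *p* ≤ 0.5 → backward AIC → *p* ≤ 0.1 → forward AIC →
   *p* ≤ 0.1 → bidirectional AIC → significant at *p* ≤ 0.05), then
   median risk-score stratification with Kaplan–Meier group medians.

A synthetic-data module (`sim_config()` and the `simulate_*()` /
`make_*_fixture()` generators) fabricates every input with recorded
ground truth, so the whole pipeline is testable offline.

## Worked example

```r
library(panelsnp)

# a genome/chain/SNP bundle whose filter cascade is known by construction
fx <- make_accounting_fixture(
  list(n_input = 592, n_no_ortholog = 68, n_too_long = 1,
       n_unplaced = 1, n_gap_at_snp = 43, n_literature = 3), seed = 1)
cas <- run_ortholog_cascade(fx$snps, fx$source, fx$target, fx$chains)
cascade_counts(cas)
#>   status          n
#> 1 conserved     479
#> 2 no_ortholog    68
#> 3 too_long        1
#> 4 unplaced        1
#> 5 gap_at_snp     43

# 101 prioritized loci, two of which share their nearest known SNP
pfx <- make_proxy_fixture(n_loci = 101, n_shared = 1, seed = 1)
nrow(assign_proxies(pfx$loci, pfx$snp_map, pfx$blocks))
#> [1] 100

# staged Cox selection on a cohort with two planted effects (HR 2 and 0.5)
cfg <- sim_config(seed = 9, beta = c(log(2), -log(2)))
set.seed(10)
gt  <- matrix(rbinom(300 * 10, 2, 0.4), 300, 10,
              dimnames = list(NULL, sprintf("v%02d", 1:10)))
rec <- simulate_survival(gt, cfg)
cf  <- collett_select(rec, sprintf("v%02d", 1:10))
cf
#> Multi-stage Cox selection
#>   stage-1 pool: 7 candidate(s)
#>   final model: 3 variable(s); 3 significant at p <= 0.05
#>   term    beta     hr     se         p
#> 1  v01  0.8239 2.2794 0.1565 1.399e-07
#> 2  v02 -0.6270 0.5342 0.1433 1.205e-05
#> 3  v05 -0.3676 0.6924 0.1378 7.644e-03
stratify(cf, rec)
#> Median risk-score stratification
#>   group   n n_events km_median
#> 1  high 129      111  161.1277
#> 2   low 171      106  376.8507
```

The 479 conserved loci are the input composition minus the planted
failure classes; with the three literature SNPs they form 482 candidate
loci. The selection recovered both planted variants with the right signs
(hazard ratios 2.28 and 0.53 against truths 2.0 and 0.5; `v05` is a
false inclusion, the known cost of stepwise selection), and the median
split separates the risk groups' Kaplan–Meier medians by more than a
factor of two.

Fitted objects have `tidy()`/`glance()` methods, and
`plot_cascade()`, `plot_block_spans()`, `plot_genotype_heatmap()` and
`autoplot()` give ggplot2 views of each result type.

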