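Package: panelsnp
Title: Cross-Species SNP Panel Design, Consensus Genotyping and Survival
    Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to design a targeted genotyping panel for a poorly
    characterized species by transferring disease-associated SNPs from a
    well-studied one, and to analyze the resulting cohort data.  The
    pipeline merges curated SNP association tables, maps SNP-centered
    windows across genomes through UCSC chain files, filters candidates by
    sequence conservation at the SNP site, prioritizes loci by UTR overlap,
    transcription-factor proximity and network hubness, assigns proxy SNPs
    via Gabriel D-prime haplotype blocks estimated from unphased genotypes,
    and emits panel target windows.  Downstream, it derives high-confidence
    variants from three-caller VCF consensus after left-alignment
    normalization, and runs a multi-stage AIC-guided Cox
    proportional-hazards variable selection with median risk-score
    stratification.  A synthetic-data module generates every input with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
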