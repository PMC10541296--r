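Package: apiscan
Title: Selection Scans and Environmental Association for Structured
    Honeybee Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for population-genomic scans in
    structured populations, built around the Japanese honeybee (Apis
    cerana japonica) study design of three diverged geographic regions
    plus admixture zones. Reads diploid genotypes from VCF and gene
    models from GFF3, applies minor-allele-frequency and missingness
    filters, performs LD pruning, genotype PCA and an ancestry-based
    exclusion rule for putative non-native individuals, computes windowed
    nucleotide diversity and pairwise FST (Weir-Cockerham and Hudson
    estimators), scans 10-kb windows with the population branch statistic
    (PBS and PBS_max) against an empirical null built from intergenic
    windows, runs a deterministic latent-factor genotype-environment
    association with genomic-control calibration and Benjamini-Hochberg
    FDR, and reports candidate genes with codon-level coding-effect
    classification. Includes a Balding-Nichols synthetic-data generator
    so the whole pipeline is testable without resequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
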