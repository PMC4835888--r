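Package: c4cnv
Title: Multiallelic C4 Copy-Number Genotyping and Case-Control
    Association from MLPA Peak Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for multiallelic copy-number analysis
    of the complement C4 locus from multiplex ligation-dependent probe
    amplification (MLPA) peak-height exports: control-probe ratio
    normalization and median scaling of probe dosages, integer copy-number
    calling with homozygous-deletion flagging and differential-bias QC,
    additive-coded case-control logistic association with covariate
    adjustment, stratification and conditioning on linked SNPs,
    DerSimonian-Laird random-effects meta-analysis across studies, and
    EM-based haplotype frequency estimation with per-haplotype copy-number
    characterization. Includes a synthetic-data generator that emulates the
    full observation model (peak heights, batch effects, disease status,
    linked haplotypes) so every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), metafor, vcfR, jsonlite
Config/testthat/edition: 3
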