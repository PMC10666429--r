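Package: rohkin
Title: Runs of Homozygosity, Robust Kinship and Founder-Event Dating for
    Small Whole-Genome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for whole-genome SNP analysis of small, deeply sequenced
    cohorts from isolated populations: VCF import with basic or advanced
    site filtering, union-of-sites cohort merging with missingness and exact
    Hardy-Weinberg quality control, per-sample heterozygosity and
    call-rate-stratified heterozygosity, minor-allele-frequency spectra,
    KING-robust pairwise kinship from genotype-concordance counts,
    sliding-window detection of runs of homozygosity (ROH) with sweeps over
    minimum segment length, ROH-based inbreeding (F_ROH) and parental
    relatedness, and dating of bottleneck and consanguinity (founder) events
    from ROH lengths via the exponential segment-length model. Includes a
    synthetic-cohort generator (pedigree gene-drop with recombination,
    planted autozygous tracts, genotyping error, missingness) that provides
    known truth for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
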