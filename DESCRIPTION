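Package: strmarker
Title: Reference-Free Discovery and Evaluation of Short-Amplicon
    Microsatellite Markers from Shotgun Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reference-free pipeline for discovering polymorphic
    short-amplicon microsatellite (STR) markers directly from unassembled
    shotgun reads of a few diploid individuals, aimed at panels usable on
    degraded non-invasive samples such as dung. Detects perfect di-, tri-
    and tetranucleotide tandem repeats in reads, clusters hits into loci by
    flanking-sequence identity, calls allele-length spectra and
    polymorphism across the sampled chromosomes, applies exclusion filters
    (repeat count, allele-size range, low-complexity or multi-copy flanks,
    contaminant similarity), designs short-amplicon primer pairs under a
    strict product-size cap, and validates them by in-silico PCR with
    mismatch-tolerant primer binding. Also computes the marker-panel
    statistics used to characterise such panels: allele frequencies,
    observed and (unbiased) expected heterozygosity, F_IS (simple and
    Weir-Cockerham), probability of identity for unrelated individuals and
    for full siblings, cumulative panel power, and paired-sample genotype
    concordance with allelic-dropout and false-allele classification. A
    synthetic-data module generates diploid genomes with planted STR loci,
    shotgun reads, and fecal-style genotype degradation so every stage can
    be tested against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    Biostrings,
    S4Vectors,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
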