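Package: karyosig
Title: Copy-Number Rearrangement Signatures in Tumor Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy toolkit for somatic copy-number signature analysis of
    tumor genomes profiled by array comparative genomic hybridization and
    shallow whole-genome sequencing. Calibrates gain/loss log2-ratio cutoffs
    from self-self control hybridizations, segments probe-level profiles by
    exact penalized least-squares changepoint search, calls arm- and
    chromosome-level aneuploidy, detects chromothripsis (oscillating
    segmental copy-number states) and breakage-fusion-bridge (terminal
    stair-step amplification) signatures, classifies loss-of-heterozygosity
    mechanisms, estimates mean telomere length from telomeric-repeat read
    content, normalizes telomerase (TRAP) and C-circle (ALT) assay signals,
    and aggregates per-tumor calls into cohort cross-tabulations and group
    contrasts. Includes a synthetic-data module that generates probe
    profiles, cohorts and read sets with known event structure so every
    detector can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    withr
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
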