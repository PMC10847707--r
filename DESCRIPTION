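Package: mmcascreen
Title: Melting-Curve Genotyping and Cohort Statistics for Newborn Hearing-Loss Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a multiplex melting-curve-analysis (MMCA) genotyping
    pipeline for a 20-variant newborn hearing-loss panel (GJB2, GJB3, SLC26A4,
    MT-RNR1): simulation of probe melt curves for arbitrary genotypes including
    mitochondrial heteroplasmy mixtures, signal processing from raw fluorescence
    to melt peaks (baseline removal, Savitzky-Golay smoothing, negative
    derivative, peak detection and refinement), calibrated delta-Tm window
    genotype calling, per-neonate screening categories combined with hearing
    screening trajectories, and cohort-level epidemiology (allele and carrier
    frequencies, contingency tests, diagnostic yield, random-effects
    meta-analysis of carrier proportions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
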