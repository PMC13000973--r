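Package: driftscan
Title: Drift-Calibrated Selection Scans for Evolve-and-Resequence Pool-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects selection in evolve-and-resequence (E&R) pool
    sequencing experiments with explicit calibration against genetic
    drift. Provides readers for PoPoolation2-style sync allele counts and
    experiment design tables; a forward Wright-Fisher simulator with
    regime-specific selection, per-generation effective population sizes,
    pool sampling and read-depth noise; analytic and simulated neutral
    null distributions for allele-frequency change and Hudson's FST with
    95th-percentile thresholds; pool-aware diversity statistics (pi,
    Watterson's theta, Tajima's D, expected heterozygosity, windowed and
    bootstrapped); a replicated Cochran-Mantel-Haenszel test with a
    drift-inflated variance; Lindley local-score region calling with
    Gumbel significance thresholds; temperature-by-regime classification
    of allele-frequency shifts (global, conditional, antagonistic
    pleiotropy); and consensus candidate-interval calling with gene
    intersection and GO enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    data.table,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
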