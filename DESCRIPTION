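Package: niptscreen
Title: Simulation and Z-Score Calling for Cell-Free DNA Prenatal Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for shallow whole-genome-sequencing noninvasive prenatal
    testing (NIPT) analysis: simulation of maternal-plasma cell-free DNA
    bin-count cohorts with known fetal truth, three-step GC-bias correction
    (LOESS, intra-run median normalization, quadratic residualization),
    reference-panel z-score aneuploidy calling with a gray zone and a fetal
    fraction gate, chromosome-Y fetal fraction estimation, Stouffer combined-Z
    calling of subchromosomal copy-number variants in 1-Mb windows, and
    screening-performance evaluation (PPV, NPV, sensitivity, specificity,
    chi-squared group comparisons, indication-stratified tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
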