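Package: telosperm
Title: Sperm Telomere Length, Telomere Genetic Scores, and Semen-Quality
    Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the relationship between telomere length and
    semen quality. Implements relative quantification of sperm telomere
    length from qPCR cycle-threshold data (per-plate standard curves,
    triplicate quality control, efficiency-corrected Pfaffl ratios against
    a 5 ng calibrator), genotype quality control for an 11-SNP telomere
    panel (call-rate filtering, Hardy-Weinberg tests, duplicate
    concordance), construction of unweighted, weighted and
    missingness-scaled telomere genetic scores, WHO-percentile ABCD
    composite scoring of semen parameters, and a full association scan
    (linear models adjusted for age and smoking, plate random effects for
    telomere outcomes, additive and codominant SNP codings, quintile
    exposures, Bonferroni correction). A synthetic cohort generator with
    the same statistical structure supports calibration and power studies
    without access to individual-level data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
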