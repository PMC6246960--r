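Package: ctdnaconcord
Title: Tumor-Plasma Concordance and Survival Analysis for Circulating Tumor DNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested, reusable pipeline for liquid-biopsy analysis of
    matched tumor-plasma samples. Detects tumor-identified variants in
    plasma cell-free DNA with UMI and positional read-family consensus
    rules and an amplicon binomial caller, quantifies circulating tumor
    DNA from droplet digital PCR counts by Poisson statistics (mutant
    allele frequency and copies per mL plasma), tabulates tumor-plasma
    concordance stratified by stage, tissue and platform, and stratifies
    baseline ctDNA for survival with Kaplan-Meier curves, log-rank tests,
    a maximally selected rank-statistic cut point and univariate Cox
    proportional-hazards models. Includes synthetic cohort and read
    simulators so the whole pipeline can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    survival,
    Rsamtools,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
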