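Package: lipidald
Title: Plasma Lipidomics Analysis for X-Linked Adrenoleukodystrophy Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for untargeted and targeted plasma lipidomics in X-linked
    adrenoleukodystrophy (ALD). Expands generic lipid-class formulas over
    radyl-chain grids into sum-composition species with monoisotopic masses
    and adduct m/z catalogs; annotates LC-MS feature tables by accurate mass
    with ppm tolerance; converts peak areas to semi-quantitative abundances
    via class internal standards and to targeted isotope-dilution
    concentrations; stratifies patient cohorts by cerebral disease, adrenal
    insufficiency and spinal-cord severity; runs normality-routed
    differential-abundance statistics with FDR control, volcano
    classification, chain-length/unsaturation LOESS profiling, PCA/PLS-DA,
    X-inactivation correlation and post-transplant biomarker trend fitting.
    Includes a seeded synthetic-data generator reproducing the statistical
    structure of an ALD cohort so the full pipeline is testable end to end.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
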