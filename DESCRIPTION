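Package: bcaamvmr
Title: One-Sample Multivariable Mendelian Randomization for Correlated
    Metabolite Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation toolkit for one-sample multivariable
    Mendelian randomization (MVMR) of highly correlated exposures, modelled
    on phenome-wide analyses of the branched-chain amino acids leucine,
    isoleucine and valine.  Provides a synthetic-cohort generator with
    shared and exposure-specific genetic loci and a latent confounder,
    phenotype curation (inverse rank-normal transformation, outlier and
    case-count filters, phecode aggregation), per-variant association scans
    with genomic control and stepwise conditional signal selection,
    cross-fitted polygenic-score instruments, two-stage least squares and
    instrumental-variable probit estimation with Sanderson-Windmeijer
    conditional F diagnostics, univariable Mendelian randomization and
    observational comparators, and cross-method concordance reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    e1071,
    jsonlite,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
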