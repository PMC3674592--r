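Package: grstransfer
Title: Transferability of Weighted Genetic Risk Scores Between Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether a weighted genetic risk score (GRS) built
    from susceptibility markers discovered in one population transfers to
    another. Reads PLINK-style text or tabular genotype data, applies standard
    genotype quality control (sample missingness, SNP call rate, exact
    Hardy-Weinberg equilibrium test), computes per-cohort allele frequencies
    and cross-population minor-allele-frequency comparisons, scores
    individuals by the sum of log-odds-ratio-weighted risk-allele counts with
    group-frequency imputation of missing genotypes, fits the case-control
    logistic association of the score, and decides via an empirical
    subsampling null distribution drawn from a large reference cohort whether
    the score's effect in a small target cohort is compatible with the
    reference. Includes a genotype simulator (Hardy-Weinberg sampling,
    logistic disease model, case-control ascertainment, Balding-Nichols
    population divergence) so the whole pipeline is testable from code.
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
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
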