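Package: paleostack
Title: Population-History Inference from Ancient DNA Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for the statistical population-genetics stack used in
    ancient-DNA studies of population continuity and turnover: pseudohaploid
    genotype calling with an empirically stratified error model, unbiased
    f2/f3/f4 statistics with weighted block jackknife standard errors,
    qpWave-style cladality tests and qpAdm-style admixture-weight estimation,
    admixture dating from the exponential decay of ancestry covariance with
    genetic distance, runs-of-homozygosity profiling with likelihood-based
    effective population size estimation, pairwise-mismatch kinship
    classification, inverse outgroup-f3 neighbor-joining trees, and
    radiocarbon date combination and calibration. A synthetic-data module
    generates every input type with known ground truth so the full pipeline
    is testable without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    phytools,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
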