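Package: alleleprime
Title: Allele-Aware Analysis of Germline-Targeting Vaccine Priming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how immunoglobulin heavy-chain variable (IGHV)
    gene allelic variation shapes B cell responses to germline-targeting
    vaccines. Quantifies per-allele naive-repertoire usage from UMI-tagged IgM
    rearrangement tables, fits competing quasi-Poisson count models of
    bnAb-precursor B cell frequencies with identity-link additive allele
    effects and ranks them by QAICc, derives genotype means and delta-method
    allele ratios, assigns germline IGHV1-2 alleles to B cell receptor reads
    with ambiguity-aware 0.5/0.5 counting, and compares antibody affinities
    with random-intercept mixed models using Satterthwaite degrees of freedom.
    A synthetic-trial generator reproduces the statistical structure of a
    two-dose, genotype-stratified trial so the full pipeline can be exercised
    and validated without access to participant-level data.
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
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    lmerTest,
    lme4,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
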