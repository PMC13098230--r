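Package: fmtrewire
Title: Multi-Omic Response Screening and Network Rewiring Analysis for
    Fecal Microbiota Transplantation Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing fecal microbiota transplantation (FMT)
    cohorts in inflammatory bowel disease: clinical response and remission
    classification from Mayo and CDAI activity scores, alpha-diversity
    estimation (observed richness, Chao1, ACE, Shannon, Simpson dominance),
    a three-criterion screen for FMT-response-associated taxa and
    metabolites with Benjamini-Hochberg false discovery rate control,
    ternary host-microbe-metabolite Spearman correlation networks with a
    baseline-to-post edge-persistence (rewiring) statistic, PCA and PLS-DA
    with variable-importance-in-projection scores, and a paired donor-patient
    synthetic cohort generator with planted ground truth for end-to-end
    validation of every stage.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
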