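Package: phenetwork
Title: Phenome-Wide Disease Networks from PheWAS Summary Statistics and
    Cohort Disease Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a SNP- and LD-block-based phenome-wide disease network
    (PheNet) from PheWAS summary statistics, with link weights derived from
    summed geometric means of absolute effect sizes. Overlays patient-level
    comorbidity (Matthews correlation coefficient and one-sided Fisher exact
    tests with Bonferroni control) to extract a co-occurrence-validated
    sub-network, characterises both networks with label-permutation null
    models (neighbourhood homogeneity H-scores, category-interaction
    Z-scores, Louvain modules), and infers a directed disease-trajectory
    network from event sequences via covariate-adjusted logistic models and
    binomial majority-ordering tests. A synthetic-data module generates
    summary statistics, linkage-disequilibrium structure, and cohorts with
    planted genetic links, comorbidities and temporal orderings so the whole
    pipeline can be validated against a known ground truth.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
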