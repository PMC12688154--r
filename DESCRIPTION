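Package: stabshift
Title: Feature-Based Prediction of Protein Stability Changes upon Point Mutation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A framework for predicting the change in protein folding free
    energy (DDG, kcal/mol) caused by single amino-acid substitutions.
    Provides parsing, merging and antisymmetric reverse-mutation augmentation
    of mutation datasets; structure-derived featurization (spatial shells,
    solvent accessibility, secondary structure, residue interaction networks,
    pharmacophore counts, Gaussian-network-model fluctuations, evolutionary
    profile scores); pair-level cross-validation with recursive feature
    elimination over a gradient-boosted tree regressor; and an
    antisymmetry-aware evaluation suite including maximum mean discrepancy
    and Steiger's test for dependent correlations. All inputs required for
    testing are generated synthetically.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    xgboost,
    igraph,
    MASS,
    bio3d,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
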