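Package: imicr
Title: Integration of Metatranscriptomics into Community Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constraint-based prediction of individual growth rates and
    metabolite interactions in microbial communities from metatranscriptomic
    data. Member genome-scale metabolic models are assembled into a
    compartmentalized community model with a shared extracellular space;
    gene expression (TPM) is converted into reaction-level correction
    factors through gene-protein-reaction rules and imposed as scaled flux
    bounds with penalized relaxation variables. A single linear program
    balances community growth against bound relaxation through one
    balancing factor, selected automatically by sensitivity analysis or
    cross-validation. Downstream analyses include growth-rate variability,
    minimum flux-sum quantification of exchanged metabolites, key-reaction
    identification by Spearman correlation with Benjamini-Hochberg
    correction, and in silico reaction knockouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
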