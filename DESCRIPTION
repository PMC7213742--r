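Package: gemsemble
Title: Ensembles of Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compact representation and analysis of ensembles of genome-scale
    metabolic network reconstructions. A set of model variants is stored as a
    single base model plus per-member feature states, so an ensemble occupies
    little more space than one model. Flux balance analysis, flux variability
    analysis, and single gene or reaction deletions are lifted to ensemble
    scale with member-indexed tibble results. Ensembles are generated from
    growth phenotype data by iterative, condition-shuffled gap-filling against
    a universal reaction database, and ensemble simulation outputs are compared
    with paired statistics and mined with random-forest feature importance to
    prioritise model curation. Models are read and written as SBML Level 3 with
    the flux-balance-constraints extension or as a documented JSON dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    pracma,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xml2
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
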