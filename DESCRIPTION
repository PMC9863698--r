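Package: fisar
Title: Fluorine Positional Isomer SAR Sets, Activity Cliffs and Matched
    Molecular Pair Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines structure-activity relationships of fluorine positional
    isomers in compound potency data. Standardizes heterogeneous potency
    measurements (Ki, IC50, EC50 and their log forms) to a common negative
    decadic logarithm scale, groups compounds that differ only in the position
    of fluorine substitution into target-based analog sets via a defluorinated
    scaffold key, detects activity cliffs from within-set potency differences,
    computes transformation-size-restricted single-cut matched molecular
    pairs, and exports a multi-layer matched-molecular-pair network for
    visualization in Cytoscape. Includes a synthetic library generator with a
    ground-truth manifest so the whole pipeline is testable without database
    access, and a small utility for comparing computed binding free energy
    rankings against experimental potency rankings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    stringr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
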