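Package: metamapr
Title: Mapping Between Metabolite Identifiers in Metabolic Network
    Reconstructions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An offline toolkit for cross-referencing metabolite identifiers
    (names, standard InChIKeys, ChEBI, HMDB, KEGG Compound, PubChem Compound
    and LIPID MAPS identifiers) in genome-scale metabolic network
    reconstructions. Implements and contrasts two mapping strategies --
    standard-InChIKey joins over a quality-checked cross-reference store, and
    metabolite-mask (merged identifier group) closure queries -- together with
    additive confidence-weighted multi-identifier mapping, a
    hits-and-matches evaluation score for identifier-mapping tests, an
    annotation-update pipeline with hydrogen-insensitive formula checking and
    neutral-form preference, and a seeded synthetic fixture generator for
    benchmarking all of the above without network access.
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
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
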