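Package: chemophylo
Title: Phylogenetic Signal in Binary Chemical Diversity and Bioactivity Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing whether plant chemical diversity and
    bioactivity carry phylogenetic signal. Implements the Fritz-Purvis D
    statistic for binary traits with permutation and Brownian-threshold
    nulls, Mantel matrix-permutation tests correlating patristic distances
    with binary squared Euclidean chemical-profile distances at species and
    genus level, binary trait coding of alkaloid-type and bioassay data with
    exclusion and reconciliation rules, and a synthetic-study generator for
    calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
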