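Package: sterolome
Title: Pollen Sterolome Quantification, Composition and Phylogenetic Signal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for pollen sterol metabolomics: filtering
    and internal-standard quantification of LC-MS feature tables, two-level
    sterol annotation by accurate mass and retention time, compositional
    summaries (proportions, Simpson diversity, Bray-Curtis dissimilarity,
    outlier screening, B-ring and carbon-class grouping), permutation-based
    multivariate statistics (NMDS, PERMANOVA with pairwise and dispersion
    tests, indicator-value analysis, Kruskal-Wallis with Dunn post hoc and
    Benjamini-Hochberg correction), phylogenetic-signal estimation
    (Blomberg's K, Pagel's lambda) on sterol traits, and scoring of pollen
    profiles against honeybee sterol requirements. A synthetic-data
    generator produces trees, compositional profiles with tunable
    phylogenetic signal, and MS-level sample tables with internal standard,
    QC dilution series and blanks, so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    phytools,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
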