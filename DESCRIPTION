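Package: planktonscape
Title: Community Ecology of Reservoir Plankton: Diversity, Water Quality,
    Networks and Assembly Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for 18S amplicon surveys of eukaryotic
    plankton in lakes and reservoirs. Computes alpha diversity (Shannon-Wiener,
    Margalef) and Bray-Curtis beta diversity with NMDS ordination and
    PERMANOVA; scores water quality with the Chinese trophic level index (TLI)
    and its nutrient-status grades; fits distance-decay regressions and Mantel
    tests against geographic and environmental distance; runs DCA gradient
    checks and redundancy analysis with permutation significance; builds
    correlation-based co-occurrence networks with module detection and Zi-Pi
    key-species classification; and infers assembly mechanisms with the Sloan
    neutral community model and a modified stochasticity ratio. Includes a
    synthetic-data generator emulating a 6-site by 3-season by 3-replicate
    reservoir survey with known ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    xml2,
    yaml
Suggests:
    biomformat,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
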