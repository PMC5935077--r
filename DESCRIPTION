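Package: marshtransplant
Title: Reciprocal-Transplant Analysis of Salt Marsh Sediment Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing reciprocal sediment-transplant experiments
    with 16S rRNA gene OTU tables: rarefaction and OTU-table filtering,
    Bray-Curtis dissimilarity, Mantel tests and matrix regressions,
    non-metric multidimensional scaling, a directional indicator-OTU
    regression scan against origin-to-destination environmental change with
    Bonferroni family-wise error control, and a formal classifier of
    transplant outcomes (no change, total adoption, host shift, random
    shift). Includes a Dirichlet-multinomial community simulator that
    generates fully factorial transplant designs with known ground truth so
    the whole pipeline can be exercised and validated without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
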