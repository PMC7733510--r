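Package: engraftr
Title: Quantifying Donor Microbiota Engraftment in Gnotobiotic Animal Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for scoring the engraftment of human donor gut microbiotas in
    human microbiota-associated (HMA) animal models from 16S rRNA amplicon
    sequence variant (ASV) count tables. Identifies each donor's core inoculum
    community (ASVs detected in every inoculum aliquot), classifies the fate of
    every core ASV in recipient hosts over a longitudinal sampling schedule
    (colonizer, persistent colonizer, donor-like abundance maintainer),
    tabulates cross-host colonization contingencies and taxonomic roll-ups,
    and provides supporting alpha/beta diversity analyses (Shannon index,
    Bray-Curtis, unweighted UniFrac, principal coordinate analysis). A
    seed-reproducible synthetic colonization simulator with known ground truth
    makes every stage of the pipeline testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    DESeq2,
    jsonlite,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
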