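Package: neuroquant
Title: Quantitative Anatomy of Cortical Interneurons: Marker Mining,
    In Situ Enrichment, Bouton Morphology and Nanoscale Point Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for the quantitative procedures used
    to profile CB1/CCK-positive GABAergic interneurons: single-cell RNA-seq
    marker gating with per-cell copy-number normalization and Grubbs outlier
    control, candidate-gene screening and Spearman correlation analysis;
    fluorescent in situ hybridization enrichment scoring with region-specific
    strong/weak classification and co-expression summaries; bouton
    distribution index computation for perisomatic versus dendritic targeting
    classification; and single-molecule localization (STORM) point-pattern
    analysis with ROI filtering, density normalization, Ripley's K/L with
    isotropic edge correction, far-apart ROI pooling and CSR envelopes.
    Seeded synthetic-data generators provide ground-truthed inputs for every
    stage.
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
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    knitr,
    nortest,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
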