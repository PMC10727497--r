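Package: orzone
Title: Zonal Olfactory Receptor Choice: Simulation and Multi-Omic Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analyses of dorsoventral (zonal) olfactory receptor (OR) gene
    regulation in the mouse olfactory epithelium: zonal annotation of the OR
    repertoire and of genomic bins, single-cell polygenic OR profiling,
    heterochromatin gene-body gradients from coverage tracks, zone-annotated
    Hi-C trans-contact aggregation, single-cell 3D-structure OR-compartment
    detection, and spatial-spot zonal assignment. A stochastic generative
    model of singular OR choice ("two opposing rheostats": a dorsoventral
    gradient of polygenic transcription pruned by a dorsoventral gradient of
    heterochromatic silencing) emits synthetic data for every modality, so
    each analysis can be validated against the latent state that produced it.
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
    methods,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
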