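Package: pseudolign
Title: Pseudotemporal Integration of Unpaired Single-Cell Transcriptomic and
    Proteomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns unpaired single-cell RNA-Seq and single-cell proteomics
    (scp-MS) datasets on a shared pseudotemporal axis. Provides quality-control
    filters and normalization for both modalities, k-nearest-neighbor
    imputation of missing protein intensities, cell-cycle annotation (FUCCI
    reporter gating and marker-gene scoring), Wilcoxon differential expression
    and nested-linear-model likelihood-ratio ranking of stimulus markers,
    diffusion-map pseudotime per modality, anchor-based alignment of the two
    pseudotemporal orders, and joint standardized transcription-translation
    profiles with confidence bands, response-onset and lag estimates. A
    synthetic-data generator produces coupled mRNA/protein datasets with known
    ground truth (cell-cycle periodicity, heterogeneous hypoxia response
    delays, first-order protein kinetics, abundance-biased detection) so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
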