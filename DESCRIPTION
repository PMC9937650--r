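Package: mblearn
Title: Mushroom Body Circuit Mining and Memory Dynamics for Second-Order Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how dopaminergic subsystems of the Drosophila
    mushroom body interact during second-order conditioning. Mines
    neuPrint-style connectome tables for feedforward MBON -> interneuron ->
    DAN pathways (threshold screening, one/two-hop enumeration, transmitter
    annotation, hub ranking), computes four-field olfactory-arena behavioural
    statistics (performance index with reciprocal averaging, area-normalised
    radial index, upwind displacement), derives memory-dynamics indices from
    performance-index curves and decomposes composite memory curves into
    non-negative combinations of driver curves in log-odds space, and
    quantifies spike trains and fluorescence traces (Gaussian-kernel rates,
    evoked spike counts, background-subtracted dF/F). Ships deterministic
    synthetic-data generators with planted ground truth so the full pipeline
    is testable without any external download.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
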