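Package: modulefish
Title: Gene-Module FISH Panel Design, Evaluation and Image Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs gene-module panels for multiplexed fluorescence in situ
    hybridization (module-FISH) assays from a single-cell RNA-seq reference,
    scores them with a probe-weighted signal model (Signal Gain and Signal
    Specificity Ratio), simulates module-level re-clustering against reference
    annotations, and quantifies multi-round module fluorescence images into
    cell-by-module intensity matrices with downstream crosstalk, cortical-depth
    and cell-proximity statistics. Includes a synthetic-data generator with
    planted cell types, co-expressed gene modules and rendered tissue images so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    EBImage,
    tiff,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
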