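Package: webfoot
Title: Ancestral State Reconstruction and Spatial Entropy of Webbed-Foot
    Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two comparative analyses of webbed-foot evolution and
    development in waterbirds. The first is maximum-likelihood ancestral
    state reconstruction of a multistate foot-morphology character under the
    one-parameter symmetric Mk ("Mk1") model on an arbitrary rooted
    phylogeny (polytomies and missing tip states allowed), including rate
    estimation by bounded one-dimensional ML, marginal per-node state
    probabilities computed by an up-down pruning pass, and counting of
    independent character origins. The second is a spatial entropy statistic
    quantifying the disorderliness of proliferating-cell distributions in
    binarised histological section images: Otsu thresholding of paired
    nuclei/proliferation channels, maximum section width measurement, a
    pairwise log-distance entropy normalised by section width, and the
    nested section/individual/species averaging scheme. A synthetic-data
    module generates Mk-evolved characters on simulated trees and rendered
    paired-channel section images from controlled point processes with known
    ground truth, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    phytools,
    tiff,
    EBImage,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
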