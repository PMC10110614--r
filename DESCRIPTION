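Package: octava
Title: Arterial-Venous Area Segmentation and Perfusion Intensity Analysis for OCTA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for differential artery-vein analysis of en face optical
    coherence tomography angiography (OCTA) images. Converts sparse manual
    artery/vein vessel gradings into dense arterial-venous area (AVA) maps by
    distance-weighted k-nearest-neighbour label propagation, trains a
    U-Net-style encoder-decoder with parallel dilated convolutions (AVA-Net)
    under a soft intersection-over-union loss to predict AVA maps directly
    from OCTA intensity images, and quantifies seven whole-image biomarkers:
    arterial/venous area percentages and their ratio, and total, arterial and
    venous perfusion intensity densities with their ratio. Includes fovea and
    layer-indicator exclusion masks, segmentation evaluation metrics,
    group-comparison statistics with Bonferroni correction, and a seedable
    synthetic OCTA scene and cohort simulator for end-to-end testing without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    tiff,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
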