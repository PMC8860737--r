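Package: hepazone
Title: Detection of Portal Fields and Central Veins and Zonated
    Quantification in Liver Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tile-based detection of portal fields (PF) and central veins
    (CV) in whole-slide images of liver tissue with a pluggable detector
    backend, merging of tile-wise detections into slide-level points,
    class-stratified point-in-box evaluation metrics, tissue masking
    (Otsu threshold, contour-area filtering, morphological smoothing),
    tessellation of tissue into lobuli and zones via a portality field
    and preflooded watershed transform, lobulus size metrics, stain
    deconvolution (optical density, Macenko stain vectors) and zonated
    quantification of stain signals.  Includes a synthetic lobular-tissue
    phantom generator providing ground truth for closed-loop testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    tiff,
    optparse
Config/testthat/edition: 3
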