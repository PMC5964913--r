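Package: pelviseg
Title: Key-Frame Guided Marker-Watershed Segmentation of Pelvic CT Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi-automated bone segmentation for pelvic CT slice sequences.
    Slices are windowed to 8-bit, stripped of table artifacts via a
    largest-component body mask, and cropped to a sequence-global bounding
    box.  Key frames -- slices where the bone topology changes -- are
    selected by a two-stage procedure (pixel-difference candidates over
    wavelet-masked "interesting images", then mutual-information and
    normalized-correlation filtering).  Expert-editable bone masks on key
    frames are propagated to every slice: the matched key frame's foreground
    and background are thinned to one-pixel skeletons, the skeletons are
    imposed as the only regional minima of the slice's Sobel gradient
    magnitude, and a marker-controlled watershed floods the result.
    Includes a synthetic CT phantom generator with ground-truth masks and
    overlap/contour-deviation evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
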