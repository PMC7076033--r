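Package: osteorient
Title: Orientation and Dynamics Metrics for Intravital Bone Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification of collagen-fiber and osteoblast orientation and
    of cell dynamics in two-photon images of BMP-2-induced ectopic bone.
    Implements the collagen fiber orientation index (CFOI) from windowed 2D
    Fourier angular spectra of second-harmonic-generation images, cell
    eccentricity and angular radius profiles from labeled masks, the
    fiber-cell orientation correlated index (OCI) by circular
    cross-correlation at a 90 degree shift, track-based mean cell velocity,
    and the osteoclast cell deformation index (CDI) from mask pairs. A
    synthetic-image generator with known ground truth (von Mises fiber
    orientations, rasterized elliptical cells, random-walk tracks,
    deforming masks) supports validation without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    ggplot2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
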