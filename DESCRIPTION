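Package: cscmorph
Title: Morphometry and Stoichiometry of Rosette Cellulose Synthesis Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative morphometry of six-lobed rosette cellulose synthesis
    complexes (CSCs) imaged top-down by freeze-fracture transmission electron
    microscopy. Provides a seeded generator of synthetic micrographs with
    ground truth; particle metrology (smallest-enclosing-circle and hexagon
    perimeter/diameter estimates, lobe polygon areas, opposite-lobe spacings,
    summary tables); reference-free 2D alignment, stability-filtered k-means
    classification and class averaging; lobe triangularity scoring by
    equal-area triangle/disc intersection-over-union; membrane-plane
    cross-sectional footprints of atomic models as unions of van der Waals
    disks, with Gaussian blurring, isosurface areas, geometric Cn oligomer
    packing and six-fold assemblies; and the comparison stage that calls the
    per-lobe cellulose synthase (CESA) stoichiometry by matching oligomer
    footprint areas to imaged lobe areas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    bio3d,
    tiff,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
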