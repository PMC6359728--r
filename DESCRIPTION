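Package: msmrec
Title: Mutual Subspace Method Recognition of Spray Areas in Aerial Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Image-set classification of aerial crop and orchard imagery
    into spray and non-spray areas using the mutual subspace method (MSM).
    Class subspaces are learned by principal component analysis of 8x8
    grayscale pattern vectors; similarity between image sets is measured by
    canonical (principal) angles between subspaces.  The package covers the
    full pipeline: a synthetic aerial-scene generator with controllable
    class separability and temporal correlation, frame extraction and
    preprocessing (grayscale conversion, area-average resizing,
    vectorization, noise-frame removal), subspace fitting and canonical
    angle computation, an offline first-half/last-half train-test protocol,
    an online sliding-window stream classifier, and confusion-matrix
    accuracy reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, png, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
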