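Package: rzcpurity
Title: Quantitative Purity Analysis for Rate-Zonal Centrifugation of DNA Origami
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies the purity of DNA origami nanostructure preparations
    after rate-zonal centrifugation from atomic force microscopy (AFM) height
    maps and density-gradient photographs. Decomposes the AFM pixel-height
    distribution into mica, staple-strand and origami fractions by least-squares
    fitting of a three-component Gaussian mixture cumulative distribution
    function; detects rod-shaped six-helix-bundle nanotubes, measures their
    contour lengths by skeletonization, and classifies monomers versus dimers by
    length; estimates standard errors of binary content fractions with a
    half-subset (without-replacement) bootstrap backed by a closed-form
    hypergeometric oracle; and scores density-gradient reproducibility from
    depth-intensity profiles. Includes seeded synthetic-data generators that
    emulate the AFM scenes, particle length samples and gradient profiles the
    analysis assumes, so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    tibble,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
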