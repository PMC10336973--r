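Package: aimcharge
Title: Neural-Network Estimation and Equilibration of Real-Space Atomic Charges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates well-behaved real-space (QTAIM-style) partial atomic
    charges for organic molecules. Atom-centered symmetry functions turn XYZ
    geometries into rotation- and translation-invariant atomic environment
    vectors, one feed-forward neural network per chemical element maps those
    descriptors to atomic charges, and a family of charge-equilibration
    kernels redistributes the residual molecular charge so that the corrected
    atomic charges sum exactly to the molecular charge. Includes a trainer for
    tailor-made per-element models from extended XYZ data, error-distribution
    statistics, prediction-error metrics, and a synthetic CHON fixture
    generator with analytic reference charges so the full pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
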