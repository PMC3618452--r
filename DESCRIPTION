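Package: nmropls
Title: Bucketing, OPLS-DA and Pathway Over-Representation for 1H-NMR
    Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Differential analysis of two-group 1H-NMR metabolomics
    studies: synthetic cohort simulation with known ground truth,
    0.01-ppm spectral bucketing with exclusion regions and constant-sum
    normalization, per-bin Student's t-tests with Storey-Tibshirani
    q-values, single-response OPLS-DA fitted by NIPALS with orthogonal
    signal correction (R2X, R2Y, k-fold Q2, VIP, back-scaled
    coefficients), hold-out classification validation, metabolite-level
    fold-change aggregation through a chemical-shift library, and
    Fisher's exact pathway over-representation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
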