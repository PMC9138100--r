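Package: chemoscore
Title: Chemometric Ranking and Sensitivity Analysis for Plant Extract Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screening plant extract preparations across panels of
    phytochemical and bioactivity assays. Reduces raw spectrophotometric
    readings to betacyanin and betaxanthin contents (von Elbe correction
    equations), DPPH percent inhibition and standard-curve equivalents;
    ranks extracts by weighted standard scores built on per-variable min-max
    normalization; performs correlation-matrix principal component analysis
    with per-variable contributions; and fits a single-hidden-layer
    perceptron surrogate whose input-output influence is decomposed with the
    Yoon weight-path method. Includes a synthetic-data generator for
    correlated assay matrices with not-detected blocks, absorbance panels
    with known pigment truth, and teacher networks, so the whole pipeline is
    testable without laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
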