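Package: slicetox
Title: Drug-Response Quantification for Ex Vivo Tumor Slice Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image quantification and dose-response analysis for ex vivo
    organotypic tumor slice chemosensitivity assays. Implements the
    fluorescence readouts used in breast tumor slice cultures: cytokeratin
    positive tumor area by morphological-reconstruction hole filling and
    Sobel edge segmentation, EdU-positive cell counting with size filters,
    and TUNEL/DAPI pixel co-localization (Otsu thresholds, Manders-style
    overlap fraction). Provides the FAC (5-fluorouracil, doxorubicin,
    4-hydroperoxycyclophosphamide) dilution-series design, per-tumor
    threshold-dilution calling with sensitive/intermediate/resistant
    classification, cohort aggregation, and a seeded synthetic-microscopy
    generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
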