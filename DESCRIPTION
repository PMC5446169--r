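Package: ihcquant
Title: Rule-Based Quantification of DAB Immunohistochemistry Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated quantification of diaminobenzidine (DAB) stained
    immunohistochemistry images using rule-based RGB pixel classification.
    Separates background from tissue and DAB-positive from
    hematoxylin-counterstained pixels, quantifies stain area fractions for
    regions of interest and for large whole-block scans processed as tiles,
    de-arrays tissue microarray (TMA) slides into their design grid and
    scores each core, and compares per-sample stain fractions and marker
    ratios (such as the Ki-67/CD31 proliferative vascular index) between
    histologic grade groups. Includes a synthetic image generator that
    produces rule-consistent fixtures with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
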