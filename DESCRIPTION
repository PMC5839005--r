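Package: tilquant
Title: Quantification and Validation of CD8+ Tumor-Infiltrating
    Lymphocytes in Brightfield IHC Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rule-based image analysis for chromogenic CD8
    immunohistochemistry: color-deconvolution stain unmixing, three-stage
    CD8+ lymphocyte detection with morphological acceptance filtering,
    oriented-bounding-box classification of elongate lymphocytes,
    tumor-center and invasive-margin region construction from pathologist
    annotations, a CD8/PD-L1 dual-stain mode, and a pathologist-concordance
    validation framework (cell matching, F1, Lin concordance correlation
    with bootstrap lower confidence bounds, McBride agreement categories)
    together with cohort-level density statistics. A seeded synthetic slide
    generator with exact planted ground truth makes the whole pipeline
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    pracma,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
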