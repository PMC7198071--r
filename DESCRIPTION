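Package: idsnet
Title: Interleaved DenseNet with Squeeze-and-Excitation Networks for
    Histopathology Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Binary classification of breast-tumour histopathology images
    (benign vs malignant) with a densely connected convolutional trunk whose
    transition-layer outputs are re-weighted by squeeze-and-excitation
    channel attention and aggregated by per-depth classification branches
    into a single fully connected head. Provides the building-block
    operations (dense blocks, transition layers, SE modules, classification
    branches), model assembly and parameter accounting, BreakHis-style data
    handling (filename parsing, manifests, stratified and patient-disjoint
    splits, rotation/mirror augmentation), a staged-learning-rate Adam
    training loop, patient-level and image-level recognition-rate metrics
    with per-magnification breakdowns, and a deterministic synthetic
    dataset generator so the whole pipeline is testable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
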