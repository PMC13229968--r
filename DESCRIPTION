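Package: phytoken
Title: Tokenization, Procedural Simulation and Evaluation of Organ-Level
    Plant Architectures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with organ-level functional-structural plant
    architectures of vegetative cowpea. Provides a documented XML dialect for
    the shoot/phytomer/internode/petiole/leaf hierarchy, a lossless
    (post-quantization) integer token codec with a 228-token vocabulary, a
    seeded procedural growth simulator emulating phytomer-based daily
    vegetative growth from day 0 to day 39, forward-kinematic 3-D
    reconstruction for trait extraction (plant height, leaf count and area,
    leaf inclination distributions), and the sequence- and distribution-level
    evaluation metrics used for architecture generation studies (token
    accuracy, weighted F1, corpus BLEU-4, ROUGE-L, one-dimensional
    Wasserstein distance, and regression error summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
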