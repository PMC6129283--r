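Package: ontoscore
Title: Ontology-Based Scoring of Sample Similarity for Batch Effect Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a per-sample ontology score: the rank correlation between
    observed sample-to-sample similarities derived from a PCA embedding of a
    gene expression matrix and expected similarities derived from a cell-type
    ontology (ancestor-set Jaccard or cosine similarity over the subclass
    hierarchy). Includes randomized- and fixed-ontology reference models,
    Gaussian noise injection for simulating artificial batch effects, a
    baseline location-scale batch adjuster with a pluggable adjuster registry,
    control-gene probabilities from standard-deviation ranks, and a synthetic
    data generator producing toy ontologies and expression matrices with
    ontology-consistent similarity structure.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
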