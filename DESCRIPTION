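Package: coexsub
Title: Molecular Subtyping from Subtype-Specific Co-Expression Modules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies tumour samples into molecular subtypes using
    network-level features rather than raw gene expression. For each
    subtype it builds a subsampling-averaged Spearman co-expression
    network, partitions the network into modules by soft-thresholded
    weighted adjacency and hierarchical clustering, ranks modules by how
    specific their co-expression pattern is to that subtype, and extracts
    the most subtype-specific edges. Each sample is then converted into a
    vector of correlation perturbations measured by adding it to
    per-subtype reference networks, and a small feed-forward neural
    network with vote aggregation performs the multi-class prediction.
    Includes a seeded synthetic-data generator with planted co-expression
    blocks for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
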