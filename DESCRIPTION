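Package: gmindex
Title: Gene Marker Indices for In Situ Stress Detection from Metatranscriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects environmental stress signatures of a target organism in
    field metatranscriptomes by comparison with laboratory stress experiments.
    Stress-regulated and constantly expressed marker transcripts are selected
    from replicated lab count tables, Gene Marker Indices (min-max normalized
    expression ratios) are evaluated on field samples, and whole marker-gene-set
    expression profiles are compared between lab and field via Bray-Curtis
    dissimilarity, Ward.D2 hierarchical clustering and a similarity-profile
    (SIMPROF) permutation test with recursive significance pruning. A synthetic
    data generator with known regulation labels and latent field stress levels
    makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
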