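Package: heatloop
Title: Heat-Stress Chromatin Architecture and Enhancer-Promoter Loop Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrative analysis of 3D chromatin reorganization under heat
    stress: binned Hi-C/C-Hi-C/HiChIP contact matrices with iterative
    balancing, distance-decay and observed/expected transforms, A/B
    compartment calling by correlation-map PCA, saddle plots and compartment
    strength, P(s) scaling curves for chromosome arms and pericentromeres,
    cumulative-binomial interaction calling with Fisher differential tests,
    promoter-/RE-centric hub detection and aggregate peak analysis (APA),
    proximal/distal regulatory-element classification with enhancer chromatin
    signatures, k-means and self-organizing-map time-course clustering, PWM
    motif scanning and enrichment, TF-network inference, and quantification
    of 3C-qPCR and dual-luciferase validation assays. A seeded synthetic-data
    generator with planted ground truth makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
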