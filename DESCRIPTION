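Package: phosflow
Title: Label-Free Phosphoproteomics Quantitation, Motif Enrichment and
    Pathway Activity Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for label-free phosphoproteomics across
    replicated cell-line panels. Provides internal-standard normalization
    and coefficient-of-variation quality control of phosphopeptide
    abundances, log2-ratio computation with sentinel codes for
    class-exclusive detections, two-fold regulation calling with a
    multi-cell-line concurrence filter, phosphosite sequence-window
    extraction with kinase-motif classification (proline-directed,
    basophilic, acidophilic), iterative binomial motif enrichment,
    chi-square homogeneity testing of kinase-subset frequencies, a
    t-statistic pathway activity score over phosphoprotein signatures,
    and Gene Ontology based pathway functional-similarity clustering.
    A seeded synthetic-data generator with planted effects and ground
    truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    ape,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
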