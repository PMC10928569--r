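Package: agelink
Title: Linking Age-Dependent Transcription to 3D Chromatin Reorganization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline coupling age-dependent transcriptional programs
    in human skin fibroblasts to interchromosomal chromatin reorganization. Provides
    subsampling-robust negative-binomial differential expression between data-driven
    age groups, prize-collecting Steiner forests over costed protein-interaction
    networks augmented with regulatory edges (identifying "bridge" transcription
    factors that connect differentially expressed genes of consecutive age
    transitions), contiguous large-average-submatrix decomposition of balanced Hi-C
    contact maps into intermingling regions, and the statistics that couple bridge-TF
    target genes to age-specific intermingling changes. A synthetic-data module
    generates cohorts, interactomes, regulons, and Hi-C maps with recorded planted
    ground truth so the full pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
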