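Package: phyloCpG
Title: Phylo-Epigenetic Analysis of CpG Island Erosion Across Closely Related Species
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparative analysis of CpG dinucleotide conservation
    in multiple sequence alignments of CpG-island loci. Detects CpG islands,
    tiles alignments into orthologous dinucleotide positions, classifies CpG
    conservation, tabulates the CpG substitution spectrum and
    clade-distinguishing markers, recodes CpG presence/absence into a binary
    character matrix, and builds molecular-clock (UPGMA) trees from both full
    alignments and CpG-only characters, with absolute-time calibration. A
    context-dependent substitution simulator with methylation-driven CpG
    hypermutability (CpG to TpG/CpA deamination) provides ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'utils.R'
    'seqio.R'
    'islands.R'
    'annotation.R'
    'recoding.R'
    'phylo.R'
    'simulate.R'
    'pipeline.R'
    'fetch.R'
    'phyloCpG-package.R'
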