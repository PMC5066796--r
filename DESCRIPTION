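Package: ap2erf
Title: Gene-Family Dissection of AP2/ERF Transcription Factors and HSP90
    Chaperones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide identification and
    characterization of the AP2/ERF transcription-factor superfamily and the
    HSP90 chaperone family from annotated proteomes. Detects AP2, B3,
    HATPase_c and HSP90 domains with a self-contained profile scorer,
    classifies genes into subfamilies (AP2, AINTEGUMENTA, ERF, DREB, RAV,
    soloist, HSP90) by domain architecture and the diagnostic residues at
    canonical AP2-domain positions 14 and 19, computes intron counts and
    splice phases from GFF3 gene models, classifies tandem versus segmental
    duplications and best-bidirectional-hit orthologs, builds
    neighbour-joining trees with pairwise-deletion distances and bootstrap
    support for clade-based subgroup assignment (A1-A6, B1-B6), and profiles
    expression via FPKM, log10 transformation, hierarchical clustering and
    the 2^-ddCt quantitative PCR calculator. A synthetic-genome generator
    with a machine-readable truth table makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
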