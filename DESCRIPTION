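Package: sicloppsr
Title: NGS Analysis of SICLOPPS Cyclic-Peptide Biopanning Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decodes and ranks hits from next-generation sequencing of
    SICLOPPS (split-intein circular ligation of peptides and proteins)
    cyclic-peptide libraries screened by iterative biopanning. Amplicon
    reads carrying an NNS-encoded CX5 extein between fixed intein anchors
    are quality-controlled, cropped and translated; peptides are counted
    and normalized to copies per million reads; sequences are classified
    as enriched across panning rounds and reranked by an adjusted inverse
    enrichment score combining final-round rank with cross-round fold
    enrichment. Motif analytics cover wildcard pattern queries, 4-of-5
    homology neighborhoods, position frequency (logo) matrices,
    deterministic agglomerative clustering of one-hot encoded peptides and
    BLOSUM62 distance trees with Newick export. A seeded simulator of
    library construction, spike-in controls and fitness-driven selection
    provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
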