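Package: coexreg
Title: Promoter Motif Scanning and Co-Expression Community Inference for
    Transcription Factor Target Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An inference workflow linking transcription factors to candidate
    target genes. Extracts strand-aware promoter windows from a genome and
    annotation, scans them with position weight matrices using exact
    match-significance computation (a dynamic program over the integer
    log-odds score distribution) and with degenerate IUPAC consensus patterns
    on both strands, normalizes RNA-seq count matrices by the median-of-ratios
    method, builds Spearman co-expression networks under Bonferroni control,
    detects communities by multi-trial greedy minimization of the map
    equation with hierarchical refinement, tests transcription-factor-family
    motif enrichment per community with one-sided Fisher's exact tests and
    Benjamini-Hochberg correction, extracts anchor subnetworks, quantifies
    qPCR data by the 2^-ddCt method, and summarizes residue conservation in
    protein alignments. Includes a seeded synthetic-data generator that
    plants promoter motifs, expression modules, differential expression,
    size factors and relative quantities with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
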