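Package: ppredit
Title: Discovery and Characterization of C-to-U RNA Editing Off-Targets of PPR Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterizing cytidine-to-uridine RNA editing
    in plant organellar transcriptomes, with a focus on off-target sites created by
    heterologously expressed pentatricopeptide repeat (PPR) editing factors. The
    package builds masked mapping references (IUPAC Y/R masking of known editing
    sites, inverted-repeat collapse), aligns strand-specific paired-end reads with a
    deterministic substitution-only aligner, calls candidate editing sites from
    strand-aware pileups with rate, type and annotation filters, and classifies
    high- and low-affinity targets. It also scores cis-elements against PPR-code
    binding predictions with anchored alignment, computes windowed pairwise context
    similarity, quantifies splice ratios, RPKM and delta-delta-Ct expression, and
    genotypes editing-site alleles across species by exact 31-mer and six-frame
    peptide scans. A synthetic-data module simulates organellar genomes and reads
    with known editing, splicing and error structure so every stage is testable.
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
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
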