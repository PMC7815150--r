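Package: olfactoR
Title: Annotation of Tandemly Arrayed Olfactory Receptor Gene Families from
    Spliced Protein-to-Genome Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts large sets of redundant protein-to-genome spliced
    alignments (Exonerate protein2genome output with embedded GFF blocks)
    into non-redundant, splice-corrected gene models for tandemly arrayed
    insect olfactory receptor (OR) gene families. Builds per-nucleotide
    alignment-coverage tracks to separate tandem gene copies, selects the
    best query protein per locus, stitches fragmented alignments at
    GT-AG-validated splice sites, locates START/STOP codons, flags
    pseudogenes and partial models, and writes GFF3, BED12+1 and FASTA
    outputs. Includes parsers for external validator outputs (Pfam 7tm_6
    domain tables, three transmembrane-helix predictors with a consensus
    vote, motif scans), a base/exon/locus annotation evaluator with
    terminal-exon tolerance, and a synthetic-data generator that emulates
    tandem OR arrays and the alignment pathologies the pipeline repairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    rtracklayer,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
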