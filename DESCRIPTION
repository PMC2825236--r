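Package: tagcontig
Title: Tag-Contig Assembly and Small ncRNA Candidate Discovery from Short RNA Tags
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles deep-sequencing short RNA tags into strand-specific
    tag-contigs (TCs) with a per-base weighted tag-depth score, distributes the
    reads of multi-mapping tags evenly over their genomic placements, classifies
    TCs against genome annotation (exons, introns, repeats, annotated ncRNAs,
    conserved elements), and calls candidate box C/D snoRNAs, box H/ACA snoRNAs
    and unclassified high-depth ncRNA loci using size/depth windows and anchored
    degenerate-motif searches. Includes a seeded synthetic-fixture generator
    (toy genome, gene models, planted ncRNAs and tag libraries) so the whole
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
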