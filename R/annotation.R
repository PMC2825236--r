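#' Annotation feature classes
#'
#' The controlled vocabulary used for genomic annotation throughout the
#' package. `ncrna_classes()` returns the subset treated as annotated ncRNAs
#' for TC classification and coverage reporting.
#'
#' @return Character vector of class names.
#' @export
feature_classes <- function() {
  c("exon", "intron", "gene", "repeat", "transposon",
    "miRNA", "pre_miRNA", "snoRNA_CD", "snoRNA_HACA", "tRNA", "snRNA",
    "other_ncRNA", "conserved_element")
}

#' @rdname feature_classes
#' @export
ncrna_classes <- function() {
  c("miRNA", "pre_miRNA", "snoRNA_CD", "snoRNA_HACA", "tRNA", "snRNA",
    "other_ncRNA")
}

#' Default mapping from GFF3 `type` to feature class
#'
#' Unmapped types (e.g. `mRNA`, `chromosome`) are dropped on import.
#'
#' @return Named character vector: names are GFF3 types, values are feature
#'   classes.
#' @export
default_class_map <- function() {
  c(exon = "exon", CDS = "exon", intron = "intron", gene = "gene",
    repeat_region = "repeat", dispersed_repeat = "repeat",
    transposable_element = "transposon", transposon = "transposon",
    miRNA = "miRNA", pre_miRNA = "pre_miRNA", miRNA_primary_transcript = "pre_miRNA",
    snoRNA = "snoRNA_CD", snoRNA_CD = "snoRNA_CD", snoRNA_HACA = "snoRNA_HACA",
    tRNA = "tRNA", snRNA = "snRNA", ncRNA = "other_ncRNA",
    rRNA = "other_ncRNA", conserved_element = "conserved_element")
}

#' Read genome annotation
#'
#' Imports GFF3 (1-based inclusive, converted internally) or BED6 (0-based
#' half-open) annotation into a `GRanges` with a `feature_class` column.
#' When a GFF3 file contains gene and exon features but no introns, introns
#' are synthesized per gene as the within-gene complement of its exons and
#' inherit the gene's strand; their `host_gene` column names the gene.
#'
#' @param path Input file.
#' @param format `"gff3"` or `"bed6"`.
#' @param genome Optional genome ([read_genome()]); when supplied, features
#'   extending beyond a chromosome end are a hard error.
#' @param class_map Named vector mapping GFF3 `type` to feature class
#'   (see [default_class_map()]).
#' @param feature_class Class assigned to all records of a BED6 file
#'   (ignored for GFF3).
#' @param synthesize_introns Synthesize introns from gene/exon structure when
#'   no intron features are present.
#' @return A `GRanges` with metadata columns `feature_class`, `name`,
#'   `host_gene`.
#' @export
read_annotation <- function(path, format = c("gff3", "bed6"), genome = NULL,
                            class_map = default_class_map(),
                            feature_class = "other_ncRNA",
                            synthesize_introns = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    cls <- unname(class_map[as.character(gr$type)])
    keep <- !is.na(cls)
    gr <- gr[keep]
    cls <- cls[keep]
    nm <- gr$Name
    if (is.null(nm)) nm <- rep(NA_character_, length(gr))
    id <- gr$ID
    if (is.null(id)) id <- rep(NA_character_, length(gr))
    nm <- ifelse(!is.na(nm), nm, ifelse(!is.na(id), id,
                 paste0(cls, "_", seq_along(gr))))
    feats <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                    IRanges::ranges(gr),
                                    strand = GenomicRanges::strand(gr))
    feats$feature_class <- cls
    feats$name <- nm
    feats$host_gene <- NA_character_
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    feats <- GenomicRanges::granges(gr)
    feats$feature_class <- rep(feature_class, length(feats))
    feats$name <- if (!is.null(gr$name)) gr$name else paste0(feature_class, "_", seq_along(feats))
    feats$host_gene <- NA_character_
  }
  validate_features(feats, genome)
  if (synthesize_introns && !any(feats$feature_class == "intron"))
    feats <- add_introns(feats)
  feats
}

#' Read conserved-element intervals (phastCons-style) from BED6
#'
#' @inheritParams read_annotation
#' @return `GRanges` with `feature_class = "conserved_element"`.
#' @export
read_conserved_elements <- function(path, genome = NULL) {
  read_annotation(path, format = "bed6", genome = genome,
                  feature_class = "conserved_element",
                  synthesize_introns = FALSE)
}

#' @noRd
validate_features <- function(feats, genome = NULL) {
  if (any(GenomicRanges::start(feats) < 1L))
    stop("feature with start < 1: ",
         feats$name[which(GenomicRanges::start(feats) < 1L)[1L]])
  if (!is.null(genome)) {
    len <- Biostrings::width(genome)[match(as.character(GenomicRanges::seqnames(feats)),
                                           names(genome))]
    if (anyNA(len))
      stop("feature on unknown chromosome: ",
           feats$name[which(is.na(len))[1L]])
    over <- GenomicRanges::end(feats) > len
    if (any(over))
      stop("feature beyond chromosome end: ", feats$name[which(over)[1L]])
  }
  invisible(feats)
}

#' Synthesize introns from gene/exon structure
#'
#' For each `gene` feature, introns are the parts of the gene span not
#' covered by any same-strand exon overlapping the gene. Introns inherit the
#' gene's strand and record it as `host_gene`.
#'
#' @param feats Annotation `GRanges` (as from [read_annotation()]).
#' @return The annotation with intron features appended.
#' @export
add_introns <- function(feats) {
  genes <- feats[feats$feature_class == "gene"]
  exons <- feats[feats$feature_class == "exon"]
  if (length(genes) == 0L) return(feats)
  out <- list(feats)
  for (i in seq_along(genes)) {
    g <- genes[i]
    ex <- exons[IRanges::overlapsAny(exons, g) &
                as.character(GenomicRanges::strand(exons)) ==
                as.character(GenomicRanges::strand(g))]
    intr <- GenomicRanges::setdiff(GenomicRanges::granges(g),
                                   GenomicRanges::granges(ex))
    if (length(intr) == 0L) next
    intr$feature_class <- "intron"
    intr$name <- paste0(g$name, "_intron", seq_along(intr))
    intr$host_gene <- g$name
    out[[length(out) + 1L]] <- intr
  }
  suppressWarnings(do.call(c, out))
}
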