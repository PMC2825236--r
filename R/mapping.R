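#' Map tags to the genome by exact full-length match
#'
#' Every placement is a full-length exact match of the tag on either strand:
#' a minus-strand placement means the reverse complement of the tag matches
#' the forward genome string. Placements on excluded chromosomes are dropped
#' *before* `n_loci` is counted, so the per-locus read weights computed later
#' are based only on retained placements.
#'
#' @param genome Genome ([read_genome()] / [as_genome()]).
#' @param tags Tag library `data.frame` ([read_tag_library()]).
#' @return `GRanges` of placements, sorted by (chrom, start, strand, tag_id),
#'   with metadata columns `tag_id` and `n_loci`.
#' @export
map_tags_exact <- function(genome, tags) {
  ac <- active_chroms(genome)
  if (length(ac) == 0L) stop("genome has no indexable (non-excluded) sequence")
  si <- .active_seqinfo(genome)
  empty <- GenomicRanges::GRanges(seqinfo = si)
  empty$tag_id <- character()
  empty$n_loci <- integer()
  if (nrow(tags) == 0L) return(empty)

  fwd <- Biostrings::DNAStringSet(tags$sequence)
  names(fwd) <- tags$tag_id
  rev <- Biostrings::reverseComplement(fwd)
  widths <- Biostrings::width(fwd)
  # one variable-width dictionary per strand (trusted band = shortest tag)
  tb <- min(widths)
  dicts <- list(`+` = Biostrings::PDict(fwd, tb.start = 1L, tb.end = tb),
                `-` = Biostrings::PDict(rev, tb.start = 1L, tb.end = tb))

  hits <- list()
  for (chrom in ac) {
    subj <- genome[[chrom]]
    for (str in c("+", "-")) {
      m <- Biostrings::matchPDict(dicts[[str]], subj, max.mismatch = 0L)
      n <- S4Vectors::elementNROWS(m)
      if (sum(n) == 0L) next
      st <- unlist(IRanges::start(m), use.names = FALSE)
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = chrom, start = st, end = st + rep(widths, n) - 1L,
        strand = str, tag_id = rep(names(fwd), n), stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) return(empty)
  h <- do.call(rbind, hits)
  gr <- GenomicRanges::GRanges(factor(h$chrom, levels = ac),
                               IRanges::IRanges(h$start, h$end),
                               strand = h$strand, seqinfo = si)
  gr$tag_id <- h$tag_id
  nl <- table(h$tag_id)
  gr$n_loci <- as.integer(nl[gr$tag_id])
  o <- order(as.integer(GenomicRanges::seqnames(gr)), GenomicRanges::start(gr),
             as.character(GenomicRanges::strand(gr)), gr$tag_id,
             method = "radix")
  gr[o]
}

#' Distribute read counts evenly over a tag's placements
#'
#' Each placement of a tag receives `read_count / n_loci` reads. Tags with
#' more placements than reads are discarded entirely (all their placements
#' are removed): an even split would assign less than one read per locus.
#'
#' @param placements `GRanges` from [map_tags_exact()] (or
#'   [read_premapped_bed()]).
#' @param tags Tag library `data.frame`.
#' @return The retained placements with an added numeric `weight` column and
#'   a `read_count` column for the parent tag.
#' @export
distribute_reads <- function(placements, tags) {
  rc <- tags$read_count[match(placements$tag_id, tags$tag_id)]
  if (anyNA(rc)) stop("placement with tag_id absent from the tag library")
  keep <- placements$n_loci <= rc
  out <- placements[keep]
  out$read_count <- rc[keep]
  out$weight <- out$read_count / out$n_loci
  out
}

#' Import pre-mapped tag placements from BED6
#'
#' For genomes too large for the built-in exact matcher, placements computed
#' externally can be supplied as BED6 with `name = tag_id`. Placements on
#' excluded chromosomes are dropped before `n_loci` is counted, mirroring
#' [map_tags_exact()].
#'
#' @param path BED6 file of placements.
#' @param genome Genome object (used for chromosome exclusion and bounds).
#' @return `GRanges` with `tag_id` and `n_loci`, as from [map_tags_exact()].
#' @export
read_premapped_bed <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "bed")
  keep <- !(as.character(GenomicRanges::seqnames(gr)) %in% excluded_chroms(genome))
  gr <- gr[keep]
  out <- GenomicRanges::GRanges(
    factor(as.character(GenomicRanges::seqnames(gr)), levels = active_chroms(genome)),
    IRanges::ranges(gr), strand = GenomicRanges::strand(gr),
    seqinfo = .active_seqinfo(genome))
  out$tag_id <- gr$name
  nl <- table(out$tag_id)
  out$n_loci <- as.integer(nl[out$tag_id])
  o <- order(as.integer(GenomicRanges::seqnames(out)), GenomicRanges::start(out),
             as.character(GenomicRanges::strand(out)), out$tag_id,
             method = "radix")
  out[o]
}
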