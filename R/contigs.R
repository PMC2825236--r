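#' Assemble strand-specific tag-contigs
#'
#' Per (chromosome, strand), tag-contigs (TCs) are the connected components
#' of the placement overlap graph: placements overlapping each other by at
#' least 1 nt chain into one TC, while merely abutting placements
#' (`start == previous end + 1`) do not merge. Each TC records its member
#' placements, the sum of their read weights, and its tag-depth -- the
#' maximum over the TC's bases of the summed weights of placements covering
#' that base.
#'
#' @param placements Weighted placements from [distribute_reads()].
#' @return `GRanges` of TCs with metadata columns `name`, `tag_depth`,
#'   `n_tags`, `n_reads` and `member_tag_ids` (a `CharacterList`).
#' @export
build_tag_contigs <- function(placements) {
  if (length(placements) == 0L) {
    tc <- GenomicRanges::GRanges(seqinfo = GenomeInfoDb::seqinfo(placements))
    tc$name <- character(); tc$tag_depth <- numeric()
    tc$n_tags <- integer(); tc$n_reads <- numeric()
    tc$member_tag_ids <- IRanges::CharacterList()
    return(tc)
  }
  if (is.null(placements$weight)) stop("placements carry no read weights; run distribute_reads() first")
  red <- GenomicRanges::reduce(placements, min.gapwidth = 0L, with.revmap = TRUE)
  revmap <- red$revmap
  tc <- GenomicRanges::granges(red)
  tc$name <- locus_name(tc)
  tc$tag_depth <- rep(NA_real_, length(tc))
  tc$n_tags <- S4Vectors::elementNROWS(revmap)
  tc$n_reads <- vapply(revmap, function(i) sum(placements$weight[i]), 0)
  tc$member_tag_ids <- IRanges::CharacterList(
    lapply(revmap, function(i) placements$tag_id[i]))
  for (str in c("+", "-")) {
    on_str <- as.character(GenomicRanges::strand(tc)) == str
    if (!any(on_str)) next
    pl <- placements[as.character(GenomicRanges::strand(placements)) == str]
    cov <- GenomicRanges::coverage(pl, weight = pl$weight)
    for (chrom in unique(as.character(GenomicRanges::seqnames(tc[on_str])))) {
      sel <- on_str & as.character(GenomicRanges::seqnames(tc)) == chrom
      v <- IRanges::Views(cov[[chrom]], IRanges::ranges(tc[sel]))
      tc$tag_depth[sel] <- IRanges::viewMaxs(v)
    }
  }
  o <- order(as.character(GenomicRanges::seqnames(tc)), GenomicRanges::start(tc),
             GenomicRanges::end(tc), as.character(GenomicRanges::strand(tc)),
             method = "radix")
  tc[o]
}

#' Tag-depth of one tag-contig
#'
#' The tag-depth is the maximum per-base accumulation of read weights over
#' the TC's interval: for each base, the weights of all member placements
#' covering it are summed, and the maximum over bases is returned.
#'
#' @param tc A length-1 `GRanges` (the TC interval).
#' @param members Weighted placements belonging to the TC (same strand,
#'   within the TC interval).
#' @return A single numeric depth.
#' @export
compute_tag_depth <- function(tc, members) {
  if (length(members) == 0L) stop("tag-contig with no member placements")
  if (is.null(members$weight)) stop("members carry no read weights")
  ir <- IRanges::shift(IRanges::ranges(members), 1L - GenomicRanges::start(tc))
  cov <- IRanges::coverage(ir, weight = members$weight,
                           width = GenomicRanges::width(tc))
  max(cov)
}
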