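#' Write tag-contigs to BED6+1
#'
#' Emits one line per TC with `name = "<chrom>_<start>_<end>"` (0-based
#' half-open, so the TC size equals `end - start`), the tag-depth rounded to
#' the nearest integer and capped at 1000 in the BED score column, and the
#' full (possibly fractional) tag-depth repeated in a 7th column. Rows are
#' sorted by (chrom, start, end, strand).
#'
#' @param tcs `GRanges` of tag-contigs with a `tag_depth` metadata column.
#' @param path Output path.
#' @export
write_tc_bed <- function(tcs, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  if (length(tcs) == 0L) return(invisible(path))
  o <- order(as.character(GenomicRanges::seqnames(tcs)),
             GenomicRanges::start(tcs), GenomicRanges::end(tcs),
             as.character(GenomicRanges::strand(tcs)), method = "radix")
  tcs <- tcs[o]
  depth <- tcs$tag_depth
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(tcs)),
    start = GenomicRanges::start(tcs) - 1L,
    end = GenomicRanges::end(tcs),
    name = locus_name(tcs),
    score = pmin(1000L, as.integer(floor(depth + 0.5))),
    strand = as.character(GenomicRanges::strand(tcs)),
    tag_depth = depth
  )
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read tag-contigs from BED6+1
#'
#' Inverse of [write_tc_bed()]; restores intervals, strands and the full
#' tag-depth from the 7th column.
#'
#' @param path Input path.
#' @return `GRanges` with a `tag_depth` column.
#' @export
read_tc_bed <- function(path) {
  if (!file.exists(path)) stop("TC BED not found: ", path)
  if (file.size(path) == 0L) {
    gr <- GenomicRanges::GRanges()
    gr$tag_depth <- numeric()
    return(gr)
  }
  gr <- rtracklayer::import(path, format = "bed",
                            extraCols = c(tag_depth = "numeric"))
  out <- GenomicRanges::granges(gr)
  out$tag_depth <- gr$tag_depth
  out
}
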