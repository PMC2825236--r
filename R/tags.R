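#' Read a short-RNA tag library
#'
#' A tag is a distinct short RNA sequence; its read count is the number of
#' times the tag was cloned and sequenced. Two input layouts are supported:
#'
#' * `fasta_with_counts`: FASTA where each header carries the read count as
#'   the final `_`- or whitespace-separated token, e.g. `>t1_5` or `>t1 5`.
#' * `two_column_table`: whitespace/tab-separated `sequence<TAB>count`.
#'
#' Sequences are normalized to the DNA alphabet (`U` to `T`, uppercase).
#' Duplicate sequences -- e.g. the same tag observed in several source
#' libraries -- are merged by summing their read counts, so the returned
#' table is one row per distinct sequence, sorted lexicographically by
#' sequence. Records with an unparsable count or non-ACGT characters are
#' dropped with a warning; an input yielding zero usable records is an error.
#'
#' @param path Input file.
#' @param format One of `"fasta_with_counts"`, `"two_column_table"`.
#' @return A `data.frame` with columns `tag_id`, `sequence`, `read_count`.
#' @export
read_tag_library <- function(path,
                             format = c("fasta_with_counts", "two_column_table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tag library not found: ", path)
  if (format == "fasta_with_counts") {
    raw <- Biostrings::readBStringSet(path)
    ids <- names(raw)
    cnt <- suppressWarnings(as.numeric(sub("^.*[_[:space:]]", "", ids)))
    seqs <- as.character(raw)
  } else {
    tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                             col.names = c("sequence", "count"),
                             colClasses = c("character", "numeric"))
    seqs <- tab$sequence
    cnt <- tab$count
    ids <- sprintf("tag%06d", seq_along(seqs))
  }
  as_tag_library(data.frame(tag_id = if (length(ids)) sub("[_[:space:]][^_[:space:]]*$", "", ids) else character(),
                            sequence = seqs, read_count = cnt,
                            stringsAsFactors = FALSE))
}

#' Normalize, validate and merge a tag table
#'
#' @param tags A `data.frame` with columns `sequence` and `read_count`
#'   (and optionally `tag_id`).
#' @return A validated tag library `data.frame`, one row per distinct
#'   sequence, lexicographically sorted.
#' @export
as_tag_library <- function(tags) {
  stopifnot(is.data.frame(tags), all(c("sequence", "read_count") %in% names(tags)))
  if (is.null(tags$tag_id)) tags$tag_id <- sprintf("tag%06d", seq_len(nrow(tags)))
  seqs <- toupper(chartr("Uu", "Tt", tags$sequence))
  cnt <- tags$read_count
  ok <- !is.na(cnt) & cnt >= 1 & grepl("^[ACGT]+$", seqs)
  if (any(!ok)) {
    warning(sum(!ok), " tag record(s) rejected (unparsable count or non-ACGT sequence)")
    seqs <- seqs[ok]; cnt <- cnt[ok]; tags <- tags[ok, , drop = FALSE]
  }
  if (length(seqs) == 0L) stop("no usable tag records")
  o <- order(seqs, tags$tag_id, method = "radix")
  seqs <- seqs[o]; cnt <- cnt[o]; ids <- tags$tag_id[o]
  first <- !duplicated(seqs)
  out <- data.frame(
    tag_id = ids[first],
    sequence = seqs[first],
    read_count = as.vector(tapply(cnt, factor(seqs, levels = seqs[first]), sum)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write a tag library as FASTA with counts in the headers
#'
#' Inverse of [read_tag_library()] for the `fasta_with_counts` layout: each
#' record is written as `>tag_id_count`.
#'
#' @param tags Tag library `data.frame`.
#' @param path Output path.
#' @export
write_tag_library <- function(tags, path) {
  x <- Biostrings::DNAStringSet(tags$sequence)
  names(x) <- paste(tags$tag_id, format(tags$read_count, trim = TRUE, scientific = FALSE), sep = "_")
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}
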