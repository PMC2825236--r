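#' Load a reference genome from FASTA
#'
#' Reads a genome into a `DNAStringSet`, normalizes sequences to uppercase and
#' flags chromosomes that must be excluded from mapping and scanning output.
#' Excluded chromosomes (by default the mitochondrial genome and the
#' unassembled-scaffold bins `chrU`/`chrUextra`) are retained in memory so
#' that placements on them can be recognized and discarded, but no pipeline
#' output ever references them.
#'
#' @param path Path to a FASTA file.
#' @param exclude Character vector of chromosome names to flag as excluded.
#' @return A `DNAStringSet` with `metadata()$excluded_chroms` set.
#' @export
read_genome <- function(path, exclude = c("chrM", "chrU", "chrUextra")) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  as_genome(seqs, exclude = exclude)
}

#' Construct a genome object from sequences
#'
#' @param seqs A named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @param exclude Chromosome names excluded from mapping/scanning output.
#' @return A `DNAStringSet` with excluded chromosomes recorded in its metadata.
#' @export
as_genome <- function(seqs, exclude = c("chrM", "chrU", "chrUextra")) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
  if (!methods::is(seqs, "DNAStringSet")) stop("seqs must be a DNAStringSet")
  if (length(seqs) == 0L) stop("genome has no sequences")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("all genome sequences must be named")
  if (anyDuplicated(names(seqs))) stop("duplicated chromosome names")
  if (any(Biostrings::width(seqs) == 0L)) stop("empty chromosome sequence")
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  S4Vectors::metadata(seqs)$excluded_chroms <- intersect(exclude, names(seqs))
  seqs
}

#' Excluded and active chromosome names
#'
#' @param genome A genome as returned by [read_genome()] / [as_genome()].
#' @return A character vector of chromosome names.
#' @export
excluded_chroms <- function(genome) {
  ex <- S4Vectors::metadata(genome)$excluded_chroms
  if (is.null(ex)) character() else ex
}

#' @rdname excluded_chroms
#' @export
active_chroms <- function(genome) {
  setdiff(names(genome), excluded_chroms(genome))
}

#' Seqinfo restricted to active chromosomes
#' @noRd
.active_seqinfo <- function(genome) {
  ac <- active_chroms(genome)
  GenomeInfoDb::Seqinfo(seqnames = ac,
                        seqlengths = Biostrings::width(genome)[match(ac, names(genome))])
}

#' Parse and render locus strings
#'
#' Locus names follow the `"<chrom>_<start>_<end>"` convention with 0-based
#' half-open coordinates, so that the TC size in nucleotides equals
#' `end - start` (e.g. `chrX_19880356_19880381` is 25 nt).
#'
#' @param x Character vector of locus strings.
#' @return `parse_locus()`: a `GRanges`; `locus_size()`: integer widths.
#' @examples
#' locus_size("chr2R_4733783_4733804")  # 21
#' @export
parse_locus <- function(x) {
  m <- regmatches(x, regexec("^(.+)_([0-9]+)_([0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed locus string: ", paste(x[bad], collapse = ", "))
  chrom <- vapply(m, `[`, "", 2L)
  start0 <- as.numeric(vapply(m, `[`, "", 3L))
  end <- as.numeric(vapply(m, `[`, "", 4L))
  if (any(end <= start0)) stop("locus end must exceed start")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1, end = end))
}

#' @rdname parse_locus
#' @export
locus_size <- function(x) {
  GenomicRanges::width(parse_locus(x))
}

#' @rdname parse_locus
#' @param gr A `GRanges`.
#' @export
locus_name <- function(gr) {
  paste(as.character(GenomicRanges::seqnames(gr)),
        GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr), sep = "_")
}

#' GC content of a sequence, in percent
#'
#' @param x Character vector of nucleotide sequences.
#' @param digits Decimal places kept (truncated, see [format_percent()]).
#' @return Numeric vector of GC percentages.
#' @examples
#' gc_percent("GTCCACCCGGGGGCGCCA")  # 83.3
#' @export
gc_percent <- function(x, digits = 1) {
  s <- Biostrings::DNAStringSet(toupper(chartr("Uu", "Tt", x)))
  gc <- Biostrings::letterFrequency(s, letters = c("G", "C"))
  trunc_decimal(100 * rowSums(gc) / Biostrings::width(s), digits)
}

#' Truncate to a fixed number of decimals
#' @noRd
trunc_decimal <- function(x, digits = 1) {
  trunc(x * 10^digits + sqrt(.Machine$double.eps)) / 10^digits
}

#' Render a count as a percentage of a denominator
#'
#' Percentages are truncated (not rounded) to `digits` decimals; this is the
#' rendering used in the package's coverage reports. A zero denominator
#' renders as `"N/A"`.
#'
#' @param n Numerator count(s).
#' @param d Denominator count(s).
#' @param digits Decimal places.
#' @return Character vector.
#' @examples
#' format_percent(153, 154)  # "99.3"
#' format_percent(284, 297)  # "95.6"
#' @export
format_percent <- function(n, d, digits = 1) {
  out <- rep("N/A", length(n))
  ok <- !is.na(d) & d > 0
  out[ok] <- formatC(trunc_decimal(100 * n[ok] / d[ok], digits),
                     format = "f", digits = digits)
  out
}
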