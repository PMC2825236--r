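.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Count mismatches of a sequence window against an IUPAC pattern
#'
#' A position mismatches when the window base is not a member of the IUPAC
#' set of the pattern base (`R` = A/G, `N` = any, etc.); `N` in the pattern
#' therefore never mismatches. Degenerate bases give no partial credit.
#'
#' @param pattern IUPAC pattern (DNA alphabet).
#' @param x Character vector of windows, each the same length as `pattern`.
#' @return Integer vector of mismatch counts.
#' @examples
#' iupac_mismatch_count("RTGATGA", "ATGATGA")  # 0
#' iupac_mismatch_count("RTGATGA", "CTGATGA")  # 1
#' @export
iupac_mismatch_count <- function(pattern, x) {
  pattern <- toupper(chartr("Uu", "Tt", pattern))
  x <- toupper(chartr("Uu", "Tt", x))
  plen <- nchar(pattern)
  if (any(nchar(x) != plen))
    stop("window length differs from pattern length")
  pat <- strsplit(pattern, "")[[1]]
  if (!all(pat %in% names(.IUPAC_SETS)))
    stop("pattern contains non-IUPAC characters")
  sets <- .IUPAC_SETS[pat]
  vapply(strsplit(x, ""), function(b)
    sum(!mapply(`%in%`, b, sets)), 0L)
}

#' Define a degenerate motif with anchor and search window
#'
#' @param name Motif name.
#' @param pattern IUPAC pattern in the DNA alphabet (RNA input is converted).
#' @param max_mismatches Mismatches tolerated (default 0).
#' @param anchor Where the search window is anchored in the TC's 5'->3'
#'   frame: `"five_prime"`, `"three_prime"`, `"midpoint"` or `"none"`.
#' @param window Motif start may fall within `window` bp either side of the
#'   anchor.
#' @return A list with class `"motif_spec"`.
#' @export
motif_spec <- function(name, pattern, max_mismatches = 0L,
                       anchor = c("five_prime", "three_prime", "midpoint", "none"),
                       window = 0L) {
  anchor <- match.arg(anchor)
  pattern <- toupper(chartr("Uu", "Tt", pattern))
  stopifnot(nchar(pattern) > 0L, window >= 0L, max_mismatches >= 0L)
  if (!all(strsplit(pattern, "")[[1]] %in% names(.IUPAC_SETS)))
    stop("pattern contains non-IUPAC characters")
  structure(list(name = name, pattern = pattern,
                 max_mismatches = as.integer(max_mismatches),
                 anchor = anchor, window = as.integer(window)),
            class = "motif_spec")
}

#' Canonical snoRNA box motif specifications
#'
#' Box C (`RTGATGA`, DNA alphabet) and box D (`CTGA`) are searched with up
#' to one mismatch within +/- 10 bp of the TC's 5' and 3' ends
#' respectively. Box H (`ANANNA`) is searched without mismatches within
#' +/- 20 bp of the TC midpoint, and box ACA (`ACA`, exact) within
#' +/- 20 bp of the 3' end.
#'
#' @return A `"motif_spec"`.
#' @export
box_c_spec <- function() motif_spec("box_C", "RTGATGA", 1L, "five_prime", 10L)

#' @rdname box_c_spec
#' @export
box_d_spec <- function() motif_spec("box_D", "CTGA", 1L, "three_prime", 10L)

#' @rdname box_c_spec
#' @export
box_h_spec <- function() motif_spec("box_H", "ANANNA", 0L, "midpoint", 20L)

#' @rdname box_c_spec
#' @export
box_aca_spec <- function() motif_spec("box_ACA", "ACA", 0L, "three_prime", 20L)

#' Anchored motif search around a tag-contig
#'
#' Searches the strand-oriented sequence of a TC plus flanking genome
#' sequence for the motif. All positions are taken in the TC's 5'->3' frame
#' (for a minus-strand TC the 5' end is the higher genomic coordinate).
#' Candidate motif start positions `p` satisfy `|p - anchor| <= window`,
#' where the anchor is the TC's first base (`five_prime`), the start
#' position at which the motif would end on the TC's last base
#' (`three_prime`), or the TC midpoint. The motif may therefore lie partly
#' or wholly outside the TC; flanks are truncated at chromosome edges. Among
#' admissible hits the one with fewest mismatches wins, ties broken by
#' smallest distance to the anchor, then by smallest `p`.
#'
#' @param tc A length-1 `GRanges`.
#' @param genome Genome object.
#' @param spec A [motif_spec()].
#' @return A one-row `data.frame` (`motif`, `chrom`, `start`, `end`,
#'   `strand`, `mismatches`, `matched_sequence`, `offset` = signed distance
#'   of the motif start from the anchor in the TC frame), or `NULL` when no
#'   admissible position is within the mismatch budget.
#' @export
anchored_search <- function(tc, genome, spec) {
  stopifnot(length(tc) == 1L, inherits(spec, "motif_spec"))
  chrom <- as.character(GenomicRanges::seqnames(tc))
  subj <- genome[[chrom]]
  if (is.null(subj)) stop("TC on chromosome absent from genome: ", chrom)
  plen <- nchar(spec$pattern)
  minus <- as.character(GenomicRanges::strand(tc)) == "-"
  pad <- spec$window + plen
  gstart <- max(1L, GenomicRanges::start(tc) - pad)
  gend <- min(length(subj), GenomicRanges::end(tc) + pad)
  region <- Biostrings::subseq(subj, gstart, gend)
  if (minus) region <- Biostrings::reverseComplement(region)
  region <- as.character(region)
  L <- GenomicRanges::width(tc)
  # frame position (1-based within `region`) of the TC's 5' base
  fp5 <- if (minus) gend - GenomicRanges::end(tc) + 1L else
    GenomicRanges::start(tc) - gstart + 1L
  anchor <- switch(spec$anchor,
    five_prime = fp5,
    three_prime = fp5 + L - plen,      # motif ends on the TC's last base
    midpoint = fp5 + L %/% 2L,
    none = fp5)
  window <- if (spec$anchor == "none") L + 2L * pad else spec$window
  pmin_ <- max(1L, anchor - window)
  pmax_ <- min(nchar(region) - plen + 1L, anchor + window)
  if (pmax_ < pmin_) return(NULL)
  p <- pmin_:pmax_
  wins <- substring(region, p, p + plen - 1L)
  mm <- iupac_mismatch_count(spec$pattern, wins)
  ok <- mm <= spec$max_mismatches
  if (!any(ok)) return(NULL)
  p <- p[ok]; mm <- mm[ok]; wins <- wins[ok]
  best <- order(mm, abs(p - anchor), p)[1L]
  pb <- p[best]
  if (minus) {
    ge <- gend - pb + 1L
    gs <- ge - plen + 1L
  } else {
    gs <- gstart + pb - 1L
    ge <- gs + plen - 1L
  }
  data.frame(motif = spec$name, chrom = chrom, start = gs, end = ge,
             strand = if (minus) "-" else "+",
             mismatches = mm[best], matched_sequence = wins[best],
             offset = pb - anchor, frame_start = pb,
             stringsAsFactors = FALSE)
}

#' Genome-wide fixed k-mer scan with mismatches
#'
#' Scans both strands of every non-excluded chromosome for full-length
#' occurrences of `kmer` within a Hamming distance of `max_mismatches`.
#' Each site is reported once per (chrom, start, strand) with its exact
#' mismatch count, so results stratify by mismatch count.
#'
#' @param genome Genome object.
#' @param kmer Nucleotide string (<= 64 nt).
#' @param max_mismatches Maximum Hamming distance (default 0).
#' @return `GRanges` of hits with metadata columns `mismatches` and
#'   `matched_sequence`, sorted by (chrom, start, strand).
#' @export
genome_kmer_scan <- function(genome, kmer, max_mismatches = 0L) {
  kmer <- toupper(chartr("Uu", "Tt", kmer))
  k <- nchar(kmer)
  stopifnot(k >= 1L, k <= 64L, grepl("^[ACGT]+$", kmer))
  si <- .active_seqinfo(genome)
  pats <- list(`+` = Biostrings::DNAString(kmer),
               `-` = Biostrings::reverseComplement(Biostrings::DNAString(kmer)))
  hits <- list()
  for (chrom in active_chroms(genome)) {
    subj <- genome[[chrom]]
    if (k > length(subj)) next
    for (str in c("+", "-")) {
      m <- Biostrings::matchPattern(pats[[str]], subj,
                                    max.mismatch = max_mismatches)
      st <- IRanges::start(m)
      inb <- st >= 1L & IRanges::end(m) <= length(subj)
      st <- st[inb]
      if (length(st) == 0L) next
      mm <- Biostrings::neditStartingAt(pats[[str]], subj, starting.at = st,
                                        with.indels = FALSE)
      gr <- GenomicRanges::GRanges(factor(chrom, levels = seqlevels(si)),
                                   IRanges::IRanges(st, width = k),
                                   strand = str, seqinfo = si)
      gr$mismatches <- as.integer(mm)
      seqs <- as.character(Biostrings::DNAStringSet(
        lapply(st, function(s) Biostrings::subseq(subj, s, s + k - 1L))))
      if (str == "-") seqs <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs)))
      gr$matched_sequence <- seqs
      hits[[length(hits) + 1L]] <- gr
    }
  }
  if (length(hits) == 0L) {
    out <- GenomicRanges::GRanges(seqinfo = si)
    out$mismatches <- integer(); out$matched_sequence <- character()
    return(out)
  }
  out <- suppressWarnings(do.call(c, hits))
  o <- order(as.integer(GenomicRanges::seqnames(out)), GenomicRanges::start(out),
             as.character(GenomicRanges::strand(out)), method = "radix")
  out[o]
}

#' Call the box C/D motif pair on a tag-contig
#'
#' Requires box C (`RTGATGA`, <= 1 mismatch) starting within +/- 10 bp of
#' the TC's 5' end, box D (`CTGA`, <= 1 mismatch) ending within the +/- 10 bp
#' window at the 3' end, and box C upstream of box D in the TC frame.
#'
#' @param tc A length-1 `GRanges`.
#' @param genome Genome object.
#' @return `list(c_hit =, d_hit =)` of one-row data.frames, or `NULL`.
#' @export
call_box_cd <- function(tc, genome) {
  ch <- anchored_search(tc, genome, box_c_spec())
  if (is.null(ch)) return(NULL)
  dh <- anchored_search(tc, genome, box_d_spec())
  if (is.null(dh)) return(NULL)
  if (ch$frame_start >= dh$frame_start) return(NULL)
  list(c_hit = ch, d_hit = dh)
}

#' Call the box H/ACA motif pair on a tag-contig
#'
#' Requires box H (`ANANNA`, exact) starting within +/- 20 bp of the TC
#' midpoint, box ACA (exact) within the +/- 20 bp window at the 3' end, and
#' box H upstream of box ACA in the TC frame.
#'
#' @inheritParams call_box_cd
#' @return `list(h_hit =, aca_hit =)`, or `NULL`.
#' @export
call_box_haca <- function(tc, genome) {
  hh <- anchored_search(tc, genome, box_h_spec())
  if (is.null(hh)) return(NULL)
  ah <- anchored_search(tc, genome, box_aca_spec())
  if (is.null(ah)) return(NULL)
  if (hh$frame_start >= ah$frame_start) return(NULL)
  list(h_hit = hh, aca_hit = ah)
}
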