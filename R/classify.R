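#' Classify tag-contigs against annotation
#'
#' For each TC, the fraction of its length overlapped by each annotation
#' class is computed (overlaps are counted on either strand; the denominator
#' is always the TC's own length). A TC is assigned the first context in the
#' priority order annotated-ncRNA > exonic > repeat > intronic > intergenic
#' whose overlap fraction reaches `min_fraction` (default 20%). The intronic
#' gate also fires when the TC overlaps a gene span by at least
#' `min_fraction` without reaching the exon gate, so that a TC inside a gene
#' is never labelled intergenic. Intronic TCs are `intronic_sense` when the
#' TC strand equals the host gene's strand, else `intronic_antisense`; the
#' host gene is taken from the intron (or gene) feature with the largest
#' overlap.
#'
#' @param tcs `GRanges` of TCs ([build_tag_contigs()]).
#' @param features Annotation `GRanges` ([read_annotation()]).
#' @param conserved Optional `GRanges` of conserved elements; a TC is flagged
#'   conserved when a single element overlaps it by at least `min_conserved_bp`.
#' @param min_fraction Overlap fraction gating each context (default 0.20).
#' @param min_conserved_bp Minimum single-element overlap for the conserved
#'   flag (default 15 bp).
#' @return `tcs` with added metadata columns `context`, `host_gene`,
#'   `conserved` and per-class `frac_*` overlap fractions.
#' @export
classify_tcs <- function(tcs, features, conserved = NULL,
                         min_fraction = 0.20, min_conserved_bp = 15L) {
  n <- length(tcs)
  frac_of <- function(feats) {
    f <- numeric(n)
    if (length(feats) == 0L || n == 0L) return(f)
    red <- GenomicRanges::reduce(GenomicRanges::granges(feats), ignore.strand = TRUE)
    ov <- GenomicRanges::findOverlaps(tcs, red, ignore.strand = TRUE)
    if (length(ov) == 0L) return(f)
    w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(tcs)[S4Vectors::queryHits(ov)],
      IRanges::ranges(red)[S4Vectors::subjectHits(ov)]))
    tot <- tapply(w, S4Vectors::queryHits(ov), sum)
    f[as.integer(names(tot))] <- as.numeric(tot)
    f / GenomicRanges::width(tcs)
  }
  cls <- features$feature_class
  frac_ncrna <- frac_of(features[cls %in% ncrna_classes()])
  frac_exon <- frac_of(features[cls == "exon"])
  frac_repeat <- frac_of(features[cls %in% c("repeat", "transposon")])
  frac_intron <- frac_of(features[cls == "intron"])
  frac_gene <- frac_of(features[cls == "gene"])

  host <- rep(NA_character_, n)
  host_strand <- rep(NA_character_, n)
  hostable <- features[cls %in% c("intron", "gene")]
  if (length(hostable) > 0L && n > 0L) {
    # prefer introns over gene spans when both overlap equally
    pref <- ifelse(hostable$feature_class == "intron", 1L, 0L)
    ov <- GenomicRanges::findOverlaps(tcs, hostable, ignore.strand = TRUE)
    if (length(ov) > 0L) {
      q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
      w <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(tcs)[q], IRanges::ranges(hostable)[s]))
      o <- order(q, -w, -pref[s], s)
      first <- !duplicated(q[o])
      qf <- q[o][first]; sf <- s[o][first]
      hg <- ifelse(is.na(hostable$host_gene[sf]), hostable$name[sf],
                   hostable$host_gene[sf])
      host[qf] <- hg
      host_strand[qf] <- as.character(GenomicRanges::strand(hostable))[sf]
    }
  }

  context <- rep("intergenic", n)
  intr_gate <- frac_intron >= min_fraction | frac_gene >= min_fraction
  sense <- !is.na(host_strand) &
    host_strand == as.character(GenomicRanges::strand(tcs))
  context[intr_gate & !sense] <- "intronic_antisense"
  context[intr_gate & sense] <- "intronic_sense"
  context[frac_repeat >= min_fraction] <- "repeat"
  context[frac_exon >= min_fraction] <- "exonic"
  context[frac_ncrna >= min_fraction] <- "ncRNA_annotated"
  host[!(context %in% c("intronic_sense", "intronic_antisense"))] <- NA_character_

  tcs$context <- context
  tcs$host_gene <- host
  tcs$conserved <- if (is.null(conserved)) rep(FALSE, n) else
    flag_conserved(tcs, conserved, min_bp = min_conserved_bp)
  tcs$frac_ncrna <- frac_ncrna
  tcs$frac_exon <- frac_exon
  tcs$frac_repeat <- frac_repeat
  tcs$frac_intron <- frac_intron
  tcs$frac_gene <- frac_gene
  tcs
}

#' Flag intervals overlapping conserved elements
#'
#' An interval is flagged conserved when at least one single conserved
#' element overlaps it by `min_bp` or more bases. Overlap is evaluated per
#' element: two elements overlapping by e.g. 8 bases each do not add up.
#'
#' @param x `GRanges` of intervals (TCs or tag placements).
#' @param elements `GRanges` of conserved elements.
#' @param min_bp Minimum per-element overlap (default 15).
#' @return Logical vector along `x`.
#' @export
flag_conserved <- function(x, elements, min_bp = 15L) {
  if (length(elements) == 0L) return(rep(FALSE, length(x)))
  IRanges::overlapsAny(x, elements, minoverlap = min_bp, ignore.strand = TRUE)
}

#' Coverage of annotated ncRNAs by tag-contigs
#'
#' For each annotated ncRNA class, counts how many annotated features are
#' (i) overlapped by at least one same-strand TC, (ii) covered over at least
#' 70% of their length by the union of same-strand TCs, and (iii) covered
#' over at least 70% of their length by a single TC. Percentages are
#' relative to the number annotated and truncated to one decimal
#' ([format_percent()]); a class with no annotated features renders as
#' `"N/A"`.
#'
#' @param features Annotation `GRanges`; only features of classes in
#'   `classes` are reported.
#' @param tcs `GRanges` of TCs.
#' @param classes ncRNA classes to report (default [ncrna_classes()]).
#' @param min_coverage Coverage fraction threshold (default 0.70).
#' @return `data.frame` with one row per class: counts `n_annotated`,
#'   `n_overlapped`, `n_cov70`, `n_cov70_single` and formatted percentage
#'   columns `pct_*`.
#' @export
coverage_report <- function(features, tcs, classes = ncrna_classes(),
                            min_coverage = 0.70) {
  rows <- lapply(classes, function(cl) {
    feats <- features[features$feature_class == cl]
    n_ann <- length(feats)
    if (n_ann == 0L)
      return(data.frame(class = cl, n_annotated = 0L, n_overlapped = 0L,
                        n_cov70 = 0L, n_cov70_single = 0L))
    ov <- GenomicRanges::findOverlaps(feats, tcs)  # strand-aware
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    n_overlapped <- length(unique(q))
    union_frac <- numeric(n_ann)
    single_frac <- numeric(n_ann)
    if (length(ov) > 0L) {
      pieces <- IRanges::pintersect(IRanges::ranges(feats)[q],
                                    IRanges::ranges(tcs)[s])
      single <- tapply(IRanges::width(pieces), q, max)
      single_frac[as.integer(names(single))] <- as.numeric(single)
      usum <- vapply(split(pieces, q), function(p)
        sum(IRanges::width(IRanges::reduce(p))), 0)
      union_frac[as.integer(names(usum))] <- usum
      union_frac <- union_frac / IRanges::width(feats)
      single_frac <- single_frac / IRanges::width(feats)
    }
    data.frame(class = cl, n_annotated = n_ann, n_overlapped = n_overlapped,
               n_cov70 = sum(union_frac >= min_coverage),
               n_cov70_single = sum(single_frac >= min_coverage))
  })
  out <- do.call(rbind, rows)
  out$pct_overlapped <- format_percent(out$n_overlapped, out$n_annotated)
  out$pct_cov70 <- format_percent(out$n_cov70, out$n_annotated)
  out$pct_cov70_single <- format_percent(out$n_cov70_single, out$n_annotated)
  rownames(out) <- NULL
  out
}
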