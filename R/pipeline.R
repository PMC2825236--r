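#' Run the full tag-contig discovery cascade
#'
#' Deterministic composition of the pipeline stages: map tags (exact,
#' full-length, both strands) -> distribute reads over multi-mapped loci ->
#' assemble strand-specific TCs with tag-depth -> classify against
#' annotation -> restrict to unannotated (intronic/intergenic) TCs ->
#' opposite-strand depth competition filter -> candidate calling:
#'
#' 1. box H/ACA snoRNAs: intronic (sense) TCs of 120-180 nt with depth >= 15
#'    carrying the box H + ACA motif pair;
#' 2. box C/D snoRNAs: intronic (sense) or intergenic TCs of 60-100 nt with
#'    depth >= 6 carrying the box C + D motif pair (TCs already called as
#'    H/ACA are excluded first);
#' 3. unclassified groups 1-3: remaining TCs with depth >= 100, banded by
#'    length and depth ([assign_group()]); TCs named in
#'    `config$exclusion_ids` (e.g. external transposon homology) are
#'    skipped.
#'
#' TCs that enter the H/ACA size/depth window but lack the motif pair are
#' reported separately in `$unresolved` for manual follow-up (snRNA-like
#' loci surface there); they remain eligible for group banding. Every TC
#' appears in at most one candidate class, snoRNA calls taking precedence
#' over group banding. Within each class candidates are ranked by tag-depth,
#' descending.
#'
#' @param genome Genome object.
#' @param tags Tag library `data.frame`.
#' @param annotation Annotation `GRanges`.
#' @param conserved_elements Optional conserved-element `GRanges`.
#' @param config A [filter_config()].
#' @param placements Optional pre-mapped placements
#'   ([read_premapped_bed()]); when supplied the built-in matcher is skipped.
#' @param verbose Emit per-stage counts via `message()`.
#' @return A list of class `"tc_pipeline_result"`: `placements`, `tcs`
#'   (classified), `calls` (`data.frame`), `unresolved`, `coverage`
#'   (the [coverage_report()]), `config`.
#' @export
run_pipeline <- function(genome, tags, annotation, conserved_elements = NULL,
                         config = filter_config(), placements = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message("[tagcontig] ", ...)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))

  if (is.null(placements)) {
    placements <- stage("map_tags_exact", map_tags_exact(genome, tags))
  }
  say(nrow(tags), " tags; ", length(placements), " exact placements")
  placements <- stage("distribute_reads", distribute_reads(placements, tags))
  say(length(placements), " placements retained after the multi-mapping discard rule")
  tcs <- stage("build_tag_contigs", build_tag_contigs(placements))
  say(length(tcs), " tag-contigs assembled")
  tcs <- stage("classify_tcs",
               classify_tcs(tcs, annotation, conserved = conserved_elements))
  unannot <- tcs[tcs$context %in% c("intronic_sense", "intronic_antisense",
                                    "intergenic")]
  say(length(unannot), " TCs outside annotated exons/ncRNAs/repeats")
  kept <- stage("strand_competition_filter",
                strand_competition_filter(unannot, config, competitors = tcs))
  say(length(kept), " TCs after the ", config$strand_ratio_min,
      "x opposite-strand depth filter")

  haca_pool <- window_filter(kept, config$haca_len, config$haca_depth_min,
                             "intronic_sense")
  haca_hits <- lapply(seq_along(haca_pool), function(i)
    call_box_haca(haca_pool[i], genome))
  haca_called <- haca_pool[!vapply(haca_hits, is.null, TRUE)]
  unresolved <- haca_pool[vapply(haca_hits, is.null, TRUE)]
  haca_hits <- haca_hits[!vapply(haca_hits, is.null, TRUE)]
  say(length(haca_pool), " TCs in the H/ACA window; ", length(haca_called),
      " with box H + ACA motifs")

  cd_pool <- window_filter(kept, config$cd_len, config$cd_depth_min,
                           c("intronic_sense", "intergenic"))
  cd_pool <- cd_pool[!(cd_pool$name %in% haca_called$name)]
  cd_hits <- lapply(seq_along(cd_pool), function(i)
    call_box_cd(cd_pool[i], genome))
  cd_called <- cd_pool[!vapply(cd_hits, is.null, TRUE)]
  cd_hits <- cd_hits[!vapply(cd_hits, is.null, TRUE)]
  say(length(cd_pool), " TCs in the C/D window; ", length(cd_called),
      " with box C + D motifs")

  sno_names <- c(haca_called$name, cd_called$name)
  group_pool <- kept[!(kept$name %in% c(sno_names, config$exclusion_ids))]
  grp <- assign_group(group_pool, config)
  grouped <- group_pool[grp != "below_threshold"]
  grp <- grp[grp != "below_threshold"]
  say(length(grouped), " unclassified high-depth TCs banded into groups 1-3")

  call_row <- function(tc, class, evidence = NULL) {
    df <- data.frame(
      name = tc$name, chrom = as.character(GenomicRanges::seqnames(tc)),
      start = GenomicRanges::start(tc) - 1L, end = GenomicRanges::end(tc),
      strand = as.character(GenomicRanges::strand(tc)),
      length = GenomicRanges::width(tc), tag_depth = tc$tag_depth,
      call_class = class, context = tc$context,
      host_gene = tc$host_gene, conserved = tc$conserved,
      motif_evidence = if (is.null(evidence)) NA_character_ else evidence,
      stringsAsFactors = FALSE)
    dom <- dominant_tag_analysis(tc, placements, tags)
    df$dominant_tag <- dom$sequence
    df$dominant_tag_fraction <- dom$fraction
    df
  }
  fmt_ev <- function(hits) paste(vapply(hits, function(h)
    sprintf("%s@%+d(%dmm)", h$motif, h$offset, h$mismatches), ""),
    collapse = ";")
  rows <- c(
    lapply(seq_along(haca_called), function(i)
      call_row(haca_called[i], "snoRNA_HACA", fmt_ev(haca_hits[[i]]))),
    lapply(seq_along(cd_called), function(i)
      call_row(cd_called[i], "snoRNA_CD", fmt_ev(cd_hits[[i]]))),
    lapply(seq_along(grouped), function(i)
      call_row(grouped[i], grp[i])))
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), chrom = character(), start = integer(),
               end = integer(), strand = character(), length = integer(),
               tag_depth = numeric(), call_class = character(),
               context = character(), host_gene = character(),
               conserved = logical(), motif_evidence = character(),
               dominant_tag = character(), dominant_tag_fraction = numeric(),
               stringsAsFactors = FALSE)
  calls <- calls[order(factor(calls$call_class,
                              levels = c("snoRNA_HACA", "snoRNA_CD",
                                         "group1", "group2", "group3")),
                       -calls$tag_depth, calls$name), , drop = FALSE]
  rownames(calls) <- NULL

  coverage <- stage("coverage_report", coverage_report(annotation, tcs))
  structure(list(placements = placements, tcs = tcs, calls = calls,
                 unresolved = unresolved, coverage = coverage,
                 config = config),
            class = "tc_pipeline_result")
}

#' @export
print.tc_pipeline_result <- function(x, ...) {
  cat("tag-contig pipeline result\n")
  cat("  placements: ", length(x$placements), "\n", sep = "")
  cat("  tag-contigs:", length(x$tcs), "\n")
  tab <- table(x$calls$call_class)
  cat("  candidate calls:", nrow(x$calls),
      if (nrow(x$calls)) paste0("(", paste(names(tab), tab, sep = ":",
                                           collapse = ", "), ")"), "\n")
  cat("  unresolved H/ACA-window TCs:", length(x$unresolved), "\n")
  invisible(x)
}

#' Most abundant tag within a tag-contig
#'
#' Sums placement weights per member tag sequence and returns the dominant
#' sequence together with its fraction of the TC's total weight. Ties are
#' broken lexicographically by sequence.
#'
#' @param tc A length-1 `GRanges` with a `member_tag_ids` column (or plain
#'   interval; members are then taken by overlap on the same strand).
#' @param placements Weighted placements ([distribute_reads()]).
#' @param tags Tag library `data.frame`.
#' @return `list(sequence =, fraction =, weight =)`.
#' @export
dominant_tag_analysis <- function(tc, placements, tags) {
  stopifnot(length(tc) == 1L)
  if (!is.null(tc$member_tag_ids)) {
    ids <- tc$member_tag_ids[[1L]]
    members <- placements[placements$tag_id %in% ids &
      IRanges::overlapsAny(placements, tc)]
  } else {
    members <- placements[IRanges::overlapsAny(placements, tc)]
  }
  if (length(members) == 0L) stop("tag-contig has no member placements")
  seqs <- tags$sequence[match(members$tag_id, tags$tag_id)]
  w <- tapply(members$weight, seqs, sum)
  w <- w[order(-as.numeric(w), names(w))]
  list(sequence = names(w)[1L],
       fraction = as.numeric(w[1L]) / sum(as.numeric(w)),
       weight = as.numeric(w[1L]))
}

#' Cross-tabulate genome k-mer hits by mismatch count and context
#'
#' Runs [genome_kmer_scan()] and classifies each hit interval against the
#' annotation with the same 20% overlap rules used for TCs, yielding a
#' (mismatch stratum x context) contingency table of site counts.
#'
#' @param genome Genome object.
#' @param kmer Nucleotide string.
#' @param max_mismatches Maximum Hamming distance.
#' @param annotation Annotation `GRanges`.
#' @return `data.frame` with columns `mismatches`, `context`, `n`.
#' @export
motif_site_census <- function(genome, kmer, max_mismatches, annotation) {
  sites <- genome_kmer_scan(genome, kmer, max_mismatches)
  if (length(sites) == 0L)
    return(data.frame(mismatches = integer(), context = character(),
                      n = integer()))
  sites <- classify_tcs(sites, annotation)
  tab <- as.data.frame(table(mismatches = sites$mismatches,
                             context = sites$context),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  out <- data.frame(mismatches = as.integer(tab$mismatches),
                    context = tab$context, n = tab$Freq,
                    stringsAsFactors = FALSE)
  out[order(out$mismatches, out$context), , drop = FALSE]
}
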