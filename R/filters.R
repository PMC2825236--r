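#' Selection thresholds for candidate calling
#'
#' Bundles the thresholds of the candidate selection cascade:
#'
#' * `strand_ratio_min`: a TC overlapped by opposite-strand TCs is retained
#'   only when its tag-depth is at least this many times the deepest
#'   competing TC (default 10).
#' * `haca_len`, `haca_depth_min`: size window (nt, inclusive) and minimum
#'   tag-depth of box H/ACA snoRNA candidates (120-180 nt, depth >= 15).
#' * `cd_len`, `cd_depth_min`: the box C/D window (60-100 nt, depth >= 6).
#' * `group_depth_min`: minimum tag-depth for unclassified high-depth TCs
#'   (default 100).
#' * `group1_depth_min`: depth separating group 1 from group 2 among TCs
#'   shorter than `short_len_max` nt (default 1000).
#' * `short_len_max`: strict length bound separating groups 1/2 from group 3
#'   (default 40: groups 1 and 2 are shorter than 40 nt).
#' * `exclusion_ids`: TC names excluded from group assignment, e.g. loci
#'   independently identified as transposon-derived.
#'
#' @param strand_ratio_min,haca_len,haca_depth_min,cd_len,cd_depth_min
#'   See above.
#' @param group_depth_min,group1_depth_min,short_len_max,exclusion_ids
#'   See above.
#' @return A list with class `"tc_filter_config"`.
#' @export
filter_config <- function(strand_ratio_min = 10,
                          haca_len = c(120L, 180L), haca_depth_min = 15,
                          cd_len = c(60L, 100L), cd_depth_min = 6,
                          group_depth_min = 100, group1_depth_min = 1000,
                          short_len_max = 40L, exclusion_ids = character()) {
  stopifnot(strand_ratio_min > 1,
            length(haca_len) == 2L, haca_len[1] <= haca_len[2],
            length(cd_len) == 2L, cd_len[1] <= cd_len[2],
            group_depth_min > 0, group1_depth_min > group_depth_min,
            short_len_max > 0)
  structure(list(strand_ratio_min = strand_ratio_min,
                 haca_len = as.integer(haca_len), haca_depth_min = haca_depth_min,
                 cd_len = as.integer(cd_len), cd_depth_min = cd_depth_min,
                 group_depth_min = group_depth_min,
                 group1_depth_min = group1_depth_min,
                 short_len_max = as.integer(short_len_max),
                 exclusion_ids = exclusion_ids),
            class = "tc_filter_config")
}

#' Opposite-strand depth competition filter
#'
#' Transposon-derived loci typically produce overlapping TCs of comparable
#' depth on both strands, whereas genuine ncRNA loci are either unopposed or
#' strongly strand-biased. A TC is retained iff it has no opposite-strand
#' overlapping TC, or its tag-depth is at least `strand_ratio_min` times the
#' maximum depth among opposite-strand TCs overlapping it by >= 1 base.
#'
#' @param tcs TCs to filter (`GRanges` with `tag_depth`).
#' @param config A [filter_config()].
#' @param competitors TC set supplying the opposite-strand competition;
#'   defaults to `tcs` itself. Pass the full TC set when `tcs` is a subset.
#' @return The retained subset of `tcs`.
#' @export
strand_competition_filter <- function(tcs, config = filter_config(),
                                      competitors = tcs) {
  if (length(tcs) == 0L) return(tcs)
  opp <- GenomicRanges::invertStrand(GenomicRanges::granges(competitors))
  ov <- GenomicRanges::findOverlaps(GenomicRanges::granges(tcs), opp)
  if (length(ov) == 0L) return(tcs)
  q <- S4Vectors::queryHits(ov)
  oppmax <- tapply(competitors$tag_depth[S4Vectors::subjectHits(ov)], q, max)
  maxdepth <- rep(0, length(tcs))
  maxdepth[as.integer(names(oppmax))] <- as.numeric(oppmax)
  tcs[maxdepth == 0 | tcs$tag_depth >= config$strand_ratio_min * maxdepth]
}

#' Size/depth/context window filter
#'
#' Retains TCs whose length lies in `len_range` (inclusive at both ends),
#' whose tag-depth is at least `depth_min`, and whose annotation context is
#' one of `contexts`.
#'
#' @param tcs Classified TCs ([classify_tcs()]).
#' @param len_range Integer length window, inclusive.
#' @param depth_min Minimum tag-depth.
#' @param contexts Character vector of admissible contexts.
#' @return The retained subset.
#' @export
window_filter <- function(tcs, len_range, depth_min, contexts) {
  if (is.null(tcs$context)) stop("TCs carry no context; run classify_tcs() first")
  len <- GenomicRanges::width(tcs)
  tcs[len >= len_range[1] & len <= len_range[2] &
      tcs$tag_depth >= depth_min & tcs$context %in% contexts]
}

#' Band unclassified high-depth TCs into groups 1-3
#'
#' Among unannotated TCs with tag-depth at least `group_depth_min`, group 1
#' comprises TCs shorter than `short_len_max` nt with depth >=
#' `group1_depth_min`; group 2 the remaining short TCs; group 3 the TCs of
#' `short_len_max` nt or longer. TCs below `group_depth_min` are
#' `below_threshold`.
#'
#' @param tcs `GRanges` of TCs.
#' @param config A [filter_config()].
#' @return Character vector along `tcs` with values `"group1"`, `"group2"`,
#'   `"group3"`, `"below_threshold"`.
#' @export
assign_group <- function(tcs, config = filter_config()) {
  len <- GenomicRanges::width(tcs)
  depth <- tcs$tag_depth
  out <- rep("below_threshold", length(tcs))
  short <- len < config$short_len_max
  out[short & depth >= config$group1_depth_min] <- "group1"
  out[short & depth >= config$group_depth_min & depth < config$group1_depth_min] <- "group2"
  out[!short & depth >= config$group_depth_min] <- "group3"
  out
}
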