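#' Specification of a synthetic desk-scale fixture
#'
#' Describes a reproducible toy dataset: a random genome with a gene/intron/
#' intergenic architecture, planted ncRNA loci carrying the correct motif
#' grammar, a transposon-like double-stranded decoy, and a tag library
#' sampled as overlapping 18-32 nt windows tiling each planted locus with
#' read counts scaled to reach a target tag-depth, plus uniform background
#' noise tags of depth ~1.
#'
#' @param seed Integer seed; the fixture is a pure function of the spec.
#' @param genome_length Total length (bp) of the two active chromosomes
#'   (default 200 kb); a small excluded `chrM` is always added.
#' @param n_genes Number of two-exon genes hosting the intronic plantings.
#' @param planted `data.frame` describing the planted loci
#'   (see [default_planted()]).
#' @param tag_length_range Tag sizes emitted by the simulated size
#'   fractionation (default 18-32 nt).
#' @param full_length_fraction Fraction of planted snoRNA loci that also
#'   emit a full-length (uncollapsed precursor) tag.
#' @param n_noise_tags Number of background tags at read count 1.
#' @return A list with class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed = 1L, genome_length = 200000L, n_genes = 6L,
                         planted = default_planted(),
                         tag_length_range = c(18L, 32L),
                         full_length_fraction = 0.5, n_noise_tags = 150L) {
  stopifnot(genome_length >= 20000L, n_genes >= 1L,
            tag_length_range[1] >= 12L,
            tag_length_range[1] <= tag_length_range[2],
            full_length_fraction >= 0, full_length_fraction <= 1)
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 n_genes = as.integer(n_genes), planted = planted,
                 tag_length_range = as.integer(tag_length_range),
                 full_length_fraction = full_length_fraction,
                 n_noise_tags = as.integer(n_noise_tags)),
            class = "fixture_spec")
}

#' Default planted loci
#'
#' Three box C/D snoRNAs (74/81/69 nt at target depths 566/42/993, two
#' intronic and one intergenic), two box H/ACA snoRNAs (145 and 143 nt at
#' depths 105 and 234, intronic sense), one 21-nt high-depth locus carrying
#' a GC-rich 18-mer as its dominant tag (depth 5027), and a 300-nt
#' transposon-like decoy expressed at comparable depth from both strands so
#' that it must fail the 10x opposite-strand filter. Lengths and depths
#' follow the size/depth windows the caller uses, so the planted loci are
#' recoverable by design. Optionally adds annotated control ncRNAs (a
#' tRNA-like and a miRNA-like locus, excluded from candidate calling by
#' annotation) and a pair of no-tag k-mer sites (one exact, one at Hamming
#' distance 1) for scan/census tests.
#'
#' @param include_annotated Add the annotated tRNA/miRNA controls.
#' @param include_kmer_sites Add the exact/1-mismatch k-mer site pair.
#' @return `data.frame` with columns `name`, `class`, `length`, `context`,
#'   `target_depth`.
#' @export
default_planted <- function(include_annotated = TRUE,
                            include_kmer_sites = TRUE) {
  p <- data.frame(
    name = c("cd1", "cd2", "cd3", "haca1", "haca2", "grp1", "decoy"),
    class = c("snoRNA_CD", "snoRNA_CD", "snoRNA_CD",
              "snoRNA_HACA", "snoRNA_HACA", "kmer_site", "transposon_like"),
    length = c(74L, 81L, 69L, 145L, 143L, 21L, 300L),
    context = c("intronic", "intronic", "intergenic",
                "intronic", "intronic", "intronic", "intergenic"),
    target_depth = c(566, 42, 993, 105, 234, 5027, 200),
    stringsAsFactors = FALSE)
  if (include_annotated)
    p <- rbind(p, data.frame(
      name = c("trna1", "mir1"), class = c("tRNA_like", "mirna_like"),
      length = c(72L, 22L), context = c("intergenic", "intergenic"),
      target_depth = c(60, 80), stringsAsFactors = FALSE))
  if (include_kmer_sites)
    p <- rbind(p, data.frame(
      name = c("ksite_exact", "ksite_1mm"), class = c("kmer_site_copy", "kmer_site_copy"),
      length = c(18L, 18L), context = c("intergenic", "intronic"),
      target_depth = c(0, 0), stringsAsFactors = FALSE))
  p
}

#' The dominant 18-mer planted in the high-depth short locus
#' @return An 18-nt DNA string.
#' @export
planted_18mer <- function() "GTCCACCCGGGGGCGCCA"

#' @noRd
.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

#' @noRd
.revcomp_chr <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Simulate a fixture in memory
#'
#' Deterministically builds the genome, annotation, conserved elements, tag
#' library and truth table described by a [fixture_spec()]. The caller's RNG
#' state is preserved.
#'
#' @param spec A [fixture_spec()].
#' @return A list: `genome`, `tags`, `annotation` (introns synthesized),
#'   `conserved`, `truth` (`data.frame`), `spec`.
#' @export
simulate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  gl <- spec$genome_length
  len2L <- as.integer(round(0.6 * gl))
  len3R <- gl - len2L
  lenM <- 2000L
  chrom_seq <- list(chr2L = .random_dna(len2L), chr3R = .random_dna(len3R),
                    chrM = .random_dna(lenM))

  # gene architecture on chr2L: exon1(300) - intron(1500) - exon2(300)
  gene_slot <- 4000L
  if (5000L + spec$n_genes * gene_slot > len2L)
    stop("infeasible packing: genome too short for ", spec$n_genes, " genes")
  genes <- data.frame(
    name = sprintf("gene%02d", seq_len(spec$n_genes)),
    start = 5000L + (seq_len(spec$n_genes) - 1L) * gene_slot,
    strand = rep_len(c("+", "-"), spec$n_genes), stringsAsFactors = FALSE)
  genes$end <- genes$start + 2100L - 1L
  intron_start <- genes$start + 300L
  intron_end <- genes$start + 1800L - 1L

  planted <- spec$planted
  intronic <- which(planted$context == "intronic")
  intergenic <- which(planted$context == "intergenic")
  if (length(intronic) > spec$n_genes)
    stop("infeasible packing: more intronic plantings than genes")
  ig_slot <- 3500L
  if (5000L + length(intergenic) * ig_slot > len3R)
    stop("infeasible packing: genome too short for intergenic plantings")

  planted$chrom <- NA_character_
  planted$start <- NA_integer_
  planted$strand <- NA_character_
  planted$host_gene <- NA_character_
  for (j in seq_along(intronic)) {
    i <- intronic[j]
    mid <- (intron_start[j] + intron_end[j]) %/% 2L
    planted$chrom[i] <- "chr2L"
    planted$start[i] <- mid - planted$length[i] %/% 2L
    planted$strand[i] <- genes$strand[j]
    planted$host_gene[i] <- genes$name[j]
  }
  ig_strands <- rep_len(c("-", "+"), length(intergenic))
  for (j in seq_along(intergenic)) {
    i <- intergenic[j]
    planted$chrom[i] <- "chr3R"
    planted$start[i] <- 5000L + (j - 1L) * ig_slot
    planted$strand[i] <- ig_strands[j]
  }
  planted$end <- planted$start + planted$length - 1L

  # planted sequences, 5'->3', with motif boxes overwritten
  kmer2 <- .random_dna(18L)  # no-tag scan target, distinct from the 18-mer
  make_seq <- function(class, L) {
    s <- strsplit(.random_dna(L), "")[[1]]
    put <- function(s, at, what) { s[at:(at + nchar(what) - 1L)] <- strsplit(what, "")[[1]]; s }
    if (class == "snoRNA_CD") {
      s <- put(s, 6L, "ATGATGA")              # box C, starts 5 nt inside 5' end
      s <- put(s, L - 10L, "CTGA")            # box D, ends 7 nt before 3' end
    } else if (class == "snoRNA_HACA") {
      s <- put(s, L %/% 2L - 2L, "ATACGA")    # box H (ANANNA), near midpoint
      s <- put(s, L - 4L, "ACA")              # box ACA, ends 2 nt before 3' end
    } else if (class == "kmer_site") {
      s <- put(s, 2L, planted_18mer())        # dominant 18-mer inside 21-nt locus
    } else if (class == "kmer_site_copy") {
      s <- strsplit(kmer2, "")[[1]]
    }
    paste(s, collapse = "")
  }
  planted$sequence <- vapply(seq_len(nrow(planted)), function(i)
    make_seq(planted$class[i], planted$length[i]), "")
  # the 1-mismatch k-mer copy: substitute one base
  mm1 <- which(planted$class == "kmer_site_copy")
  if (length(mm1) >= 2L) {
    i <- mm1[2L]
    s <- strsplit(planted$sequence[i], "")[[1]]
    s[9L] <- setdiff(c("A", "C", "G", "T"), s[9L])[1L]
    planted$sequence[i] <- paste(s, collapse = "")
  }

  write_into <- function(chrom_seq, chrom, start, seq, strand) {
    if (strand == "-") seq <- .revcomp_chr(seq)
    substr(chrom_seq[[chrom]], start, start + nchar(seq) - 1L) <- seq
    chrom_seq
  }
  for (i in seq_len(nrow(planted)))
    chrom_seq <- write_into(chrom_seq, planted$chrom[i], planted$start[i],
                            planted$sequence[i], planted$strand[i])
  # a copy of the first planted locus on the excluded chrM: placements there
  # must be discarded before multi-mapping weights are computed
  chrom_seq <- write_into(chrom_seq, "chrM", 500L,
                          planted$sequence[1L], planted$strand[1L])

  genome <- as_genome(Biostrings::DNAStringSet(unlist(chrom_seq)))

  # ---- tag library -------------------------------------------------------
  tag_rows <- list()
  add_tag <- function(seq, count) tag_rows[[length(tag_rows) + 1L]] <<-
    data.frame(sequence = seq, read_count = count, stringsAsFactors = FALSE)
  tile_tags <- function(oriented_seq, target_depth, w = 24L, step = 12L) {
    L <- nchar(oriented_seq)
    w <- min(w, L)
    starts <- unique(c(seq(1L, max(1L, L - w + 1L), by = step), L - w + 1L))
    cov <- IRanges::coverage(IRanges::IRanges(starts, width = w))
    count <- ceiling(target_depth / max(cov))
    for (p in starts) add_tag(substr(oriented_seq, p, p + w - 1L), count)
  }
  has_tags <- planted$class %in% c("snoRNA_CD", "snoRNA_HACA", "tRNA_like",
                                   "mirna_like")
  for (i in which(has_tags))
    tile_tags(planted$sequence[i], planted$target_depth[i])
  # full-length precursor tags for a fraction of the planted snoRNAs
  sno <- which(planted$class %in% c("snoRNA_CD", "snoRNA_HACA"))
  n_full <- ceiling(spec$full_length_fraction * length(sno))
  for (i in utils::head(sno, n_full)) add_tag(planted$sequence[i], 2)
  # the short high-depth locus: dominant 18-mer plus the full 21-mer
  for (i in which(planted$class == "kmer_site")) {
    td <- planted$target_depth[i]
    c18 <- floor(0.8 * td)
    add_tag(substr(planted$sequence[i], 2L, 19L), c18)
    add_tag(planted$sequence[i], td - c18)
  }
  # transposon-like decoy: comparable depth from both strands
  for (i in which(planted$class == "transposon_like")) {
    tile_tags(planted$sequence[i], planted$target_depth[i])
    tile_tags(.revcomp_chr(planted$sequence[i]), planted$target_depth[i])
  }
  # background noise: depth-1 tags clear of the planted loci
  avoid <- split(data.frame(s = planted$start - 40L, e = planted$end + 40L),
                 planted$chrom)
  clear_of_planted <- function(chrom, s, e) {
    a <- avoid[[chrom]]
    is.null(a) || !any(s <= a$e & e >= a$s)
  }
  chrom_pick <- sample(c("chr2L", "chr3R"), spec$n_noise_tags, replace = TRUE,
                       prob = c(len2L, len3R))
  n_placed <- 0L
  while (n_placed < spec$n_noise_tags) {
    chrom <- chrom_pick[n_placed + 1L]
    L <- sample(spec$tag_length_range[1]:spec$tag_length_range[2], 1L)
    pos <- sample(nchar(chrom_seq[[chrom]]) - L, 1L)
    if (!clear_of_planted(chrom, pos, pos + L - 1L)) next
    s <- substr(chrom_seq[[chrom]], pos, pos + L - 1L)
    if (sample(c(TRUE, FALSE), 1L)) s <- .revcomp_chr(s)
    add_tag(s, 1)
    n_placed <- n_placed + 1L
  }
  tags <- as_tag_library(do.call(rbind, tag_rows))

  # ---- annotation --------------------------------------------------------
  ann <- list()
  grg <- GenomicRanges::GRanges("chr2L", IRanges::IRanges(genes$start, genes$end),
                                strand = genes$strand)
  grg$feature_class <- "gene"; grg$name <- genes$name; grg$host_gene <- NA_character_
  ex1 <- GenomicRanges::GRanges("chr2L",
    IRanges::IRanges(genes$start, genes$start + 299L), strand = genes$strand)
  ex2 <- GenomicRanges::GRanges("chr2L",
    IRanges::IRanges(genes$start + 1800L, genes$end), strand = genes$strand)
  exs <- c(ex1, ex2)
  exs$feature_class <- "exon"
  exs$name <- paste0(rep(genes$name, 2L), c(rep("_ex1", nrow(genes)), rep("_ex2", nrow(genes))))
  exs$host_gene <- rep(genes$name, 2L)
  ann <- c(ann, list(grg, exs))
  annotated_classes <- c(tRNA_like = "tRNA", mirna_like = "miRNA")
  for (i in which(planted$class %in% names(annotated_classes))) {
    f <- GenomicRanges::GRanges(planted$chrom[i],
      IRanges::IRanges(planted$start[i], planted$end[i]),
      strand = planted$strand[i])
    f$feature_class <- unname(annotated_classes[planted$class[i]])
    f$name <- planted$name[i]; f$host_gene <- NA_character_
    ann <- c(ann, list(f))
  }
  annotation <- add_introns(suppressWarnings(do.call(c, ann)))

  # conserved elements: one over the first H/ACA planting, one intergenic
  cons <- GenomicRanges::GRanges()
  haca_i <- which(planted$class == "snoRNA_HACA")
  if (length(haca_i) > 0L) {
    i <- haca_i[1L]
    mid <- (planted$start[i] + planted$end[i]) %/% 2L
    cons <- GenomicRanges::GRanges(planted$chrom[i],
                                   IRanges::IRanges(mid - 30L, mid + 30L))
  }
  cons <- suppressWarnings(c(cons, GenomicRanges::GRanges("chr3R",
    IRanges::IRanges(len3R - 1500L, len3R - 1300L))))
  cons$feature_class <- "conserved_element"
  cons$name <- paste0("cons", seq_along(cons))
  cons$host_gene <- NA_character_

  expected <- with(planted, ifelse(class == "snoRNA_CD", "snoRNA_CD",
    ifelse(class == "snoRNA_HACA", "snoRNA_HACA",
    ifelse(class == "kmer_site", "group1",
    ifelse(class == "transposon_like", "rejected",
    ifelse(class %in% names(annotated_classes), "annotated", "none"))))))
  truth <- data.frame(name = planted$name, class = planted$class,
                      chrom = planted$chrom, start = planted$start - 1L,
                      end = planted$end, strand = planted$strand,
                      length = planted$length,
                      target_depth = planted$target_depth,
                      context = planted$context, host_gene = planted$host_gene,
                      expected_call = expected, sequence = planted$sequence,
                      stringsAsFactors = FALSE)

  list(genome = genome, tags = tags, annotation = annotation,
       conserved = cons, truth = truth, spec = spec)
}

#' Generate a fixture and write it to disk
#'
#' Writes `genome.fa`, `tags.fa` (counts in headers), `annotation.gff3`,
#' `conserved.bed` and `truth.tsv` under `dir`. Outputs are byte-identical
#' across runs for a fixed spec.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the [simulate_fixture()] list with an added `files`
#'   element of paths.
#' @export
generate_fixture <- function(spec = fixture_spec(), dir) {
  fx <- simulate_fixture(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(genome = file.path(dir, "genome.fa"),
                tags = file.path(dir, "tags.fa"),
                annotation = file.path(dir, "annotation.gff3"),
                conserved = file.path(dir, "conserved.bed"),
                truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(fx$genome, files$genome)
  write_tag_library(fx$tags, files$tags)
  gff <- fx$annotation[fx$annotation$feature_class != "intron"]  # introns are derived
  type_of <- c(gene = "gene", exon = "exon", tRNA = "tRNA", miRNA = "miRNA")
  out <- GenomicRanges::granges(gff)
  out$source <- "tagcontig_sim"
  out$type <- unname(type_of[gff$feature_class])
  out$ID <- gff$name
  out$Name <- gff$name
  rtracklayer::export(out, files$annotation, format = "gff3")
  bed <- GenomicRanges::granges(fx$conserved)
  bed$name <- fx$conserved$name
  bed$score <- 0L
  rtracklayer::export(bed, files$conserved, format = "bed")
  utils::write.table(fx$truth, files$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fx$files <- files
  invisible(fx)
}

#' Join pipeline calls to the fixture truth table
#'
#' A planted locus counts as recovered when a call of its expected class on
#' the same strand overlaps it by at least `min_overlap` of the planted
#' length. Decoy rows (`expected_call == "rejected"`) are verified to have
#' attracted no call at all.
#'
#' @param result A `tc_pipeline_result` ([run_pipeline()]).
#' @param truth The fixture truth `data.frame`.
#' @param min_overlap Minimum overlap fraction of the planted length.
#' @return A list: `recall`, `precision`, `decoy_rejected` (logical),
#'   `detail` (per-truth-row `data.frame`).
#' @export
evaluate_recovery <- function(result, truth, min_overlap = 0.5) {
  calls <- result$calls
  cgr <- if (nrow(calls) > 0L)
    GenomicRanges::GRanges(calls$chrom,
                           IRanges::IRanges(calls$start + 1L, calls$end),
                           strand = calls$strand)
  else GenomicRanges::GRanges()
  tgr <- GenomicRanges::GRanges(truth$chrom,
                                IRanges::IRanges(truth$start + 1L, truth$end),
                                strand = truth$strand)
  matched_call <- rep(NA_integer_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    if (length(cgr) == 0L) break
    ov <- GenomicRanges::findOverlaps(tgr[i], cgr,
      minoverlap = as.integer(ceiling(min_overlap * truth$length[i])))
    hits <- S4Vectors::subjectHits(ov)
    hits <- hits[calls$call_class[hits] == truth$expected_call[i]]
    if (length(hits) > 0L) matched_call[i] <- hits[1L]
  }
  is_cand <- truth$expected_call %in% c("snoRNA_CD", "snoRNA_HACA",
                                        "group1", "group2", "group3")
  recall <- if (any(is_cand)) mean(!is.na(matched_call[is_cand])) else NA_real_
  decoy <- truth$expected_call == "rejected"
  decoy_rejected <- !any(decoy) || length(cgr) == 0L ||
    !any(IRanges::overlapsAny(tgr[decoy], cgr, ignore.strand = TRUE))
  precision <- if (nrow(calls) > 0L)
    sum(!is.na(matched_call)) / nrow(calls) else NA_real_
  list(recall = recall, precision = precision,
       decoy_rejected = decoy_rejected,
       detail = cbind(truth[, c("name", "class", "expected_call")],
                      matched_call = matched_call))
}
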