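test_that("fixture generation is byte-identical for a fixed seed and differs across seeds", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir(); d3 <- withr::local_tempdir()
  generate_fixture(fixture_spec(seed = 9, genome_length = 60000L, n_genes = 6L,
                                n_noise_tags = 30L), d1)
  generate_fixture(fixture_spec(seed = 9, genome_length = 60000L, n_genes = 6L,
                                n_noise_tags = 30L), d2)
  generate_fixture(fixture_spec(seed = 10, genome_length = 60000L, n_genes = 6L,
                                n_noise_tags = 30L), d3)
  for (f in c("genome.fa", "tags.fa", "annotation.gff3", "conserved.bed", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d3, "genome.fa"))))
})

test_that("the truth table is complete and planted loci carry their motif grammar", {
  fx <- simulate_fixture(fixture_spec(seed = 13))
  tr <- fx$truth
  expect_true(all(c("name", "class", "chrom", "start", "end", "strand",
                    "length", "target_depth", "expected_call") %in% names(tr)))
  expect_true(all(tr$end - tr$start == tr$length))
  expect_true(all(tr$chrom %in% names(fx$genome)))
  for (i in which(tr$class == "snoRNA_CD")) {
    expect_match(substr(tr$sequence[i], 6, 12), "^[AG]TGATGA$")
    L <- tr$length[i]
    expect_equal(substr(tr$sequence[i], L - 10, L - 7), "CTGA")
  }
  for (i in which(tr$class == "snoRNA_HACA")) {
    L <- tr$length[i]
    h <- substr(tr$sequence[i], L %/% 2 - 2, L %/% 2 + 3)
    expect_equal(iupac_mismatch_count("ANANNA", h), 0L)
    expect_equal(substr(tr$sequence[i], L - 4, L - 2), "ACA")
  }
  # the genome really contains each planted sequence in its stated orientation
  for (i in seq_len(nrow(tr))) {
    got <- as.character(Biostrings::subseq(fx$genome[[tr$chrom[i]]],
                                           tr$start[i] + 1L, tr$end[i]))
    if (tr$strand[i] == "-") got <- revcomp(got)
    expect_equal(got, tr$sequence[i])
  }
})

test_that("planted loci reach their target depths and the decoy fails the strand filter", {
  fx <- simulate_fixture(fixture_spec(seed = 17))
  pl <- distribute_reads(map_tags_exact(fx$genome, fx$tags), fx$tags)
  tcs <- build_tag_contigs(pl)
  tr <- fx$truth
  tgr <- GRanges(tr$chrom, IRanges(tr$start + 1L, tr$end), strand = tr$strand)
  for (i in which(tr$target_depth > 0)) {
    ov <- findOverlaps(tgr[i], tcs)
    expect_true(length(ov) >= 1L, label = tr$name[i])
    d <- max(tcs$tag_depth[subjectHits(ov)])
    expect_true(d >= tr$target_depth[i] && d <= tr$target_depth[i] + 5,
                label = paste(tr$name[i], "depth", d))
  }
  # the transposon-like region yields overlapping TCs on both strands,
  # neither of which survives the 10x competition
  decoy <- tgr[tr$expected_call == "rejected"]
  dt <- tcs[overlapsAny(tcs, decoy, ignore.strand = TRUE)]
  expect_setequal(as.character(strand(dt)), c("+", "-"))
  kept <- strand_competition_filter(dt, filter_config(), competitors = tcs)
  expect_equal(length(kept), 0L)
})

test_that("infeasible packings are rejected with a hard error", {
  expect_error(simulate_fixture(fixture_spec(seed = 1, genome_length = 40000L,
                                             n_genes = 6L)),
               "infeasible packing")
  expect_error(simulate_fixture(fixture_spec(seed = 1, n_genes = 3L)),
               "infeasible packing")
})

test_that("fixture files round-trip through the package readers", {
  d <- withr::local_tempdir()
  fx <- generate_fixture(fixture_spec(seed = 21, genome_length = 80000L,
                                      n_noise_tags = 40L), d)
  g <- read_genome(fx$files$genome)
  expect_equal(names(g), names(fx$genome))
  expect_equal(excluded_chroms(g), "chrM")
  tags <- read_tag_library(fx$files$tags)
  expect_equal(tags$sequence, fx$tags$sequence)
  expect_equal(tags$read_count, fx$tags$read_count)
  ann <- read_annotation(fx$files$annotation, "gff3", genome = g)
  for (cls in c("gene", "exon", "intron", "tRNA", "miRNA"))
    expect_equal(sum(ann$feature_class == cls),
                 sum(fx$annotation$feature_class == cls), label = cls)
  cons <- read_conserved_elements(fx$files$conserved, genome = g)
  expect_equal(length(cons), length(fx$conserved))
  expect_equal(start(cons), start(fx$conserved))
})
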