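tc_at <- function(chrom, start, end, strand) {
  GRanges(chrom, IRanges(start, end), strand = strand)
}

test_that("IUPAC mismatch counting uses set membership per position", {
  expect_equal(iupac_mismatch_count("RTGATGA", "ATGATGA"), 0L)
  expect_equal(iupac_mismatch_count("RTGATGA", "GTGATGA"), 0L)
  expect_equal(iupac_mismatch_count("RTGATGA", "CTGATGA"), 1L)
  expect_equal(iupac_mismatch_count("ANANNA", "ATACGA"), 0L)
  expect_equal(iupac_mismatch_count("ANANNA", "TTACGA"), 1L)
  # RNA input is normalized
  expect_equal(iupac_mismatch_count("RUGAUGA", "AUGAUGA"), 0L)
  expect_error(iupac_mismatch_count("ACG", "ACGT"), "length")
  # agreement with Biostrings' IUPAC-aware edit distance on random windows
  set.seed(151)
  pats <- c("RTGATGA", "CTGA", "ANANNA", "NRYSWKM")
  for (p in pats) {
    wins <- replicate(60, random_dna_str(nchar(p)))
    want <- vapply(wins, function(w)
      as.integer(Biostrings::neditAt(Biostrings::DNAString(p),
                                     Biostrings::DNAString(w),
                                     at = 1, fixed = "subject")), 1L,
      USE.NAMES = FALSE)
    expect_equal(iupac_mismatch_count(p, wins), want)
  }
})

test_that("anchored searches find planted boxes near the correct TC ends", {
  set.seed(163)
  # 74-nt TC with box C 5 nt inside the 5' end and box D ending 7 nt before the 3' end
  body <- strsplit(random_dna_str(74), "")[[1]]
  body[6:12] <- strsplit("ATGATGA", "")[[1]]
  body[64:67] <- strsplit("CTGA", "")[[1]]
  chr <- paste0(random_dna_str(200), paste(body, collapse = ""), random_dna_str(200))
  g <- toy_genome(chr1 = chr)
  tc <- tc_at("chr1", 201, 274, "+")
  ch <- anchored_search(tc, g, box_c_spec())
  expect_equal(ch$mismatches, 0L)
  expect_equal(ch$offset, 5L)
  expect_equal(ch$start, 206L)
  pair <- call_box_cd(tc, g)
  expect_false(is.null(pair))
  expect_equal(pair$d_hit$matched_sequence, "CTGA")
})

test_that("motifs may lie outside the TC; absent motifs return NULL", {
  set.seed(167)
  chr <- paste0(strrep("T", 100), strrep("G", 50), "ACA", strrep("T", 100))
  g <- toy_genome(chr1 = chr)
  # ACA starts 8 nt downstream of the TC 3' end (TC ends at 142, ACA at 151)
  tc <- tc_at("chr1", 101, 142, "+")
  hit <- anchored_search(tc, g, box_aca_spec())
  expect_false(is.null(hit))
  expect_equal(hit$start, 151L)
  # no admissible window position within the mismatch budget
  g2 <- toy_genome(chr1 = strrep("G", 300))
  expect_null(anchored_search(tc_at("chr1", 101, 142, "+"), g2, box_aca_spec()))
})

test_that("box C/D calling requires both boxes in order, on either strand identically", {
  set.seed(173)
  body <- strsplit(random_dna_str(74), "")[[1]]
  body[6:12] <- strsplit("ATGATGA", "")[[1]]
  body[64:67] <- strsplit("CTGA", "")[[1]]
  sno <- paste(body, collapse = "")
  left <- random_dna_str(150); right <- random_dna_str(150)
  g_plus <- toy_genome(chr1 = paste0(left, sno, right))
  g_minus <- toy_genome(chr1 = paste0(left, revcomp(sno), right))
  tc_p <- tc_at("chr1", 151, 224, "+")
  tc_m <- tc_at("chr1", 151, 224, "-")
  p <- call_box_cd(tc_p, g_plus)
  m <- call_box_cd(tc_m, g_minus)
  expect_false(is.null(p))
  expect_false(is.null(m))
  # identical hits in the TC frame; mirrored genomic coordinates
  expect_equal(m$c_hit$offset, p$c_hit$offset)
  expect_equal(m$d_hit$offset, p$d_hit$offset)
  expect_equal(m$c_hit$matched_sequence, p$c_hit$matched_sequence)
  expect_equal(m$c_hit$start - 151, 224 - p$c_hit$end)
  # box C alone is not a call: make the whole 3' search window CTGA-free
  # (an all-C stretch is 3 mismatches from CTGA at every offset)
  nod <- body; nod[50:74] <- "C"
  g_nod <- toy_genome(chr1 = paste0(left, paste(nod, collapse = ""),
                                    strrep("C", 30), right))
  expect_null(call_box_cd(tc_at("chr1", 151, 224, "+"), g_nod))
})

test_that("box H/ACA calling enforces the midpoint and 3' windows", {
  set.seed(179)
  L <- 145
  body <- strsplit(gsub("A", "G", random_dna_str(L)), "")[[1]]  # suppress chance ANANNA
  mid <- L %/% 2
  body[(mid - 3):(mid + 2)] <- strsplit("ACACGA", "")[[1]]
  body[(L - 4):(L - 2)] <- strsplit("ACA", "")[[1]]
  chr <- paste0(strrep("C", 200), paste(body, collapse = ""), strrep("C", 200))
  g <- toy_genome(chr1 = chr)
  tc <- tc_at("chr1", 201, 200 + L, "+")
  pair <- call_box_haca(tc, g)
  expect_false(is.null(pair))
  expect_equal(pair$h_hit$mismatches, 0L)
  # an H motif 40 nt from the midpoint is out of window
  far <- strsplit(gsub("A", "G", random_dna_str(L)), "")[[1]]
  far[(mid - 40):(mid - 35)] <- strsplit("ACACGA", "")[[1]]
  far[(L - 4):(L - 2)] <- strsplit("ACA", "")[[1]]
  g_far <- toy_genome(chr1 = paste0(strrep("C", 200), paste(far, collapse = ""),
                                    strrep("C", 200)))
  expect_null(call_box_haca(tc, g_far))
})

test_that("genome k-mer scanning reports each site once at its exact mismatch count", {
  set.seed(181)
  kmer <- "GTCCACCCGGGGGCGCCA"
  mut <- strsplit(kmer, "")[[1]]; mut[7] <- "T"
  chr <- paste0(random_dna_str(3000), kmer, random_dna_str(2000),
                paste(mut, collapse = ""), random_dna_str(1000),
                revcomp(kmer), random_dna_str(500))
  g <- toy_genome(chr1 = chr)
  h0 <- genome_kmer_scan(g, kmer, 0)
  expect_equal(sum(h0$mismatches == 0L), 2L)  # forward + reverse plant
  expect_setequal(as.character(strand(h0)), c("+", "-"))
  h1 <- genome_kmer_scan(g, kmer, 1)
  expect_equal(sum(h1$mismatches == 1L), 1L)
  expect_equal(start(h1[h1$mismatches == 1L]), 3000 + 18 + 2000 + 1L)
  # monotone: stratum m hits are a subset of the m+1 scan
  k0 <- paste(start(h0), strand(h0))
  k1 <- paste(start(h1), strand(h1))
  expect_true(all(k0 %in% k1))
})

test_that("k-mer scanning matches the exhaustive Hamming oracle and mirrors under reverse complement", {
  set.seed(191)
  kmer <- random_dna_str(18)
  pieces <- character(0)
  for (mm in c(0, 1, 2, 2)) {
    s <- strsplit(kmer, "")[[1]]
    if (mm > 0) {
      at <- sample(18, mm)
      s[at] <- vapply(s[at], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    }
    pieces <- c(pieces, random_dna_str(2500), paste(s, collapse = ""))
  }
  chr1 <- paste0(paste(pieces, collapse = ""), random_dna_str(1000))
  chr2 <- paste0(random_dna_str(2000), revcomp(kmer), random_dna_str(800))
  g <- toy_genome(chr1 = chr1, chr2 = chr2)
  for (m in 0:2) {
    expect_equal(scan_as_df(genome_kmer_scan(g, kmer, m)),
                 oracle_kmer_scan(g, kmer, m))
  }
  # reverse-complemented genome: same sites, strands flipped, coords mirrored
  g_rc <- toy_genome(chr1 = revcomp(chr1), chr2 = revcomp(chr2))
  fwd <- scan_as_df(genome_kmer_scan(g, kmer, 2))
  rcv <- scan_as_df(genome_kmer_scan(g_rc, kmer, 2))
  lens <- c(chr1 = nchar(chr1), chr2 = nchar(chr2))
  mirrored <- data.frame(chrom = fwd$chrom,
                         start = lens[fwd$chrom] - (fwd$start + 17L) + 1L,
                         strand = ifelse(fwd$strand == "+", "-", "+"),
                         mismatches = fwd$mismatches)
  mirrored <- mirrored[order(mirrored$chrom, mirrored$start, mirrored$strand), ]
  rownames(mirrored) <- NULL
  expect_equal(rcv, mirrored, ignore_attr = TRUE)
})
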