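test_that("planted tags are found at their loci on the correct strands", {
  set.seed(11)
  tag <- "ACGTACGTACGTACGTAC"
  chr <- paste0(random_dna_str(500), tag, random_dna_str(300),
                revcomp(tag), random_dna_str(200))
  g <- toy_genome(chr1 = chr)
  tags <- as_tag_library(data.frame(tag_id = "t1", sequence = tag, read_count = 4))
  pl <- map_tags_exact(g, tags)
  expect_equal(length(pl), 2L)
  expect_equal(as.character(strand(pl)), c("+", "-"))
  expect_equal(start(pl), c(501L, 501L + nchar(tag) + 300L))
  expect_equal(unique(pl$n_loci), 2L)
})

test_that("exact mapping agrees with a brute-force sliding-window scan", {
  set.seed(23)
  chr <- random_dna_str(50000)
  g <- toy_genome(chr1 = chr)
  # half sampled from the genome (guaranteed hits), half random 20-mers
  pos <- sample(50000 - 20, 100)
  seqs <- unique(c(substring(chr, pos, pos + 19),
                   replicate(100, random_dna_str(20))))
  tags <- as_tag_library(data.frame(sequence = seqs, read_count = 50))
  pl <- map_tags_exact(g, tags)
  got <- data.frame(start = start(pl), strand = as.character(strand(pl)),
                    tag = tags$sequence[match(pl$tag_id, tags$tag_id)],
                    stringsAsFactors = FALSE)
  want <- do.call(rbind, lapply(tags$sequence, function(s) {
    rbind(
      if (nrow(h <- oracle_hamming(chr, s, 0L)))
        data.frame(start = h$start, strand = "+", tag = s),
      if (nrow(h <- oracle_hamming(chr, revcomp(s), 0L)))
        data.frame(start = h$start, strand = "-", tag = s))
  }))
  key <- function(d) sort(paste(d$start, d$strand, d$tag))
  expect_equal(key(got), key(want))
})

test_that("placements on excluded chromosomes are discarded before n_loci is counted", {
  set.seed(31)
  tag <- random_dna_str(20)
  g <- toy_genome(chr1 = paste0(random_dna_str(100), tag, random_dna_str(100)),
                  chrM = paste0(random_dna_str(50), tag, random_dna_str(50)))
  tags <- as_tag_library(data.frame(sequence = tag, read_count = 3))
  pl <- map_tags_exact(g, tags)
  expect_equal(length(pl), 1L)
  expect_equal(as.character(seqnames(pl)), "chr1")
  expect_equal(pl$n_loci, 1L)  # the chrM hit never enters the count
  w <- distribute_reads(pl, tags)
  expect_equal(w$weight, 3)   # full read mass stays on the retained locus
})

test_that("a tag longer than every chromosome yields zero placements, not an error", {
  g <- toy_genome(chr1 = random_dna_str(30))
  tags <- as_tag_library(data.frame(sequence = random_dna_str(50), read_count = 2))
  expect_silent(pl <- map_tags_exact(g, tags))
  expect_equal(length(pl), 0L)
})

test_that("reads are split evenly over loci and over-mapped tags are discarded entirely", {
  set.seed(41)
  t6 <- random_dna_str(18); t2 <- random_dna_str(18); t1 <- random_dna_str(18)
  chr <- paste0(random_dna_str(50), t6, random_dna_str(20), t6,
                random_dna_str(20), t6, random_dna_str(50),
                paste(rep(paste0(t2, random_dna_str(10)), 5), collapse = ""),
                t1, random_dna_str(50))
  g <- toy_genome(chr1 = chr)
  tags <- as_tag_library(data.frame(tag_id = c("a", "b", "c"),
                                    sequence = c(t6, t2, t1),
                                    read_count = c(6, 2, 1)))
  pl <- map_tags_exact(g, tags)
  w <- distribute_reads(pl, tags)
  a <- w[w$tag_id == tags$tag_id[tags$sequence == t6]]
  expect_equal(length(a), 3L)
  expect_equal(unique(a$weight), 2)      # 6 reads over 3 loci
  expect_false(any(w$tag_id == tags$tag_id[tags$sequence == t2]))  # 5 loci > 2 reads
  c1 <- w[w$tag_id == tags$tag_id[tags$sequence == t1]]
  expect_equal(c1$weight, 1)
  # read-mass conservation over retained tags
  retained <- tags$read_count[tags$tag_id %in% unique(w$tag_id)]
  expect_equal(sum(w$weight), sum(retained), tolerance = 1e-9)
})

test_that("reverse-complementing the genome mirrors placements onto the other strand", {
  set.seed(53)
  chr <- random_dna_str(3000)
  g1 <- toy_genome(chr1 = chr)
  g2 <- toy_genome(chr1 = revcomp(chr))
  pos <- sample(2900, 20)
  tags <- as_tag_library(data.frame(sequence = substring(chr, pos, pos + 19),
                                    read_count = 9))
  p1 <- map_tags_exact(g1, tags)
  p2 <- map_tags_exact(g2, tags)
  expect_equal(length(p1), length(p2))
  L <- nchar(chr)
  flip <- data.frame(start = L - end(p1) + 1L,
                     strand = ifelse(as.character(strand(p1)) == "+", "-", "+"),
                     tag = p1$tag_id)
  got <- data.frame(start = start(p2), strand = as.character(strand(p2)),
                    tag = p2$tag_id)
  key <- function(d) sort(paste(d$start, d$strand, d$tag))
  expect_equal(key(got), key(flip))
})
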