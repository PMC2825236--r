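suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

toy_genome <- function(..., exclude = c("chrM", "chrU", "chrUextra")) {
  as_genome(Biostrings::DNAStringSet(c(...)), exclude = exclude)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# GRanges of weighted placements from a compact spec (1-based closed coords)
placements_gr <- function(chrom, start, end, strand, weight,
                          tag_id = sprintf("t%03d", seq_along(start))) {
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  gr$tag_id <- tag_id
  gr$weight <- weight
  gr
}

# Brute-force oracle for contig assembly + tag-depth: connected components of
# the >=1-nt-overlap graph per (chrom, strand), depth by literal per-base
# accumulation of member weights.
oracle_contigs <- function(pl) {
  out <- list()
  df <- data.frame(chrom = as.character(seqnames(pl)), start = start(pl),
                   end = end(pl), strand = as.character(strand(pl)),
                   weight = pl$weight, stringsAsFactors = FALSE)
  for (key in unique(paste(df$chrom, df$strand))) {
    sub <- df[paste(df$chrom, df$strand) == key, , drop = FALSE]
    n <- nrow(sub)
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (comp[i] != comp[j] &&
            sub$start[i] <= sub$end[j] && sub$end[i] >= sub$start[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cc in unique(comp)) {
      m <- sub[comp == cc, , drop = FALSE]
      lo <- min(m$start); hi <- max(m$end)
      depth_per_base <- vapply(lo:hi, function(b)
        sum(m$weight[m$start <= b & m$end >= b]), 0)
      out[[length(out) + 1L]] <- data.frame(
        chrom = m$chrom[1L], start = lo, end = hi, strand = m$strand[1L],
        tag_depth = max(depth_per_base), n_tags = nrow(m),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$end, res$strand), , drop = FALSE]
}

# Brute-force Hamming scan oracle: mismatch count of the k-mer at every
# full-length window of the forward string (vectorized over pattern columns).
oracle_hamming <- function(seq_str, kmer, max_mm) {
  s <- strsplit(seq_str, "")[[1]]
  p <- strsplit(kmer, "")[[1]]
  k <- length(p)
  L <- length(s)
  if (L < k) return(data.frame(start = integer(), mismatches = integer()))
  mm <- integer(L - k + 1L)
  for (j in seq_len(k)) mm <- mm + (s[j:(L - k + j)] != p[j])
  keep <- which(mm <= max_mm)
  data.frame(start = keep, mismatches = mm[keep])
}

# Both-strand oracle against a genome, matching genome_kmer_scan's output
oracle_kmer_scan <- function(genome, kmer, max_mm) {
  rows <- list()
  for (chrom in active_chroms(genome)) {
    fwd <- as.character(genome[[chrom]])
    for (str in c("+", "-")) {
      pat <- if (str == "+") kmer else revcomp(kmer)
      h <- oracle_hamming(fwd, pat, max_mm)
      if (nrow(h))
        rows[[length(rows) + 1L]] <- data.frame(chrom = chrom, start = h$start,
                                                strand = str,
                                                mismatches = h$mismatches)
    }
  }
  if (!length(rows)) return(data.frame(chrom = character(), start = integer(),
                                       strand = character(),
                                       mismatches = integer()))
  res <- do.call(rbind, rows)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

scan_as_df <- function(hits) {
  if (length(hits) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), mismatches = integer()))
  df <- data.frame(chrom = as.character(seqnames(hits)), start = start(hits),
                   strand = as.character(strand(hits)),
                   mismatches = hits$mismatches, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# dyadic weights (multiples of 1/8) sum without rounding error in any order,
# so implementation and oracle can be compared exactly
dyadic_weights <- function(n) sample(1:24, n, replace = TRUE) / 8
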