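# Independent oracles. These deliberately avoid the package's code paths:
# exhaustive enumeration for the fold, character-by-character sliding scans
# for mapping / homology / seed sites, and textbook closed forms for the
# correlation.

oracle_pairable <- function(a, b) {
  p <- paste0(a, b)
  p %in% c("AT", "TA", "CG", "GC", "GT", "TG")
}

# maximum base pairs over all nested structures, by exhaustive recursion
# (no memoization; feasible for length <= 14)
oracle_max_pairs <- function(seq) {
  ch <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  rec <- function(idx) {
    if (length(idx) < 2L) return(0L)
    i <- idx[1]
    rest <- idx[-1]
    best <- rec(rest)
    for (k in rest) {
      if (k - i <= 3L) next
      if (oracle_pairable(ch[i], ch[k])) {
        inside <- rest[rest > i & rest < k]
        outside <- rest[rest > k]
        cand <- 1L + rec(inside) + rec(outside)
        if (cand > best) best <- cand
      }
    }
    best
  }
  rec(seq_along(ch))
}

# all exact occurrences of a tag in a genome string, both strands,
# position-by-position
oracle_exact_loci <- function(tag, genome_str, chrom = "chr1") {
  out <- list()
  L <- nchar(tag)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tag)))
  for (i in seq_len(max(0L, nchar(genome_str) - L + 1L))) {
    piece <- substr(genome_str, i, i + L - 1L)
    if (piece == tag) {
      out[[length(out) + 1L]] <- data.frame(chrom = chrom, start = i - 1L,
                                            end = i - 1L + L, strand = "+")
    }
    if (piece == rc) {
      out[[length(out) + 1L]] <- data.frame(chrom = chrom, start = i - 1L,
                                            end = i - 1L + L, strand = "-")
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  do.call(rbind, out)
}

# position-by-position canonical seed-site scan with strongest-type overlap
# resolution
oracle_seed_sites <- function(mirna, utr) {
  mirna <- toupper(chartr("U", "T", mirna))
  utr <- toupper(chartr("U", "T", utr))
  rc1 <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  s78 <- rc1(substr(mirna, 2, 8))
  s67 <- rc1(substr(mirna, 2, 7))
  found <- list()
  n <- nchar(utr)
  for (p in seq_len(n)) {
    if (p + 6L <= n && substr(utr, p, p + 6L) == s78) {
      if (p + 7L <= n && substr(utr, p + 7L, p + 7L) == "A") {
        found[[length(found) + 1L]] <- data.frame(type = "8mer", start = p - 1L,
                                                  end = p + 7L)
      } else {
        found[[length(found) + 1L]] <- data.frame(type = "7mer-m8",
                                                  start = p - 1L, end = p + 6L)
      }
    }
    if (p + 6L <= n && substr(utr, p, p + 5L) == s67 &&
        substr(utr, p + 6L, p + 6L) == "A") {
      found[[length(found) + 1L]] <- data.frame(type = "7mer-1A",
                                                start = p - 1L, end = p + 6L)
    }
  }
  if (length(found) == 0) {
    return(data.frame(type = character(0), start = integer(0),
                      end = integer(0)))
  }
  df <- do.call(rbind, found)
  prio <- c("8mer" = 3L, "7mer-m8" = 2L, "7mer-1A" = 1L)
  df <- df[order(-prio[df$type], df$start), , drop = FALSE]
  kept <- rep(FALSE, nrow(df))
  for (i in seq_len(nrow(df))) {
    kept[i] <- !any(kept & df$start < df$end[i] & df$end > df$start[i])
  }
  df <- df[kept, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# textbook closed-form Pearson correlation
oracle_pcc <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# brute-force 5'-anchored homology scan: at every offset on both strands,
# the covered region is the longest mature prefix ending in a match with
# at most one interior mismatch
oracle_homology_hits <- function(mature, genome_str, min_coverage = 0.8) {
  m <- nchar(mature)
  hits <- 0L
  scan_dir <- function(g) {
    found <- 0L
    for (o in seq_len(nchar(g))) {
      avail <- min(m, nchar(g) - o + 1L)
      if (avail / m <= min_coverage) next
      mism <- which(strsplit(substr(g, o, o + avail - 1L), "")[[1]] !=
                      strsplit(substr(mature, 1, avail), "")[[1]])
      L <- if (length(mism) >= 2L) mism[2] - 1L else avail
      while (L %in% mism) L <- L - 1L
      mm <- sum(mism <= L)
      if (L / m > min_coverage && mm <= 1L) found <- found + 1L
    }
    found
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(genome_str)))
  scan_dir(genome_str) + scan_dir(rc)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a base guaranteed to mismatch the given base
blocker <- function(base) setdiff(c("A", "C", "G", "T"), base)[1]
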