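# Novel-candidate discovery: mapping filters, precursor excision, rule-based
# calling and the permutation signal-to-noise control.

fake_mapped <- function(n_loci_per_tag, repeat_hits = integer(0)) {
  n <- length(n_loci_per_tag)
  tags <- data.frame(sequence = vapply(rep(20, n), random_seq, character(1)),
                     L = rep(1L, n), n_loci = n_loci_per_tag)
  loci <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- n_loci_per_tag[i]
    if (k == 0) return(NULL)
    data.frame(tag = i, chrom = "chr1",
               start = seq(100 * i, by = 40, length.out = k),
               end = seq(100 * i, by = 40, length.out = k) + 20L,
               strand = "+")
  }))
  if (is.null(loci)) {
    loci <- data.frame(tag = integer(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0))
  }
  list(tags = tags, loci = loci)
}

test_that("mapping-multiplicity and repeat filters follow the published rule", {
  mapped <- fake_mapped(c(1L, 5L, 6L, 0L))
  filt <- filter_mappings(mapped, NULL, max_loci = 5)
  # 1 and exactly 5 loci retained; 6 loci and unmapped discarded
  expect_equal(nrow(filt$tags), 2)
  expect_setequal(filt$tags$n_loci, c(1L, 5L))

  # a single locus inside a repeat interval discards the tag
  rep_track <- GenomicRanges::GRanges("chr1", IRanges::IRanges(90, 140))
  mapped1 <- fake_mapped(c(1L, 1L))  # tag 1 at 100-120, tag 2 at 200-220
  filt1 <- filter_mappings(mapped1, rep_track)
  expect_equal(nrow(filt1$tags), 1)
  expect_equal(filt1$loci$start, 200)

  # idempotence
  expect_identical(filter_mappings(filt1, rep_track), filt1)
})

test_that("precursor windows are clipped, deduplicated and cover the locus", {
  g <- Biostrings::DNAStringSet(c(chr1 = random_seq(2000)))
  filt <- list(
    tags = data.frame(sequence = c(random_seq(22), random_seq(22)),
                      L = c(5L, 3L), n_loci = c(1L, 1L)),
    loci = data.frame(tag = c(1L, 2L), chrom = "chr1",
                      start = c(10L, 12L), end = c(32L, 34L), strand = "+")
  )
  win <- excise_precursors(filt, g, flank = 70)
  expect_true(all(win$start >= 0))            # clipped at the chromosome start
  expect_true(all(win$end <= 2000))
  # the two overlapping loci form one cluster: two windows, not four
  expect_equal(length(unique(win$cluster_id)), 1)
  expect_equal(nrow(win), 2)
  # each window contains the anchor locus
  expect_true(all(win$start <= win$anchor_start & win$end >= win$anchor_end))
})

test_that("one excised window contains each well-supported planted precursor", {
  b <- tiny_bundle()
  an <- analyzed_bundle(b, "tiny1")
  rep_track <- b$genome$catalog$tracks[
    b$genome$catalog$tracks$category == "repeat"]
  filt <- filter_mappings(list(tags = an$tags, loci = an$loci), rep_track)
  win <- excise_precursors(filt, b$genome$genome)
  hp <- b$genome$catalog$hairpins
  mat_counts <- rowSums(b$libs$countable[hp$mirna_id, , drop = FALSE])
  for (i in which(mat_counts >= 20)) {
    covered <- any(win$chrom == hp$chrom[i] & win$strand == hp$strand[i] &
                     win$start <= hp$start0[i] &
                     win$end >= hp$start0[i] + nchar(hp$sequence[i]))
    expect_true(covered, info = hp$hairpin_id[i])
  }
})

test_that("planted hairpins are called; scattered stacks are rejected", {
  b <- tiny_bundle()
  an <- analyzed_bundle(b, "tiny1")
  rep_track <- b$genome$catalog$tracks[
    b$genome$catalog$tracks$category == "repeat"]
  filt <- filter_mappings(list(tags = an$tags, loci = an$loci), rep_track)
  win <- excise_precursors(filt, b$genome$genome)
  stacks <- build_read_stacks(win, filt, b$genome$genome)
  calls <- call_candidates(stacks)

  hp <- b$genome$catalog$hairpins
  mat_counts <- rowSums(b$libs$countable[hp$mirna_id, , drop = FALSE])
  pass <- calls[calls$passes, ]
  for (i in which(mat_counts >= 20)) {
    called <- any(pass$chrom == hp$chrom[i] & pass$strand == hp$strand[i] &
                    pass$start < hp$start0[i] + 53 & pass$end > hp$start0[i])
    expect_true(called, info = hp$hairpin_id[i])
  }

  # a stack of uniformly scattered reads across an unstructured window
  # fails arm-consistency
  withr::with_seed(13, wseq <- random_seq(160))
  members <- data.frame(rel_start = seq(1, 120, by = 12),
                        rel_end = seq(1, 120, by = 12) + 21L,
                        sequence = substring(wseq, seq(1, 120, by = 12),
                                             seq(1, 120, by = 12) + 21L),
                        L = rep(3L, 10))
  members$total <- members$L
  scattered <- structure(list(
    window = data.frame(window_id = "w-x", chrom = "chr1", start = 0L,
                        end = 160L, strand = "+", cluster_id = 99L),
    sequence = wseq, members = members), class = "read_stack")
  res <- call_candidates(list("w-x" = scattered))
  expect_false(res$rule_arms)
  expect_false(res$passes)
})

test_that("a stack split across mature and star arms still passes", {
  b <- tiny_bundle()
  hp <- b$genome$catalog$hairpins[1, ]
  flank5 <- random_seq(40)
  flank3 <- random_seq(40)
  wseq <- paste0(flank5, hp$sequence, flank3)
  m_start <- 41L
  s_start <- 41L + hp$star_start - 1L
  members <- data.frame(
    rel_start = c(m_start, s_start),
    rel_end = c(m_start + 21L, s_start + 21L),
    sequence = c(substr(hp$sequence, 1, 22),
                 substr(hp$sequence, hp$star_start, hp$star_end)),
    L = c(50L, 50L))
  members$total <- members$L
  st <- structure(list(
    window = data.frame(window_id = "w-b", chrom = "chr1", start = 0L,
                        end = nchar(wseq), strand = "+", cluster_id = 1L),
    sequence = wseq, members = members), class = "read_stack")
  res <- call_candidates(list("w-b" = st))
  expect_true(res$rule_hairpin)
  expect_true(res$rule_arms)
  expect_true(res$passes)
})

test_that("permutation preserves composition and totals, deterministically", {
  b <- tiny_bundle()
  an <- analyzed_bundle(b, "tiny1")
  tags <- an$tags
  p1 <- permute_reads(tags, seed = 99)
  p2 <- permute_reads(tags, seed = 99)
  expect_identical(p1$sequence, p2$sequence)
  p3 <- permute_reads(tags, seed = 100)
  expect_false(identical(p1$sequence, p3$sequence))
  # per-tag base composition and length preserved
  comp <- function(s) vapply(strsplit(s, ""), function(x) {
    paste(sort(x), collapse = "")
  }, character(1))
  expect_identical(comp(p1$sequence), comp(tags$sequence))
  # counts untouched: per-library totals conserved exactly
  expect_identical(p1$layer, tags$layer)
  expect_identical(p1$broiler, tags$broiler)
})

test_that("permuted data yields fewer candidates than real data", {
  b <- tiny_bundle()
  an <- analyzed_bundle(b, "tiny1")
  rep_track <- b$genome$catalog$tracks[
    b$genome$catalog$tracks$category == "repeat"]
  run_calls <- function(tags) {
    mapped <- map_exact(tags, b$genome$genome)
    filt <- filter_mappings(mapped, rep_track)
    win <- excise_precursors(filt, b$genome$genome)
    calls <- call_candidates(build_read_stacks(win, filt, b$genome$genome))
    mirgallus:::count_candidate_loci(calls)
  }
  n_real <- run_calls(an$tags[, c("sequence", "layer", "broiler")])
  for (s in c(101, 202, 303)) {
    n_perm <- run_calls(permute_reads(an$tags, seed = s))
    expect_lt(n_perm, n_real)
  }
  expect_gt(n_real, 0)
})

test_that("signal-to-noise arithmetic matches the published example", {
  snr <- signal_to_noise(222, 16)
  expect_equal(snr$ratio, 222 / 16)
  expect_equal(snr$ratio_rounded, 14L)
  expect_false(snr$degenerate_denominator)

  deg <- signal_to_noise(10, 0)
  expect_equal(deg$ratio, 10)
  expect_true(deg$degenerate_denominator)

  expect_equal(signal_to_noise(0, 5)$ratio, 0)
})
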