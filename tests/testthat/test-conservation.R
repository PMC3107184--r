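# Fold engine, homology scan, hairpin pairing rule, lineage classification.

test_that("simple folds are exact", {
  f <- fold_hairpin("GGGGAAAACCCC")
  expect_equal(f$n_pairs, 4)
  expect_equal(f$structure, "((((....))))")
  expect_equal(f$pairs[1], 12)

  f0 <- fold_hairpin("AAAAAAAAAAAA")
  expect_equal(f0$n_pairs, 0)
  expect_equal(f0$structure, strrep(".", 12))

  expect_error(fold_hairpin("ACGTXXGT"), "invalid characters")
  expect_error(fold_hairpin(random_seq(501)), "<= 500")
})

test_that("fold structures are well-formed (balanced, min loop 3)", {
  withr::with_seed(31, seqs <- vapply(rep(30, 20), random_seq, character(1)))
  for (s in seqs) {
    f <- fold_hairpin(s)
    p <- f$pairs
    idx <- which(!is.na(p))
    expect_true(all(p[p[idx]] == idx))            # mutual consistency
    expect_true(all(abs(p[idx] - idx) >= 4))      # min hairpin loop of 3
    expect_equal(mirgallus::fold_from_dotbracket(f$structure)$pairs, p)
  }
})

test_that("fold pair counts equal exhaustive enumeration up to 14 nt", {
  withr::with_seed(41, {
    seqs <- c("GGGGAAAACCCC", "ACGTACGTACGTAC",
              vapply(sample(8:14, 40, replace = TRUE), random_seq, character(1)))
  })
  for (s in seqs) {
    expect_equal(fold_hairpin(s)$n_pairs, oracle_max_pairs(s), label = s)
  }
})

test_that("homology acceptance enforces coverage, mismatches and 5' anchoring", {
  withr::with_seed(8, {
    mature <- random_seq(22)
    left <- random_seq(400)
    right <- random_seq(400)
  })
  # exact full-length copy: accepted with coverage 1, 0 mismatches
  g_exact <- paste0(left, mature, right)
  h <- scan_homology(mature, g_exact)
  best <- h[which.max(h$covered_length), ]
  expect_equal(best$coverage_fraction, 1)
  expect_equal(best$mismatches, 0)
  expect_true(best$anchored_5p)

  mutate_at <- function(s, pos) {
    for (p in pos) {
      old <- substr(s, p, p)
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    s
  }
  # only positions 1-17 matchable (coverage 17/22 = 0.773 <= 0.80): rejected;
  # blockers stop the covered region from extending into the flank by chance
  g_prefix <- paste0(left, substr(mature, 1, 17),
                     blocker(substr(mature, 18, 18)),
                     blocker(substr(mature, 19, 19)), right)
  expect_equal(nrow(scan_homology(mature, g_prefix)), 0)
  # full-length with 2 mismatches: rejected ("fewer than two" = at most 1)
  g_mm2 <- paste0(left, mutate_at(mature, c(5, 15)), right)
  expect_equal(nrow(scan_homology(mature, g_mm2)), 0)
  # full-length with 1 mismatch: accepted
  g_mm1 <- paste0(left, mutate_at(mature, 15), right)
  expect_gt(nrow(scan_homology(mature, g_mm1)), 0)
  # positions 3-22 only (not 5'-anchored): rejected; the flank boundary is
  # blocked so the 5' end cannot re-anchor by chance
  g_unanchored <- paste0(left, blocker(substr(mature, 1, 1)),
                         blocker(substr(mature, 2, 2)),
                         substr(mature, 3, 22), right)
  expect_equal(nrow(scan_homology(mature, g_unanchored)), 0)
  # genome shorter than the minimal covered prefix: empty result
  expect_equal(nrow(scan_homology(mature, "ACGTACGT")), 0)
})

test_that("the scan agrees with a brute-force all-offsets Hamming oracle", {
  withr::with_seed(9, {
    for (rep in 1:5) {
      mature <- random_seq(22)
      g <- random_seq(2000)
      # plant one exact and one single-mismatch copy
      substr(g, 501, 522) <- mature
      one_mm <- mature
      substr(one_mm, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                        substr(one_mm, 10, 10))[1]
      substr(g, 1201, 1222) <- one_mm
      got <- nrow(scan_homology(mature, g))
      expect_equal(got, oracle_homology_hits(mature, g))
      expect_gte(got, 2)
    }
  })
})

test_that("tightening the coverage threshold never adds accepted hits", {
  withr::with_seed(10, {
    mature <- random_seq(22)
    g <- random_seq(1500)
    substr(g, 301, 322) <- mature
    substr(g, 901, 918) <- substr(mature, 1, 18)  # partial copy
  })
  n_loose <- nrow(scan_homology(mature, g, min_coverage = 0.8))
  n_tight <- nrow(scan_homology(mature, g, min_coverage = 0.95))
  expect_lte(n_tight, n_loose)
})

test_that("hairpin_check thresholds the mature-star paired fraction strictly", {
  mature <- "TAGCTTATCAGACTGATGTTGA"
  loop <- "AACAAACAA"
  star_perfect <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(mature)))
  hp <- paste0(mature, loop, star_perfect)
  f <- fold_hairpin(hp)
  expect_true(hairpin_check(f, c(1, 22), c(32, 53)))

  # unstructured: nothing pairs, fraction 0
  f_flat <- fold_hairpin(strrep("A", 53))
  expect_false(hairpin_check(f_flat, c(1, 22), c(32, 53)))

  # at most 15/22 = 0.682 positions pairable into the star: below the
  # strict 0.70 bound. The mature avoids G so the C-run in the broken star
  # region cannot re-pair anywhere in the mature.
  mature15 <- "TACCTTATCAACACTAATTTCA"
  star15 <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(mature15))), "")[[1]]
  star15[16:22] <- "C"
  hp15 <- paste0(mature15, loop, paste(star15, collapse = ""))
  f15 <- fold_hairpin(hp15)
  pos <- 1:22
  frac <- mean(!is.na(f15$pairs[pos]) & f15$pairs[pos] >= 32 &
                 f15$pairs[pos] <= 53)
  expect_lte(frac, 15 / 22)
  expect_false(hairpin_check(f15, c(1, 22), c(32, 53)))

  expect_error(hairpin_check(f, c(1, 22), c(20, 40)), "must not overlap")
})

test_that("lineage classification follows the conservation hierarchy", {
  six <- c(human = FALSE, mouse = FALSE, rat = FALSE, opossum = FALSE,
           frog = FALSE, zebrafish = FALSE)
  # present in zebrafish and frog only: still vertebrate-conserved
  zf <- six; zf[c("zebrafish", "frog")] <- TRUE
  expect_equal(classify_lineage(zf, TRUE), "vertebrate_conserved")
  expect_equal(classify_lineage(six, TRUE), "avian_specific")
  expect_equal(classify_lineage(six, FALSE), "chicken_specific")

  # 32 candidates, none vertebrate-conserved, 19 in zebra finch -> 13 specific
  calls <- vapply(seq_len(32), function(i) {
    classify_lineage(six, i <= 19)
  }, character(1))
  expect_equal(sum(calls == "chicken_specific"), 13)
})

test_that("planted homologs are detected and decoys rejected", {
  b <- tiny_bundle()
  matures <- setNames(b$genome$catalog$mirnas$sequence,
                      b$genome$catalog$mirnas$id)
  mat <- conservation_matrix(matures, b$species_genomes)
  for (id in names(matures)) {
    planted <- b$truth$planted_homolog_map[[id]]
    for (sp in colnames(mat)) {
      expect_equal(mat[id, sp], as.integer(sp %in% planted),
                   info = paste(id, sp))
    }
  }
  # rows sum equals independent per-species accepts
  expect_equal(unname(rowSums(mat)),
               unname(lengths(b$truth$planted_homolog_map[names(matures)])))

  # 3-mismatch decoys are never accepted
  withr::with_seed(12, {
    for (rep in 1:5) {
      m <- random_seq(22)
      decoy <- m
      for (p in c(3, 11, 19)) {
        substr(decoy, p, p) <- setdiff(c("A", "C", "G", "T"),
                                       substr(decoy, p, p))[1]
      }
      g <- random_seq(1000)
      substr(g, 401, 422) <- decoy
      expect_false(homolog_in_genome(m, g))
    }
  })
})
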