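# Annotation cascade, expression table, arm comparison and isomiR stacks.

# minimal hand-built catalog for cascade unit tests
toy_catalog <- function(mirna_seq, rrna_range = NULL, mrna_range = NULL) {
  ranges <- list()
  if (!is.null(rrna_range)) ranges$rRNA <- rrna_range
  if (!is.null(mrna_range)) ranges$mRNA <- mrna_range
  gr <- if (length(ranges) > 0) {
    GenomicRanges::GRanges(
      "chr1",
      IRanges::IRanges(vapply(ranges, `[`, numeric(1), 1),
                       vapply(ranges, `[`, numeric(1), 2)),
      strand = "+", category = names(ranges),
      feature_id = paste0(names(ranges), "-1"))
  } else {
    GenomicRanges::GRanges()
  }
  structure(list(
    mirnas = data.frame(id = "mir-x", sequence = mirna_seq,
                        stringsAsFactors = FALSE),
    stars = data.frame(id = character(0), sequence = character(0)),
    metazoan_mirnas = data.frame(id = character(0), sequence = character(0)),
    metazoan_stars = data.frame(id = character(0), sequence = character(0)),
    hairpins = data.frame(),
    tracks = gr
  ), class = "ref_catalog")
}

test_that("the 20-25 nt / 19-nt prefix counting rule is enforced exactly", {
  ref <- "TAGCTTATCAGACTGATGTTGA"  # 22 nt
  p19 <- substr(ref, 1, 19)
  expect_true(match_mirna_prefix(paste0(p19, "AAA"), ref))     # 22 nt, 3' tail free
  expect_false(match_mirna_prefix(p19, ref))                   # 19 nt: too short
  expect_false(match_mirna_prefix(paste0(p19, "AAAAAAA"), ref)) # 26 nt: too long
  expect_true(match_mirna_prefix(paste0(p19, "T"), ref))       # 20 nt boundary
  expect_true(match_mirna_prefix(paste0(p19, "GGGGGG"), ref))  # 25 nt boundary
  expect_false(match_mirna_prefix(paste0("A", substr(ref, 2, 22)), ref))
  expect_error(match_mirna_prefix("ACGTACGTACGTACGTACGT", "ACGT"), "19 nt")
})

test_that("cascade priority: miRNA beats rRNA beats mRNA; first hit wins", {
  mirna <- "TAGCTTATCAGACTGATGTTGA"
  tag <- paste0(substr(mirna, 1, 19), "CCC")
  cat1 <- toy_catalog(mirna, rrna_range = c(1, 100), mrna_range = c(1, 100))
  tags <- data.frame(sequence = tag, L = 5L)
  loci <- data.frame(tag = 1L, chrom = "chr1", start = 10L,
                     end = 10L + nchar(tag), strand = "+")
  res <- annotate_cascade(tags, cat1, loci)
  # sequence rule outranks every interval class even with a locus inside rRNA
  expect_equal(res$assignments$category, "chicken_miRNA")
  expect_equal(res$assignments$matched_ids, "mir-x")

  # same tag without a prefix match falls through to the first interval class
  cat2 <- toy_catalog("GGGGGGGGGGGGGGGGGGGGGG", rrna_range = c(1, 100),
                      mrna_range = c(1, 100))
  res2 <- suppressWarnings(annotate_cascade(tags, cat2, loci))
  expect_equal(res2$assignments$category, "rRNA")

  # mRNA only reached when no earlier class claims the tag
  cat3 <- toy_catalog("GGGGGGGGGGGGGGGGGGGGGG", mrna_range = c(1, 100))
  res3 <- suppressWarnings(annotate_cascade(tags, cat3, loci))
  expect_equal(res3$assignments$category, "mRNA")

  # nothing matches: unannotated
  cat4 <- toy_catalog("GGGGGGGGGGGGGGGGGGGGGG")
  res4 <- suppressWarnings(annotate_cascade(tags, cat4, NULL))
  expect_equal(res4$assignments$category, "unannotated")
})

test_that("the cascade order is the fixed published order", {
  expect_identical(mirgallus:::ANNOTATION_ORDER,
                   c("chicken_miRNA", "chicken_miRNA_star", "metazoan_miRNA",
                     "metazoan_miRNA_star", "snoRNA", "snRNA", "rRNA", "tRNA",
                     "mRNA", "repeat"))
})

test_that("category totals partition the library reads", {
  b <- tiny_bundle()
  an <- analyzed_bundle(b, "tiny1")
  totals <- an$annotation$category_totals
  expect_equal(unname(colSums(totals)),
               unname(vapply(b$libs$libraries, nrow, integer(1))))
})

test_that("planted reads annotate to their source categories (diagonal)", {
  b <- tiny_bundle()
  an <- analyzed_bundle(b, "tiny1")
  # every countable planted mature read (5' offset 0, 20-25 nt) is credited
  # to its miRNA in the expression table
  countable <- b$libs$countable
  for (id in b$genome$catalog$mirnas$id) {
    for (lib in c("layer", "broiler")) {
      planted <- countable[id, lib]
      got <- an$expr_tab[[lib]][an$expr_tab$mirna_id == id]
      if (planted > 0) expect_gte(got, planted)
    }
  }
  # contaminant classes receive at least 95% of the reads planted from them
  # (a read may be claimed by an earlier class if it also maps there)
  totals <- an$annotation$category_totals
  for (cl in c("snoRNA", "snRNA", "rRNA", "tRNA", "mRNA", "repeat")) {
    planted <- sum(vapply(b$libs$libraries, function(df) {
      sum(df$source_category == cl)
    }, numeric(1)))
    expect_gte(sum(totals[cl, ]), 0.95 * planted)
  }
})

test_that("expression-table ratios follow the printed display convention", {
  tags <- data.frame(sequence = sprintf("SEQ%02d", 1:4),
                     layer = c(222998L, 32663L, 1409L, 91L),
                     broiler = c(131609L, 87111L, 9002L, 1038L))
  ann <- list(assignments = data.frame(
    sequence = tags$sequence, category = "chicken_miRNA",
    matched_ids = c("gga-miR-206", "gga-let-7c", "gga-miR-130b", "gga-miR-15c"),
    stringsAsFactors = FALSE))
  tab <- build_expression_table(ann, tags)
  bl <- setNames(tab$bl_display, tab$mirna_id)
  expect_equal(bl[["gga-miR-206"]], 0.59)
  expect_equal(bl[["gga-let-7c"]], 2.67)
  expect_equal(bl[["gga-miR-130b"]], 6.39)
  expect_equal(bl[["gga-miR-15c"]], 11.4)
})

test_that("a zero layer count gives an undefined ratio", {
  tags <- data.frame(sequence = "S1", layer = 0L, broiler = 17L)
  ann <- list(assignments = data.frame(sequence = "S1",
                                       category = "chicken_miRNA",
                                       matched_ids = "mir-z"))
  tab <- build_expression_table(ann, tags)
  expect_true(is.na(tab$ratio))
  expect_true(is.na(tab$bl_display))
})

test_that("a multi-matching tag is credited to every matching miRNA", {
  tags <- data.frame(sequence = "S1", layer = 10L, broiler = 20L)
  ann <- list(assignments = data.frame(sequence = "S1",
                                       category = "chicken_miRNA",
                                       matched_ids = "mir-a,mir-b"))
  tab <- build_expression_table(ann, tags)
  expect_setequal(tab$mirna_id, c("mir-a", "mir-b"))
  expect_equal(tab$layer, c(10L, 10L))
})

test_that("arm comparison reproduces the star-dominant and similar-level calls", {
  mature <- data.frame(
    mirna_id = c("gga-miR-181a", "gga-miR-199", "gga-miR-1329"),
    layer = c(2015L, 91L, 16L), broiler = c(2543L, 318L, 123L),
    ratio = NA_real_, bl_display = NA_real_)
  star <- data.frame(
    mirna_id = c("gga-miR-181a*", "gga-miR-199*", "gga-miR-1329*",
                 "gga-miR-140*", "gga-miR-126*"),
    layer = c(142L, 26L, 36L, 911L, 11L),
    broiler = c(32L, 133L, 44L, 711L, 28L),
    ratio = NA_real_, bl_display = NA_real_)
  arms <- arm_comparison(mature, star)
  row <- function(id) arms[arms$mirna_id == id, ]
  expect_true(row("gga-miR-140")$star_dominant)    # mature (0,0), star (911,711)
  expect_true(row("gga-miR-126")$star_dominant)
  expect_false(row("gga-miR-181a")$star_dominant)
  expect_false(row("gga-miR-181a")$similar_levels) # 4558 vs 174: ~26-fold
  expect_true(row("gga-miR-199")$similar_levels)   # 409 vs 159: ~2.6-fold
  expect_true(row("gga-miR-1329")$similar_levels)  # 139 vs 80: ~1.7-fold

  # both arms silent: excluded
  none <- arm_comparison(
    data.frame(mirna_id = "m", layer = 0L, broiler = 0L,
               ratio = NA_real_, bl_display = NA_real_),
    data.frame(mirna_id = "m*", layer = 0L, broiler = 0L,
               ratio = NA_real_, bl_display = NA_real_))
  expect_equal(nrow(none), 0)
})

test_that("isomiR stacks flag non-reference dominance and break ties by offset", {
  hairpin <- list(hairpin_id = "hp-t", sequence = paste0(
    "GGACG", "TAGCTTATCAGACTGATGTTGA", "AACAAACAA",
    "TCAACATCAGTCTGATAAGCTA", "CGTCC"), mature_start = 6L, mature_end = 27L)
  ref <- substr(hairpin$sequence, 6, 27)
  shifted <- substr(hairpin$sequence, 7, 28)   # +1/+1 isoform
  trimmed <- substr(hairpin$sequence, 6, 25)   # 0/-2 isoform

  tags <- data.frame(sequence = c(ref, shifted), layer = c(50L, 10L),
                     broiler = c(40L, 5L))
  st <- isomir_profile(tags, hairpin)
  expect_false(attr(st, "nonref_dominant"))
  expect_true(st$is_reference[attr(st, "most_abundant")])

  tags2 <- data.frame(sequence = c(ref, shifted), layer = c(5L, 50L),
                      broiler = c(5L, 40L))
  st2 <- isomir_profile(tags2, hairpin)
  expect_true(attr(st2, "nonref_dominant"))

  # equal totals: the smaller |5' offset| row wins
  tags3 <- data.frame(sequence = c(shifted, trimmed), layer = c(30L, 30L),
                      broiler = c(0L, 0L))
  st3 <- isomir_profile(tags3, hairpin)
  top <- st3[attr(st3, "most_abundant"), ]
  expect_equal(top$offset_5p, 0L)
  expect_equal(top$offset_3p, -2L)

  # tags outside the hairpin contribute nothing
  expect_null(isomir_profile(
    data.frame(sequence = "GGGTTTGGGTTTGGGTTTGG", layer = 1L, broiler = 0L),
    hairpin))
})
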