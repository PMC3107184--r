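# Synthetic-data generator: determinism, ground-truth integrity, and the
# planted signals every downstream stage is validated against.

test_that("generation is deterministic given a seed and config", {
  cfg <- tiny_config(seed = 3L)
  g1 <- gen_genome(cfg)
  g2 <- gen_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$features, g2$features)
  expect_identical(g1$catalog$mirnas, g2$catalog$mirnas)

  t1 <- plan_ground_truth(cfg, g1$catalog)
  t2 <- plan_ground_truth(cfg, g2$catalog)
  expect_identical(t1$de, t2$de)

  u1 <- gen_utrs(cfg, g1$catalog, t1)
  u2 <- gen_utrs(cfg, g2$catalog, t2)
  expect_identical(u1, u2)
})

test_that("a config with no miRNAs yields an empty miRNA track, no failure", {
  cfg <- tiny_config(seed = 2L, n_mirnas = 0L, n_de_mirnas = 0L,
                     n_true_targets = 0L)
  g <- gen_genome(cfg)
  expect_equal(sum(g$tracks$category == "miRNA_hairpin"), 0)
  expect_equal(nrow(g$catalog$mirnas), 0)
  expect_gt(length(g$tracks), 0)
})

test_that("infeasible feature packing fails explicitly", {
  expect_error(gen_genome(tiny_config(seed = 1L, genome_length = 5000L)),
               "infeasible packing")
})

test_that("every planted precursor passes the fold + pairing hairpin rules", {
  hp <- tiny_bundle()$genome$catalog$hairpins
  for (i in seq_len(nrow(hp))) {
    f <- fold_hairpin(hp$sequence[i])
    expect_true(hairpin_check(f, c(hp$mature_start[i], hp$mature_end[i]),
                              c(hp$star_start[i], hp$star_end[i])),
                info = hp$hairpin_id[i])
  }
})

test_that("emitted libraries conserve the configured read totals exactly", {
  b <- tiny_bundle()
  expect_identical(vapply(b$libs$libraries, nrow, integer(1)),
                   b$config$library_sizes)
})

test_that("star-dominant loci emit star reads only", {
  b <- tiny_bundle()
  sd_id <- b$truth$star_dominant_ids
  expect_length(sd_id, 1)
  for (lib in b$libs$libraries) {
    expect_equal(sum(lib$source_id == sd_id), 0)
    expect_gt(sum(lib$source_id == paste0(sd_id, "*")), 0)
  }
})

test_that("observed count ratios of planted DE miRNAs track their folds", {
  b <- tiny_bundle(seed = 7L)
  up <- b$truth$de[b$truth$de$direction == "broiler_up", ]
  expect_gt(nrow(up), 0)
  for (i in seq_len(nrow(up))) {
    n_l <- sum(b$libs$libraries$layer$source_id == up$mirna_id[i])
    n_b <- sum(b$libs$libraries$broiler$source_id == up$mirna_id[i])
    if (n_l < 100) next  # sampling error dominates tiny loci
    ratio <- n_b / n_l
    expect_gt(ratio, up$fold[i] * 0.7, label = up$mirna_id[i])
    expect_lt(ratio, up$fold[i] * 1.4, label = up$mirna_id[i])
  }
})

test_that("the expression matrix has 9 x 2 x 3 = 54 sample columns at defaults", {
  b <- tiny_bundle()
  expect_equal(ncol(b$expression$matrix), 54)
  expect_equal(nrow(b$expression$manifest), 54)
  expect_setequal(unique(b$expression$manifest$timepoint),
                  c("E10", "E12", "E14", "E18", "D1", "W2", "W4", "W6", "W8"))
})

test_that("noiseless planted folds are exact and targets oppose their miRNA", {
  cfg <- tiny_config(seed = 4L, noise_sd = 0)
  g <- gen_genome(cfg)
  truth <- plan_ground_truth(cfg, g$catalog)
  em <- gen_expression_matrix(cfg, truth)
  man <- em$manifest
  mir_dir <- setNames(truth$de$direction, truth$de$mirna_id)
  for (i in seq_len(nrow(truth$true_targets))) {
    gene <- truth$true_targets$gene_id[i]
    mdir <- mir_dir[[truth$true_targets$mirna_id[i]]]
    b_mean <- mean(em$matrix[gene, man$sample_id[man$timepoint == "E10" &
                                                   man$breed == "broiler"]])
    l_mean <- mean(em$matrix[gene, man$sample_id[man$timepoint == "E10" &
                                                   man$breed == "layer"]])
    ratio <- b_mean / l_mean
    # gene direction is opposite to the miRNA's, with an exact 2-fold offset
    if (mdir == "broiler_up") expect_equal(ratio, 0.5) else expect_equal(ratio, 2)
  }
})

test_that("planted co-expressed PPI pairs correlate; random pairs are free", {
  cfg <- tiny_config(seed = 5L, noise_sd = 0)
  g <- gen_genome(cfg)
  truth <- plan_ground_truth(cfg, g$catalog)
  em <- gen_expression_matrix(cfg, truth)
  expect_gt(nrow(truth$coexpr_pairs), 0)
  for (i in seq_len(nrow(truth$coexpr_pairs))) {
    r <- pcc(em$matrix[truth$coexpr_pairs$gene_a[i], ],
             em$matrix[truth$coexpr_pairs$gene_b[i], ])
    expect_equal(r, 1)  # identical planted profiles in the noiseless limit
  }

  expect_equal(nrow(gen_ppi_edges(tiny_config(seed = 5L, n_ppi_edges = 0L,
                                              n_true_targets = 0L),
                                  plan_ground_truth(tiny_config(seed = 5L,
                                                                n_ppi_edges = 0L,
                                                                n_true_targets = 0L),
                                                    g$catalog))), 0)
})

test_that("most planted PPI pairs survive the correlation filter at 0.3", {
  b <- tiny_bundle()
  true_edges <- b$ppi[b$ppi$planted, c("gene_a", "gene_b")]
  kept <- filter_ppi(true_edges, b$expression$matrix, r_cut = 0.3)
  expect_gte(nrow(kept) / nrow(true_edges), 0.9)
})

test_that("UTRs carry exactly the planted sites; negatives carry none", {
  b <- tiny_bundle()
  matures <- setNames(b$genome$catalog$mirnas$sequence,
                      b$genome$catalog$mirnas$id)
  planted <- rbind(b$truth$true_targets[, c("mirna_id", "gene_id")],
                   b$truth$site_only_genes[, c("mirna_id", "gene_id")])
  for (i in seq_len(nrow(planted))) {
    sites <- find_seed_sites(matures[[planted$mirna_id[i]]],
                             b$utrs[[planted$gene_id[i]]])
    expect_gte(nrow(sites), 1)
    expect_true("8mer" %in% sites$type)
  }
  negatives <- setdiff(names(b$utrs), planted$gene_id)
  for (g in head(negatives, 10)) {
    for (m in matures) {
      expect_equal(nrow(find_seed_sites(m, b$utrs[[g]])), 0)
    }
  }
})

test_that("ground truth passes referential integrity against its catalog", {
  b <- tiny_bundle()
  expect_true(validate_ground_truth(b$truth, b$genome$catalog))
  bad <- b$truth
  bad$de$mirna_id[1] <- "mir-nonexistent"
  expect_error(validate_ground_truth(bad, b$genome$catalog), "not in catalog")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(isomir_5p_probs = c(0.5, 0.5, 0, 0, 0.1)),
               "summing to 1")
  expect_error(sim_config(de_fold_range = c(0.5, 2)), "exceed 1")
  expect_error(sim_config(library_sizes = c(0, 100)), "positive")
})
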