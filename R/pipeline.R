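# Pipeline orchestration: one validated configuration drives all stages in
# dependency order (simulate -> preprocess -> annotate -> diffexp ->
# [conservation, novel] -> network) and produces a machine-readable run
# report. Every numeric threshold of the analysis lives in the config with
# its published default.

#' Default pipeline configuration
#'
#' @return nested list of defaults; see [validate_config()] for the fields.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    output_dir = "mirgallus_out",
    simulate = TRUE,
    input_dir = NULL,
    adapter = "TCGTATGCCGTCTTCTGCTTG",
    library_size_basis = "mapped",
    stages = list(preprocess = TRUE, annotate = TRUE, diffexp = TRUE,
                  conservation = TRUE, novel = TRUE, network = TRUE),
    thresholds = list(
      alpha = 1e-4,      # LRT significance cutoff
      fold = 1.5,        # microarray fold-change gate
      p = 0.05,          # microarray t-test cutoff
      r_cut = 0.3,       # |PCC| cutoff for target-target edges
      coverage = 0.8,    # homology coverage (strict lower bound)
      pairing = 0.7,     # mature-star pairing fraction (strict lower bound)
      max_loci = 5L,     # mapping-multiplicity cutoff
      prefix_len = 19L,  # 5' prefix length of the miRNA counting rule
      tag_len = c(20L, 25L),
      read_len = c(16L, 30L),
      flank = 70L,
      min_overlap = 5L   # adapter trimming overlap
    ),
    sim = list()
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

config_error <- function(errors) {
  stop(structure(class = c("mirgallus_config_error", "error", "condition"),
                 list(message = paste0("invalid configuration:\n",
                                       paste("-", errors, collapse = "\n")),
                      call = NULL, errors = errors)))
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path, a YAML string, or a list; merges it over
#' [default_pipeline_config()] and checks every threshold against its
#' documented range. All violations are reported together; no partial
#' configuration is ever returned.
#'
#' @param config path, YAML text or list.
#' @return validated configuration list (class `pipeline_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (file.exists(config)) yaml::read_yaml(config)
              else yaml::yaml.load(config)
  }
  if (!is.list(config)) config_error("configuration must be a mapping")
  cfg <- merge_config(default_pipeline_config(), config)
  th <- cfg$thresholds
  errors <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)

  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed),
      "seed: must be an integer")
  chk(is.numeric(th$alpha) && th$alpha > 0 && th$alpha < 1,
      "thresholds.alpha: must be in (0, 1)")
  chk(is.numeric(th$p) && th$p > 0 && th$p < 1,
      "thresholds.p: must be in (0, 1)")
  chk(is.numeric(th$fold) && th$fold > 1, "thresholds.fold: must exceed 1")
  chk(is.numeric(th$r_cut) && th$r_cut >= 0 && th$r_cut <= 1,
      "thresholds.r_cut: must be in [0, 1]")
  chk(is.numeric(th$coverage) && th$coverage > 0 && th$coverage < 1,
      "thresholds.coverage: must be in (0, 1)")
  chk(is.numeric(th$pairing) && th$pairing > 0 && th$pairing < 1,
      "thresholds.pairing: must be in (0, 1)")
  chk(is.numeric(th$max_loci) && th$max_loci >= 1,
      "thresholds.max_loci: must be >= 1")
  chk(is.numeric(th$prefix_len) && th$prefix_len >= 1,
      "thresholds.prefix_len: must be >= 1")
  chk(length(th$tag_len) == 2L && th$tag_len[1] <= th$tag_len[2],
      "thresholds.tag_len: must be an ordered pair")
  chk(length(th$read_len) == 2L && th$read_len[1] <= th$read_len[2],
      "thresholds.read_len: must be an ordered pair")
  chk(is.numeric(th$flank) && th$flank >= 10,
      "thresholds.flank: must be >= 10")
  chk(cfg$library_size_basis %in% c("mapped", "raw"),
      "library_size_basis: must be 'mapped' or 'raw'")
  if (!isTRUE(cfg$simulate)) {
    chk(!is.null(cfg$input_dir) && dir.exists(cfg$input_dir),
        "input_dir: must exist when simulate is false")
  }
  if (length(errors) > 0) config_error(errors)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

data_error <- function(msg) {
  stop(structure(class = c("mirgallus_data_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order on a synthetic bundle
#' (or a bundle directory written by [write_bundle()]), writes all stage
#' artifacts under `output_dir`, and returns the run report. Identical
#' configuration and seed give identical artifacts and report (timing
#' fields aside).
#'
#' @param config anything accepted by [validate_config()].
#' @return the run report (class `run_report`), invisibly also written as
#'   `report.json` under the output directory.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  th <- cfg$thresholds
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package_version = as.character(utils::packageVersion("mirgallus")),
                 config = unclass(cfg), stages = list())
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- expr
    list(value = val, seconds = round(proc.time()[["elapsed"]] - t0, 2))
  }

  # --- simulate / load inputs ---------------------------------------------
  sim_args <- c(list(seed = cfg$seed), cfg$sim)
  bundle <- if (isTRUE(cfg$simulate)) {
    st <- t_stage(simulate_bundle(do.call(sim_config, sim_args)))
    report$stages$simulate <- list(status = "ok", seconds = st$seconds,
                                   n_mirna_loci = nrow(st$value$genome$catalog$mirnas),
                                   reads_per_library = vapply(st$value$libs$libraries,
                                                              nrow, integer(1)))
    write_bundle(st$value, file.path(cfg$output_dir, "bundle"))
    st$value
  } else {
    st <- t_stage(read_bundle(cfg$input_dir))
    report$stages$load <- list(status = "ok", seconds = st$seconds)
    st$value
  }
  catalog <- bundle$genome$catalog
  genome <- bundle$genome$genome
  message("[mirgallus] inputs ready")

  # --- preprocess ----------------------------------------------------------
  if (!isTRUE(cfg$stages$preprocess)) {
    report$stages$preprocess <- list(status = "skipped")
    return(finish_report(report, cfg))
  }
  st <- t_stage({
    adapter <- if (!is.null(bundle$config)) bundle$config$adapter else cfg$adapter
    raw <- if (isTRUE(cfg$simulate)) {
      # reconstruct the 36-cycle machine reads: insert + adapter, truncated
      lapply(bundle$libs$libraries, function(df) {
        substr(paste0(df$sequence, adapter), 1L, 36L)
      })
    } else {
      lapply(bundle$libs$libraries, function(df) df$sequence)
    }
    trimmed <- lapply(raw, trim_adapter, adapter = adapter,
                      min_overlap = th$min_overlap)
    kept <- lapply(trimmed, filter_length, min_len = th$read_len[1],
                   max_len = th$read_len[2])
    tags <- collapse_reads(kept)
    mapped <- map_exact(tags, genome)
    summaries <- lapply(names(kept), function(lib) {
      summarize_library(mapped$tags, lib)
    })
    names(summaries) <- names(kept)
    list(tags = mapped$tags, loci = mapped$loci, summaries = summaries)
  })
  pre <- st$value
  mapped_totals <- vapply(pre$summaries, `[[`, numeric(1), "mapped_reads")
  report$stages$preprocess <- list(
    status = "ok", seconds = st$seconds,
    reads_in = vapply(bundle$libs$libraries, nrow, integer(1)),
    unique_tags = nrow(pre$tags),
    mapped_reads = mapped_totals,
    mapped_fraction = vapply(pre$summaries, `[[`, numeric(1), "mapped_fraction")
  )
  message("[mirgallus] preprocess: ", nrow(pre$tags), " unique tags")

  # --- annotate ------------------------------------------------------------
  if (!isTRUE(cfg$stages$annotate)) {
    report$stages$annotate <- list(status = "skipped")
    return(finish_report(report, cfg))
  }
  st <- t_stage({
    ann <- annotate_cascade(pre$tags, catalog, pre$loci)
    expr_tab <- build_expression_table(ann, pre$tags)
    star_tab <- build_expression_table(ann, pre$tags,
                                       category = "chicken_miRNA_star")
    arms <- arm_comparison(expr_tab, star_tab)
    list(ann = ann, expr_tab = expr_tab, star_tab = star_tab, arms = arms)
  })
  annv <- st$value
  write.table(annv$expr_tab, file.path(cfg$output_dir, "expression_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(annv$arms, file.path(cfg$output_dir, "arm_comparison.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  report$stages$annotate <- list(
    status = "ok", seconds = st$seconds,
    category_reads = apply(annv$ann$category_totals, 1, sum),
    n_mirnas_detected = nrow(annv$expr_tab),
    n_stars_detected = nrow(annv$star_tab),
    n_star_dominant = sum(annv$arms$star_dominant)
  )
  message("[mirgallus] annotate: ", nrow(annv$expr_tab), " miRNAs detected")

  # --- diffexp -------------------------------------------------------------
  de_called <- NULL
  de_genes <- NULL
  if (isTRUE(cfg$stages$diffexp)) {
    st <- t_stage({
      n_ab <- if (cfg$library_size_basis == "mapped") mapped_totals else
        vapply(bundle$libs$libraries, nrow, integer(1))
      message("[mirgallus] PAPER-GAP: library sizes taken as ",
              cfg$library_size_basis, " read totals")
      de_tab <- call_de_mirnas(annv$expr_tab, n_ab[["layer"]], n_ab[["broiler"]],
                               alpha = th$alpha)
      de_g <- de_genes_microarray(bundle$expression$matrix,
                                  bundle$expression$manifest,
                                  fold = th$fold, p_threshold = th$p)
      list(de_tab = de_tab, de_genes = de_g)
    })
    de_called <- st$value$de_tab
    de_genes <- st$value$de_genes
    write.table(de_called, file.path(cfg$output_dir, "de_mirnas.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$diffexp <- list(
      status = "ok", seconds = st$seconds,
      n_tested = nrow(de_called),
      n_significant = sum(de_called$significant),
      n_de_genes_union = length(de_genes$union_nonredundant)
    )
    message("[mirgallus] diffexp: ", sum(de_called$significant),
            " significant miRNAs")
  } else {
    report$stages$diffexp <- list(status = "skipped")
  }

  # --- conservation --------------------------------------------------------
  if (isTRUE(cfg$stages$conservation) && length(bundle$species_genomes) > 0) {
    st <- t_stage({
      matures <- setNames(catalog$mirnas$sequence, catalog$mirnas$id)
      mat <- conservation_matrix(matures, bundle$species_genomes,
                                 flank = th$flank,
                                 min_coverage = th$coverage)
      lineage <- vapply(rownames(mat), function(id) {
        classify_lineage(mat[id, SIM_VERTEBRATES],
                         mat[id, "zebra_finch"] == 1L)
      }, character(1))
      list(matrix = mat, lineage = lineage)
    })
    cons <- st$value
    write.table(cons$matrix, file.path(cfg$output_dir, "conservation_matrix.tsv"),
                sep = "\t", quote = FALSE)
    report$stages$conservation <- list(
      status = "ok", seconds = st$seconds,
      lineage_counts = as.list(table(cons$lineage))
    )
    message("[mirgallus] conservation: ",
            paste(names(table(cons$lineage)), table(cons$lineage),
                  collapse = ", ", sep = "="))
  } else {
    report$stages$conservation <- list(status = "skipped")
  }

  # --- novel candidates ----------------------------------------------------
  if (isTRUE(cfg$stages$novel)) {
    st <- t_stage({
      repeat_track <- catalog$tracks[catalog$tracks$category == "repeat"]
      filt <- filter_mappings(list(tags = pre$tags, loci = pre$loci),
                              repeat_track, max_loci = th$max_loci)
      win <- excise_precursors(filt, genome, flank = th$flank)
      stacks <- build_read_stacks(win, filt, genome)
      calls <- call_candidates(stacks, pairing_threshold = th$pairing)
      n_real <- count_candidate_loci(calls)

      perm_tags <- permute_reads(pre$tags, stage_seed(cfg$seed, "permute"))
      perm_mapped <- map_exact(perm_tags, genome)
      perm_filt <- filter_mappings(perm_mapped, repeat_track,
                                   max_loci = th$max_loci)
      perm_win <- excise_precursors(perm_filt, genome, flank = th$flank)
      perm_stacks <- build_read_stacks(perm_win, perm_filt, genome)
      perm_calls <- call_candidates(perm_stacks,
                                    pairing_threshold = th$pairing)
      n_perm <- count_candidate_loci(perm_calls)
      list(calls = calls, n_real = n_real,
           n_perm_windows = nrow(perm_calls), perm_calls = perm_calls,
           snr = signal_to_noise(n_real, n_perm))
    })
    nov <- st$value
    write.table(nov$calls, file.path(cfg$output_dir, "novel_candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$novel <- list(
      status = "ok", seconds = st$seconds,
      n_windows = nrow(nov$calls),
      n_candidates = nov$snr$n_real,
      n_permuted_candidates = nov$snr$n_permuted,
      n_permuted_windows = nov$n_perm_windows,
      signal_to_noise = nov$snr$ratio,
      snr_degenerate = nov$snr$degenerate_denominator
    )
    message("[mirgallus] novel: ", nov$snr$n_real, " candidates (",
            nov$snr$n_permuted, " on permuted reads)")
  } else {
    report$stages$novel <- list(status = "skipped")
  }

  # --- network -------------------------------------------------------------
  if (isTRUE(cfg$stages$network)) {
    if (is.null(de_called)) data_error("network stage requires diffexp")
    st <- t_stage({
      de_sig <- de_called[de_called$significant & !is.na(de_called$direction), ]
      mirnas <- setNames(
        catalog$mirnas$sequence[match(de_sig$mirna_id, catalog$mirnas$id)],
        de_sig$mirna_id)
      mirnas <- mirnas[!is.na(mirnas)]
      preds <- predict_targets(mirnas, bundle$utrs)
      dirs <- setNames(de_sig$direction, de_sig$mirna_id)
      mt <- filter_targets_by_expression(preds, de_genes, dirs)
      tt <- filter_ppi(bundle$ppi[, c("gene_a", "gene_b")],
                       bundle$expression$matrix, r_cut = th$r_cut)
      net <- assemble_network(mt, tt)
      write_network(net, file.path(cfg$output_dir, "network"))
      net
    })
    net <- st$value
    report$stages$network <- c(list(status = "ok", seconds = st$seconds),
                               network_summary(net))
    message("[mirgallus] network: ", nrow(net$mt_edges), " miRNA-target + ",
            nrow(net$tt_edges), " target-target edges")
  } else {
    report$stages$network <- list(status = "skipped")
  }

  finish_report(report, cfg)
}

finish_report <- function(report, cfg) {
  report$finished <- TRUE
  class(report) <- c("run_report", "list")
  path <- file.path(cfg$output_dir, "report.json")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(report)
}

#' Read a bundle directory written by [write_bundle()]
#'
#' Reconstructs the in-memory bundle (genome, tracks, catalog, read
#' libraries, expression matrix, PPI edges, UTRs, species genomes) from the
#' plain-text artifacts.
#'
#' @param dir bundle directory.
#' @return a `sim_bundle`-shaped list (ground truth not included).
#' @export
read_bundle <- function(dir) {
  if (!dir.exists(dir)) data_error(paste("bundle directory not found:", dir))
  need <- c("genome.fa", "tracks.bed", "catalog.fa", "catalog_manifest.tsv",
            "expression_matrix.tsv", "sample_manifest.tsv", "ppi_edges.tsv",
            "utrs.fa")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0) {
    data_error(paste("bundle is missing:", paste(missing, collapse = ", ")))
  }
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub("\\s.*", "", names(genome))
  tracks <- read_bed(file.path(dir, "tracks.bed"))
  tracks$category <- ifelse(grepl("^hp-", tracks$feature_id), "miRNA_hairpin",
                            sub("-sim-.*$", "", tracks$feature_id))
  cat_fa <- Biostrings::readDNAStringSet(file.path(dir, "catalog.fa"))
  names(cat_fa) <- sub("\\s.*", "", names(cat_fa))
  manifest <- read.table(file.path(dir, "catalog_manifest.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE,
                         comment.char = "")
  mature <- manifest[manifest$arm == "mature", ]
  star <- manifest[manifest$arm == "star", ]
  hp_ids <- unique(manifest$hairpin_id)
  hp_seq <- as.character(cat_fa[hp_ids])
  hairpins <- data.frame(
    hairpin_id = hp_ids,
    mirna_id = mature$id[match(hp_ids, mature$hairpin_id)],
    sequence = hp_seq,
    mature_start = 1L, mature_end = MATURE_LEN,
    star_start = MATURE_LEN + LOOP_LEN + 1L, star_end = HAIRPIN_LEN,
    chrom = manifest$chrom[match(hp_ids, manifest$hairpin_id)],
    start0 = manifest$start0[match(hp_ids, manifest$hairpin_id)],
    strand = manifest$strand[match(hp_ids, manifest$hairpin_id)],
    stringsAsFactors = FALSE
  )
  catalog <- list(
    mirnas = data.frame(id = mature$id,
                        sequence = as.character(cat_fa[mature$id]),
                        hairpin_id = mature$hairpin_id,
                        stringsAsFactors = FALSE),
    stars = data.frame(id = star$id, sequence = as.character(cat_fa[star$id]),
                       hairpin_id = star$hairpin_id,
                       mirna_id = sub("\\*$", "", star$id),
                       stringsAsFactors = FALSE),
    metazoan_mirnas = data.frame(id = character(0), sequence = character(0)),
    metazoan_stars = data.frame(id = character(0), sequence = character(0)),
    hairpins = hairpins,
    tracks = tracks[tracks$category != "miRNA_hairpin"]
  )
  class(catalog) <- "ref_catalog"

  fq <- list.files(dir, pattern = "\\.fastq$", full.names = TRUE)
  libraries <- lapply(setNames(fq, sub("\\.fastq$", "", basename(fq))),
                      function(p) data.frame(sequence = read_reads(p),
                                             stringsAsFactors = FALSE))

  em <- read.table(file.path(dir, "expression_matrix.tsv"), header = TRUE,
                   sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(em[, -1, drop = FALSE])
  rownames(mat) <- em$gene_id
  sm <- read.table(file.path(dir, "sample_manifest.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
  ppi <- read.table(file.path(dir, "ppi_edges.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  utr_fa <- Biostrings::readDNAStringSet(file.path(dir, "utrs.fa"))
  utrs <- setNames(as_dna(as.character(utr_fa)), sub("\\s.*", "", names(utr_fa)))
  sp_files <- list.files(dir, pattern = "^species_.*\\.fa$", full.names = TRUE)
  species <- lapply(setNames(sp_files,
                             sub("^species_(.*)\\.fa$", "\\1", basename(sp_files))),
                    Biostrings::readDNAStringSet)

  list(config = NULL,
       genome = list(genome = genome, tracks = tracks, catalog = catalog),
       truth = NULL,
       libs = list(libraries = libraries),
       expression = list(matrix = mat, manifest = sm),
       ppi = ppi, utrs = utrs, species_genomes = species)
}
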