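# Read-library generator. Per-library read counts are drawn multinomially
# from the configured library-size total, with per-locus expected rates (per
# mapped read) equal between breeds except for the planted DE folds; the
# contaminant mass absorbs the remainder so totals are exact. isomiR offsets
# are applied on hairpin coordinates and resampled when they would leave the
# hairpin or the 16-30 nt insert range.

ISOMIR_5P_OFFSETS <- -2:2
ISOMIR_3P_OFFSETS <- -3:3

# reads from one hairpin arm with configured 5'/3' end heterogeneity
sample_arm_reads <- function(n, hairpin_seq, arm_start, arm_end, config) {
  if (n == 0L) {
    return(data.frame(sequence = character(0), off5 = integer(0),
                      off3 = integer(0), stringsAsFactors = FALSE))
  }
  hp_len <- nchar(hairpin_seq)
  off5 <- sample(ISOMIR_5P_OFFSETS, n, replace = TRUE, prob = config$isomir_5p_probs)
  off3 <- sample(ISOMIR_3P_OFFSETS, n, replace = TRUE, prob = config$isomir_3p_probs)
  repeat {
    start <- arm_start + off5
    end <- arm_end + off3
    len <- end - start + 1L
    bad <- start < 1L | end > hp_len | len < 16L | len > 30L
    if (!any(bad)) break
    off5[bad] <- sample(ISOMIR_5P_OFFSETS, sum(bad), replace = TRUE,
                        prob = config$isomir_5p_probs)
    off3[bad] <- sample(ISOMIR_3P_OFFSETS, sum(bad), replace = TRUE,
                        prob = config$isomir_3p_probs)
  }
  data.frame(sequence = substring(hairpin_seq, arm_start + off5, arm_end + off3),
             off5 = off5, off3 = off3, stringsAsFactors = FALSE)
}

#' Generate the two breed read libraries
#'
#' Emits exactly `library_sizes` reads per library. Null miRNAs have equal
#' expected rates per sequenced read in both libraries; planted DE miRNAs
#' have their broiler rate multiplied (broiler-up) or divided (layer-up) by
#' the planted fold. Star-arm reads are drawn at `star_fraction`, except at
#' star-dominant loci where the mature arm is silent. Contaminant reads are
#' exact substrings of planted ncRNA/mRNA/repeat features.
#'
#' @param config a [sim_config()].
#' @param catalog `ref_catalog` from [gen_genome()] (the full `sim_genome`
#'   `features` table must be passed via `features`).
#' @param truth a `ground_truth`.
#' @param features the `features` data frame of the `sim_genome`.
#' @return an object of class `sim_libraries`: `libraries` is a named list of
#'   per-read data frames (sequence, source_category, source_id, off5, off3),
#'   `countable` holds the per-miRNA / per-star counts of planted reads that
#'   satisfy the 5'-19-nt prefix counting rule (5' offset 0, length 20-25).
#' @export
gen_read_libraries <- function(config, catalog, truth, features) {
  with_seed(stage_seed(config$seed, "reads"), {
    libs <- names(config$library_sizes)
    n_ref <- config$library_sizes[[1]]
    hp <- catalog$hairpins
    fold <- setNames(rep(1, length(truth$mirna_ids)), truth$mirna_ids)
    if (nrow(truth$de) > 0) {
      f <- ifelse(truth$de$direction == "broiler_up", truth$de$fold,
                  1 / truth$de$fold)
      fold[truth$de$mirna_id] <- f
    }
    contam_feats <- features[features$category %in% CONTAMINANT_CLASSES, , drop = FALSE]

    out <- lapply(setNames(nm = libs), function(lib) {
      n_lib <- config$library_sizes[[lib]]
      scale <- n_lib / n_ref
      e_locus <- truth$abundance * (1 - config$contaminant_fraction) * n_ref * scale
      if (lib == "broiler") e_locus <- e_locus * fold
      e_contam_total <- n_lib - sum(e_locus)
      if (e_contam_total <= 0) {
        stop("planted DE folds leave no room for contaminant reads; ",
             "rebalance de_fold_range or contaminant_fraction")
      }
      e_contam <- truth$contaminant_weights * e_contam_total
      probs <- c(e_locus, e_contam)
      counts <- as.vector(rmultinom(1, n_lib, probs))
      names(counts) <- names(probs)

      reads <- vector("list", length(counts))
      for (i in seq_along(truth$mirna_ids)) {
        id <- truth$mirna_ids[i]
        c_i <- counts[[id]]
        if (c_i == 0L) next
        rec <- hp[hp$mirna_id == id, ]
        n_star <- if (id %in% truth$star_dominant_ids) c_i else
          stats::rbinom(1, c_i, config$star_fraction)
        n_mat <- c_i - n_star
        mat <- sample_arm_reads(n_mat, rec$sequence, rec$mature_start,
                                rec$mature_end, config)
        if (n_mat > 0) {
          mat$source_category <- "miRNA"
          mat$source_id <- id
        }
        st <- sample_arm_reads(n_star, rec$sequence, rec$star_start,
                               rec$star_end, config)
        if (n_star > 0) {
          st$source_category <- "miRNA_star"
          st$source_id <- paste0(id, "*")
        }
        reads[[i]] <- rbind(mat, st)
      }
      for (j in seq_along(CONTAMINANT_CLASSES)) {
        cl <- names(truth$contaminant_weights)[j]
        c_j <- counts[[cl]]
        if (c_j == 0L) next
        pool <- contam_feats[contam_feats$category == cl, , drop = FALSE]
        pick <- sample(nrow(pool), c_j, replace = TRUE)
        len <- sample(16:30, c_j, replace = TRUE)
        maxstart <- pool$width[pick] - len + 1L
        start <- 1L + floor(runif(c_j) * maxstart)
        reads[[length(truth$mirna_ids) + j]] <- data.frame(
          sequence = substring(pool$sequence[pick], start, start + len - 1L),
          off5 = NA_integer_, off3 = NA_integer_,
          source_category = cl, source_id = pool$feature_id[pick],
          stringsAsFactors = FALSE
        )
      }
      reads <- do.call(rbind, reads[!vapply(reads, is.null, logical(1))])
      reads <- reads[sample(nrow(reads)), , drop = FALSE]
      rownames(reads) <- NULL
      stopifnot(nrow(reads) == n_lib)
      reads[, c("sequence", "source_category", "source_id", "off5", "off3")]
    })

    # planted reads that the 20-25 nt / 5'-19-nt prefix rule will count
    countable <- lapply(out, function(df) {
      counted <- !is.na(df$off5) & df$off5 == 0L &
        nchar(df$sequence) >= 20L & nchar(df$sequence) <= 25L
      table(factor(df$source_id[counted],
                   levels = c(truth$mirna_ids, paste0(truth$mirna_ids, "*"))))
    })

    res <- list(libraries = out,
                countable = do.call(cbind, countable))
    class(res) <- "sim_libraries"
    res
  })
}

#' Write raw FASTQ files (with 3' adapter) for a simulated bundle
#'
#' Reads are emitted as fixed 36-cycle raw sequences: insert plus adapter,
#' truncated, with a constant quality string -- the form the preprocessing
#' module expects as input.
#'
#' @param sim_libs a `sim_libraries` object.
#' @param config the [sim_config()] used to generate it.
#' @param dir output directory.
#' @param read_length machine read length.
#' @return invisibly, the written file paths.
#' @export
write_raw_fastq <- function(sim_libs, config, dir, read_length = 36L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(sim_libs$libraries), function(lib) {
    df <- sim_libs$libraries[[lib]]
    raw <- substr(paste0(df$sequence, config$adapter), 1L, read_length)
    path <- file.path(dir, paste0(lib, ".fastq"))
    qual <- vapply(nchar(raw), function(w) strrep("I", w), character(1))
    writeLines(paste0("@", lib, "_", seq_along(raw), "\n", raw, "\n+\n", qual),
               path)
    path
  }, character(1))
  invisible(paths)
}
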