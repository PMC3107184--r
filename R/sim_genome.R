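# Synthetic genome, feature tracks and reference catalog. Hairpin loci are
# planted as perfect inverted repeats (mature arm + unpairable-biased loop +
# reverse-complement star arm) so that every planted precursor folds into a
# stem-loop under the package's base-pair-maximization fold. Contaminant
# feature classes mirror the annotation cascade: snoRNA, snRNA, rRNA, tRNA,
# mRNA exons and repeats.

MATURE_LEN <- 22L
LOOP_LEN <- 9L
HAIRPIN_LEN <- 2L * MATURE_LEN + LOOP_LEN

CONTAMINANT_CLASSES <- c("snoRNA", "snRNA", "rRNA", "tRNA", "mRNA", "repeat")

# Non-overlapping 0-based feature starts for the given widths, uniformly
# random gaps. Errors out when the features cannot be packed.
place_features <- function(genome_length, widths) {
  k <- length(widths)
  free <- genome_length - sum(widths)
  if (free < 0) {
    stop("infeasible packing: planted features (", sum(widths),
         " nt) exceed genome length (", genome_length, " nt)")
  }
  if (k == 0L) return(integer(0))
  gaps <- as.vector(rmultinom(1, free, rep(1, k + 1L)))
  cumsum(gaps[seq_len(k)]) + c(0L, cumsum(widths))[seq_len(k)]
}

# One planted hairpin: mature on the 5' arm; star arm = reverse complement
# of the mature with `n_mismatches` substituted positions (real passenger
# strands are imperfect complements -- this also prevents star reads from
# exactly matching the mature locus on the opposite strand). The loop is
# drawn from {A, C} so it cannot pair with itself and rarely competes with
# the stem. 3 mismatches leave 19/22 mature positions pairable (> 70%).
make_hairpin <- function(mature, n_mismatches = 3L) {
  loop <- paste(sample(c("A", "C"), LOOP_LEN, replace = TRUE, prob = c(0.7, 0.3)),
                collapse = "")
  star <- strsplit(revcomp(mature), "")[[1]]
  pos <- sample(length(star), n_mismatches)
  for (p in pos) star[p] <- sample(setdiff(DNA_BASES, star[p]), 1)
  star <- paste(star, collapse = "")
  list(hairpin = paste0(mature, loop, star), star = star)
}

#' Generate a synthetic genome with feature tracks and reference catalog
#'
#' Plants `n_mirnas` hairpin loci plus snoRNA/snRNA/rRNA/tRNA/mRNA/repeat
#' features at non-overlapping positions on a single random chromosome and
#' assembles the reference catalog (mature, star and hairpin records plus the
#' annotation interval tracks) used by the rest of the pipeline.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_genome`: a list with elements `genome`
#'   (a [Biostrings::DNAStringSet] of one chromosome), `tracks` (a
#'   [GenomicRanges::GRanges] with `category` and `feature_id` columns),
#'   `features` (feature sequences) and `catalog` (a `ref_catalog`).
#' @export
gen_genome <- function(config) {
  validate_sim_config(config)
  with_seed(stage_seed(config$seed, "genome"), {
    n <- config$n_mirnas

    # distinct matures with distinct 19-nt 5' prefixes (also vs star arms),
    # so prefix-rule annotation is unambiguous for planted loci
    matures <- character(0)
    stars <- character(0)
    hairpins <- character(0)
    seen <- character(0)
    while (length(matures) < n) {
      m <- random_dna(MATURE_LEN)
      # a mature arm with strong internal self-structure or long homopolymer
      # runs would misfold the precursor in genomic context (runs also blur
      # the arm boundary against the loop); real arms show neither
      if (grepl("(.)\\1{4}", m)) next
      if (fold_hairpin(m)$n_pairs >= 4L) next
      hp <- make_hairpin(m)
      p <- c(substr(m, 1, 19), substr(hp$star, 1, 19))
      if (any(p %in% seen)) next
      # postcondition by construction: the planted precursor must pass the
      # conservation module's fold + pairing check
      f <- fold_hairpin(hp$hairpin)
      if (!hairpin_check(f, c(1L, MATURE_LEN),
                         c(MATURE_LEN + LOOP_LEN + 1L, HAIRPIN_LEN))) next
      matures <- c(matures, m)
      stars <- c(stars, hp$star)
      hairpins <- c(hairpins, hp$hairpin)
      seen <- c(seen, p)
    }
    mirna_ids <- if (n > 0) sprintf("mir-sim-%02d", seq_len(n)) else character(0)

    # contaminant feature counts scale with the genome
    n_feat <- c(
      snoRNA = max(2L, config$genome_length %/% 25000L),
      snRNA  = max(2L, config$genome_length %/% 25000L),
      rRNA   = max(2L, config$genome_length %/% 33000L),
      tRNA   = max(3L, config$genome_length %/% 16000L),
      mRNA   = max(3L, config$genome_length %/% 12000L),
      "repeat" = max(2L, config$genome_length %/% 16000L)
    )
    feat_width <- c(snoRNA = 80L, snRNA = 120L, rRNA = 160L, tRNA = 75L,
                    mRNA = 400L, "repeat" = 300L)

    categories <- c(rep("miRNA_hairpin", n),
                    rep(names(n_feat), n_feat))
    widths <- c(rep(HAIRPIN_LEN, n), rep(feat_width, n_feat))
    seqs <- c(hairpins, random_dna(widths[categories != "miRNA_hairpin"]))
    ids <- c(sprintf("hp-sim-%02d", seq_len(n)),
             unlist(lapply(names(n_feat), function(cl) {
               sprintf("%s-sim-%02d", cl, seq_len(n_feat[[cl]]))
             }), use.names = FALSE))

    if (config$genome_length < 10L * sum(widths)) {
      stop("infeasible packing: genome_length must be at least 10x the total ",
           "planted feature length (", sum(widths), " nt)")
    }

    ord <- sample(length(widths))
    starts0 <- integer(length(widths))
    starts0[ord] <- place_features(config$genome_length, widths[ord])
    strands <- sample(c("+", "-"), length(widths), replace = TRUE)

    # assemble the chromosome: random background with planted slices
    genome_chars <- strsplit(random_dna(config$genome_length), "")[[1]]
    for (i in seq_along(widths)) {
      planted <- if (strands[i] == "+") seqs[i] else revcomp(seqs[i])
      genome_chars[(starts0[i] + 1L):(starts0[i] + widths[i])] <-
        strsplit(planted, "")[[1]]
    }
    genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
    names(genome) <- "chr1"

    tracks <- GenomicRanges::GRanges(
      seqnames = "chr1",
      ranges = IRanges::IRanges(start = starts0 + 1L, width = widths),
      strand = strands,
      category = categories,
      feature_id = ids
    )

    features <- data.frame(
      feature_id = ids, category = categories, sequence = seqs,
      chrom = "chr1", start0 = starts0, width = widths, strand = strands,
      stringsAsFactors = FALSE
    )

    hp_idx <- which(categories == "miRNA_hairpin")
    hairpin_df <- data.frame(
      hairpin_id = ids[hp_idx],
      mirna_id = mirna_ids,
      sequence = hairpins,
      mature_start = rep(1L, n), mature_end = rep(MATURE_LEN, n),
      star_start = rep(MATURE_LEN + LOOP_LEN + 1L, n),
      star_end = rep(HAIRPIN_LEN, n),
      chrom = rep("chr1", n), start0 = starts0[hp_idx],
      strand = strands[hp_idx],
      stringsAsFactors = FALSE
    )

    catalog <- list(
      mirnas = data.frame(id = mirna_ids, sequence = matures,
                          hairpin_id = ids[hp_idx], stringsAsFactors = FALSE),
      stars = data.frame(id = if (n > 0) paste0(mirna_ids, "*") else character(0),
                         sequence = stars,
                         hairpin_id = ids[hp_idx], mirna_id = mirna_ids,
                         stringsAsFactors = FALSE),
      metazoan_mirnas = data.frame(id = character(0), sequence = character(0),
                                   stringsAsFactors = FALSE),
      metazoan_stars = data.frame(id = character(0), sequence = character(0),
                                  stringsAsFactors = FALSE),
      hairpins = hairpin_df,
      tracks = tracks[tracks$category != "miRNA_hairpin"]
    )
    class(catalog) <- "ref_catalog"

    out <- list(genome = genome, tracks = tracks, features = features,
                catalog = catalog)
    class(out) <- "sim_genome"
    out
  })
}

SIM_VERTEBRATES <- c("human", "mouse", "rat", "opossum", "frog", "zebrafish")
SIM_SPECIES <- c(SIM_VERTEBRATES, "zebra_finch")

#' Generate per-species genomes with planted miRNA homologs
#'
#' For each species in the ground truth's homolog map, the full hairpin
#' precursor of every conserved miRNA is planted verbatim into an otherwise
#' random genome, so the conservation scan + fold + pairing rules can be
#' validated against a known answer.
#'
#' @param config a [sim_config()].
#' @param catalog the `ref_catalog` from [gen_genome()].
#' @param truth a `ground_truth` from [plan_ground_truth()].
#' @param species_length genome length per species.
#' @return named list of single-chromosome [Biostrings::DNAStringSet] objects.
#' @export
gen_species_genomes <- function(config, catalog, truth, species_length = 20000L) {
  with_seed(stage_seed(config$seed, "species"), {
    lapply(setNames(nm = SIM_SPECIES), function(sp) {
      planted_ids <- names(truth$planted_homolog_map)[
        vapply(truth$planted_homolog_map, function(x) sp %in% x, logical(1))]
      hp <- catalog$hairpins[match(planted_ids, catalog$hairpins$mirna_id), , drop = FALSE]
      widths <- rep(HAIRPIN_LEN, nrow(hp))
      starts0 <- place_features(species_length, widths)
      g <- strsplit(random_dna(species_length), "")[[1]]
      strands <- sample(c("+", "-"), nrow(hp), replace = TRUE)
      for (i in seq_len(nrow(hp))) {
        planted <- if (strands[i] == "+") hp$sequence[i] else revcomp(hp$sequence[i])
        g[(starts0[i] + 1L):(starts0[i] + HAIRPIN_LEN)] <- strsplit(planted, "")[[1]]
      }
      gs <- Biostrings::DNAStringSet(paste(g, collapse = ""))
      names(gs) <- "chr1"
      gs
    })
  })
}
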