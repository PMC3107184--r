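# Simulation configuration: the study conditions every synthetic bundle is
# generated under. Defaults emulate the real two-breed experiment at 1/100
# sequencing depth: two libraries (layer, broiler) of 16-30 nt inserts, a
# dominant 22 nt size class, planted differential expression, isomiR end
# heterogeneity, miRNA* arms including star-dominant loci, and contaminant
# rRNA/tRNA/snoRNA/snRNA/mRNA/repeat reads.

#' Simulation configuration
#'
#' Builds the configuration object consumed by every generator in the
#' synthetic-data module. All randomness downstream derives from `seed`.
#'
#' @param seed integer master RNG seed.
#' @param genome_length genome size in nt; must be at least ten times the
#'   total planted feature length.
#' @param n_mirnas number of miRNA hairpin loci to plant.
#' @param n_de_mirnas number of differentially expressed miRNAs (balanced
#'   between broiler-up and layer-up so library composition stays comparable).
#' @param de_fold_range range (both > 1) the true expression folds are drawn
#'   from, uniformly.
#' @param library_sizes named integer pair: reads per library, layer then
#'   broiler. Defaults are the real library sizes scaled down 100-fold.
#' @param star_fraction fraction of a locus's reads drawn from the star arm
#'   (except star-dominant loci, which emit star reads only).
#' @param star_dominant_ids miRNA ids whose mature arm is silent; `NULL`
#'   (default) lets the planner pick one non-DE locus, mirroring the
#'   miR-140-like pattern where only the star strand is sequenced.
#' @param isomir_5p_probs probability vector over 5' start offsets -2..+2.
#' @param isomir_3p_probs probability vector over 3' end offsets -3..+3.
#' @param contaminant_fraction fraction of each library drawn from non-miRNA
#'   features (rRNA, tRNA, snoRNA, snRNA, mRNA, repeats).
#' @param n_genes genes on the synthetic expression array.
#' @param n_timepoints developmental stages (default 9: E10..W8).
#' @param n_replicates biological replicates per breed per stage (default 3,
#'   for 9 x 2 x 3 = 54 arrays at defaults).
#' @param noise_sd log2-scale array noise standard deviation.
#' @param n_ppi_edges protein-protein interaction edges to emit (half planted
#'   co-expressed pairs, half random pairs).
#' @param n_true_targets planted (miRNA, target gene) pairs with seed sites
#'   and opposite breed expression.
#' @param adapter 3' sequencing adapter appended to raw reads.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 100000L,
                       n_mirnas = 30L,
                       n_de_mirnas = 10L,
                       de_fold_range = c(4, 8),
                       library_sizes = c(layer = 27000L, broiler = 25766L),
                       star_fraction = 0.1,
                       star_dominant_ids = NULL,
                       isomir_5p_probs = c(0.01, 0.03, 0.92, 0.03, 0.01),
                       isomir_3p_probs = c(0.01, 0.04, 0.15, 0.55, 0.15, 0.07, 0.03),
                       contaminant_fraction = 0.35,
                       n_genes = 200L,
                       n_timepoints = 9L,
                       n_replicates = 3L,
                       noise_sd = 0.2,
                       n_ppi_edges = 60L,
                       n_true_targets = 30L,
                       adapter = "TCGTATGCCGTCTTCTGCTTG") {
  cfg <- list(
    seed = as.integer(seed),
    genome_length = as.integer(genome_length),
    n_mirnas = as.integer(n_mirnas),
    n_de_mirnas = as.integer(n_de_mirnas),
    de_fold_range = as.numeric(de_fold_range),
    library_sizes = setNames(as.integer(library_sizes),
                             names(library_sizes) %||% c("layer", "broiler")),
    star_fraction = star_fraction,
    star_dominant_ids = star_dominant_ids,
    isomir_5p_probs = setNames(isomir_5p_probs, as.character(-2:2)),
    isomir_3p_probs = setNames(isomir_3p_probs, as.character(-3:3)),
    contaminant_fraction = contaminant_fraction,
    n_genes = as.integer(n_genes),
    n_timepoints = as.integer(n_timepoints),
    n_replicates = as.integer(n_replicates),
    noise_sd = noise_sd,
    n_ppi_edges = as.integer(n_ppi_edges),
    n_true_targets = as.integer(n_true_targets),
    adapter = as_dna(adapter)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  probs_ok <- function(p) abs(sum(p) - 1) <= 1e-9 && all(p >= 0)
  if (!probs_ok(cfg$isomir_5p_probs) || length(cfg$isomir_5p_probs) != 5L) {
    stop("isomir_5p_probs must be 5 probabilities over offsets -2..+2 summing to 1")
  }
  if (!probs_ok(cfg$isomir_3p_probs) || length(cfg$isomir_3p_probs) != 7L) {
    stop("isomir_3p_probs must be 7 probabilities over offsets -3..+3 summing to 1")
  }
  if (length(cfg$de_fold_range) != 2L || any(cfg$de_fold_range <= 1)) {
    stop("de_fold_range values must both exceed 1")
  }
  if (length(cfg$library_sizes) != 2L || any(cfg$library_sizes <= 0L)) {
    stop("library_sizes must be two positive integers")
  }
  if (cfg$star_fraction < 0 || cfg$star_fraction > 1) stop("star_fraction must lie in [0, 1]")
  if (cfg$contaminant_fraction < 0 || cfg$contaminant_fraction > 1) {
    stop("contaminant_fraction must lie in [0, 1]")
  }
  if (cfg$n_de_mirnas > cfg$n_mirnas) stop("n_de_mirnas cannot exceed n_mirnas")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed,
      "| genome", x$genome_length, "nt |", x$n_mirnas, "miRNA loci (",
      x$n_de_mirnas, "DE ) | libraries",
      paste(sprintf("%s=%d", names(x$library_sizes), x$library_sizes), collapse = ", "),
      "\n")
  invisible(x)
}
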