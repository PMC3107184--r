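# Synthetic developmental expression matrix (nine stages x two breeds x
# three replicates at defaults), PPI edge list and 3'UTR sequences with
# planted seed sites. Arrays are emitted pre-normalized on the linear
# intensity scale; noise is lognormal with a configurable log2-scale sd.

SIM_TIMEPOINTS <- c("E10", "E12", "E14", "E18", "D1", "W2", "W4", "W6", "W8")
EMBRYONIC_TIMEPOINTS <- c("E10", "E12", "E14", "E18")

#' Generate the gene x sample expression matrix
#'
#' Each gene follows a smooth latent developmental profile shared between
#' breeds; planted breed-differential genes (true miRNA targets and decoys)
#' receive a twofold breed offset at the embryonic stages, with targets
#' oriented opposite to their miRNA's sequencing-based direction. Genes in a
#' planted co-expressed PPI pair share one latent profile.
#'
#' @param config a [sim_config()].
#' @param truth a `ground_truth`.
#' @return an object of class `sim_expression`: `matrix` (linear-scale
#'   intensities, genes x samples), `manifest` (sample_id, breed, timepoint,
#'   replicate) and `directions` (planted per-gene breed direction per
#'   embryonic time point).
#' @export
gen_expression_matrix <- function(config, truth) {
  with_seed(stage_seed(config$seed, "expression"), {
    tps <- SIM_TIMEPOINTS[seq_len(config$n_timepoints)]
    breeds <- c("layer", "broiler")
    reps <- seq_len(config$n_replicates)
    manifest <- expand.grid(replicate = reps, breed = breeds, timepoint = tps,
                            stringsAsFactors = FALSE)[, c(3, 2, 1)]
    manifest$sample_id <- sprintf("%s_%s_%d", manifest$timepoint,
                                  manifest$breed, manifest$replicate)

    genes <- truth$gene_ids
    n_g <- length(genes)
    n_tp <- length(tps)

    # latent log2 profile: level + random walk over stages
    latent <- matrix(0, n_g, n_tp, dimnames = list(genes, tps))
    base <- rnorm(n_g, 8, 1.5)
    steps <- matrix(rnorm(n_g * (n_tp - 1L), 0, 0.8), n_g)
    latent[, 1] <- base
    for (k in seq_len(n_tp - 1L)) latent[, k + 1L] <- latent[, k] + steps[, k]

    # co-expressed PPI pairs share the latent profile
    if (nrow(truth$coexpr_pairs) > 0) {
      for (i in seq_len(nrow(truth$coexpr_pairs))) {
        latent[truth$coexpr_pairs$gene_b[i], ] <-
          latent[truth$coexpr_pairs$gene_a[i], ]
      }
    }

    # planted breed effects on the log2 scale at embryonic stages:
    # +/- 0.5 per breed = 2-fold between breeds
    mir_dir <- setNames(truth$de$direction, truth$de$mirna_id)
    gene_dir <- character(0)
    if (nrow(truth$true_targets) > 0) {
      opp <- ifelse(mir_dir[truth$true_targets$mirna_id] == "broiler_up",
                    "layer_up", "broiler_up")
      gene_dir <- setNames(opp, truth$true_targets$gene_id)
    }
    if (nrow(truth$decoy_de_genes) > 0) {
      gene_dir <- c(gene_dir, setNames(truth$decoy_de_genes$direction,
                                       truth$decoy_de_genes$gene_id))
    }

    emb <- intersect(EMBRYONIC_TIMEPOINTS, tps)
    mat <- matrix(0, n_g, nrow(manifest),
                  dimnames = list(genes, manifest$sample_id))
    for (s in seq_len(nrow(manifest))) {
      tp <- manifest$timepoint[s]
      breed <- manifest$breed[s]
      eff <- numeric(n_g)
      if (tp %in% emb && length(gene_dir) > 0) {
        up_here <- names(gene_dir)[gene_dir == paste0(breed, "_up")]
        dn_here <- names(gene_dir)[gene_dir != paste0(breed, "_up")]
        eff[match(up_here, genes)] <- 0.5
        eff[match(dn_here, genes)] <- -0.5
      }
      noise <- if (config$noise_sd > 0) rnorm(n_g, 0, config$noise_sd) else 0
      mat[, s] <- 2^(latent[, tp] + eff + noise)
    }

    directions <- if (length(gene_dir) > 0) {
      expand.grid(gene_id = names(gene_dir), timepoint = emb,
                  stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = character(0), timepoint = character(0))
    }
    if (nrow(directions) > 0) directions$direction <- gene_dir[directions$gene_id]

    res <- list(matrix = mat, manifest = manifest, directions = directions)
    class(res) <- "sim_expression"
    res
  })
}

#' Generate the PPI edge list
#'
#' Mixes the truth's planted co-expressed pairs with random, expression-
#' independent pairs up to `n_ppi_edges`.
#'
#' @param config a [sim_config()].
#' @param truth a `ground_truth`.
#' @return data frame (gene_a, gene_b, planted).
#' @export
gen_ppi_edges <- function(config, truth) {
  with_seed(stage_seed(config$seed, "ppi"), {
    true_pairs <- truth$coexpr_pairs
    n_true <- nrow(true_pairs)
    n_rand <- max(0L, config$n_ppi_edges - n_true)
    seen <- character(n_true)
    if (n_true > 0) {
      seen <- paste(pmin(true_pairs$gene_a, true_pairs$gene_b),
                    pmax(true_pairs$gene_a, true_pairs$gene_b))
    }
    rand <- data.frame(gene_a = character(0), gene_b = character(0))
    while (nrow(rand) < n_rand) {
      a <- sample(truth$gene_ids, 1)
      b <- sample(setdiff(truth$gene_ids, a), 1)
      key <- paste(min(a, b), max(a, b))
      if (key %in% seen) next
      seen <- c(seen, key)
      rand <- rbind(rand, data.frame(gene_a = a, gene_b = b))
    }
    edges <- rbind(
      if (n_true > 0) cbind(true_pairs, planted = TRUE) else NULL,
      if (nrow(rand) > 0) cbind(rand, planted = FALSE) else NULL
    )
    if (is.null(edges)) {
      edges <- data.frame(gene_a = character(0), gene_b = character(0),
                          planted = logical(0))
    }
    rownames(edges) <- NULL
    edges
  })
}

# Fast raw seed-pattern counter: every catalog miRNA contributes two 7-nt
# patterns (reverse complement of positions 2-8; reverse complement of 2-7
# followed by A). A planted 8mer site matches both once, so a UTR carrying
# exactly its planted sites and nothing else has a raw count of 2 per site.
seed_pattern_dict <- function(matures) {
  if (length(matures) == 0) return(NULL)
  pats <- c(revcomp(substr(matures, 2, 8)),
            paste0(revcomp(substr(matures, 2, 7)), "A"))
  Biostrings::PDict(unique(pats))
}

count_seed_patterns <- function(utr, dict) {
  if (is.null(dict)) return(0L)
  sum(Biostrings::countPDict(dict, Biostrings::DNAString(utr)))
}

#' Generate 3'UTR sequences with planted seed sites
#'
#' Every (miRNA, gene) pair in the truth's target and site-only sets gets one
#' planted 8mer site (reverse complement of miRNA positions 2-8 followed by
#' A). All remaining UTR sequence is rejection-sampled so that no UTR carries
#' an unintended site for any catalog miRNA; genes outside the planted sets
#' therefore constitute a verified negative set.
#'
#' @param config a [sim_config()].
#' @param catalog `ref_catalog` from [gen_genome()].
#' @param truth a `ground_truth`.
#' @param utr_length UTR length in nt.
#' @return named character vector of UTR sequences (DNA alphabet), one per gene.
#' @export
gen_utrs <- function(config, catalog, truth, utr_length = 300L) {
  with_seed(stage_seed(config$seed, "utrs"), {
    matures <- catalog$mirnas$sequence
    planted <- rbind(
      truth$true_targets[, c("mirna_id", "gene_id")],
      truth$site_only_genes[, c("mirna_id", "gene_id")]
    )
    site_for <- split(planted$mirna_id, planted$gene_id)
    mature_by_id <- setNames(catalog$mirnas$sequence, catalog$mirnas$id)
    dict <- seed_pattern_dict(matures)

    utrs <- vapply(truth$gene_ids, function(g) {
      wanted <- site_for[[g]]
      n_sites <- length(wanted)
      for (attempt in seq_len(200L)) {
        utr <- random_dna(utr_length)
        if (n_sites > 0) {
          # plant one 8mer per assigned miRNA at spaced positions
          pos <- sort(sample(seq(5L, utr_length - 12L, by = 12L), n_sites))
          for (k in seq_len(n_sites)) {
            site <- paste0(revcomp(substr(mature_by_id[[wanted[k]]], 2, 8)), "A")
            substr(utr, pos[k], pos[k] + 7L) <- site
          }
        }
        # a clean UTR matches the raw 7-nt pattern set exactly twice per
        # planted 8mer (positions 2-8, and 2-7 + A) and nowhere else
        if (count_seed_patterns(utr, dict) == 2L * n_sites) return(utr)
      }
      stop("could not rejection-sample a UTR without unintended seed sites")
    }, character(1))
    utrs
  })
}
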