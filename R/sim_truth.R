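# Ground-truth planner: which miRNAs are differentially expressed and how
# strongly, which locus is star-dominant, which genes are true targets,
# which PPI pairs are genuinely co-expressed, and which species carry a
# planted homolog. Everything downstream generators emit is keyed to this.

#' Plan the ground truth for a synthetic bundle
#'
#' @param config a [sim_config()].
#' @param catalog the `ref_catalog` from [gen_genome()].
#' @return an object of class `ground_truth`.
#' @export
plan_ground_truth <- function(config, catalog) {
  with_seed(stage_seed(config$seed, "truth"), {
    ids <- catalog$mirnas$id
    n <- length(ids)

    # heavy-tailed relative abundances, as in real small RNA libraries
    w <- exp(rnorm(n, 0, 1.2))
    names(w) <- ids

    # star-dominant locus: configured, or the least abundant locus
    star_dom <- config$star_dominant_ids
    if (is.null(star_dom) && n > 0) star_dom <- ids[which.min(w)]
    star_dom <- intersect(star_dom, ids)

    # DE miRNAs drawn among reasonably expressed, non-star-dominant loci;
    # raising weights to at least the 60th percentile keeps every planted DE
    # locus detectable at the configured sequencing depth
    eligible <- setdiff(ids[order(w, decreasing = TRUE)], star_dom)
    n_de <- min(config$n_de_mirnas, length(eligible))
    de_ids <- sample(head(eligible, max(n_de, ceiling(length(eligible) * 0.7))), n_de)
    if (n_de > 0) {
      floor_w <- stats::quantile(w, 0.6)
      w[de_ids] <- pmax(w[de_ids], floor_w)
    }
    w <- w / sum(w)

    de <- data.frame(
      mirna_id = de_ids,
      direction = rep_len(c("broiler_up", "layer_up"), n_de),
      fold = runif(n_de, config$de_fold_range[1], config$de_fold_range[2]),
      stringsAsFactors = FALSE
    )

    # cap the DE weight mass so that broiler-side expected miRNA counts
    # (folds applied) never exhaust the contaminant budget
    if (n_de > 0) {
      f_all <- setNames(rep(1, n), ids)
      f_all[de$mirna_id] <- ifelse(de$direction == "broiler_up",
                                   de$fold, 1 / de$fold)
      for (iter in seq_len(200L)) {
        if ((1 - config$contaminant_fraction) * sum(w * f_all) <= 0.92) break
        w[de_ids] <- w[de_ids] * 0.9
        w <- w / sum(w)
      }
    }

    gene_ids <- sprintf("gene-%03d", seq_len(config$n_genes))

    # planted targets: opposite breed expression + a seed site in the UTR
    n_tt <- min(config$n_true_targets, config$n_genes %/% 3)
    target_genes <- sample(gene_ids, n_tt)
    true_targets <- if (n_de > 0 && n_tt > 0) {
      data.frame(
        mirna_id = rep_len(de_ids, n_tt),
        gene_id = target_genes,
        site_type = "8mer",
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(mirna_id = character(0), gene_id = character(0),
                 site_type = character(0), stringsAsFactors = FALSE)
    }

    remaining <- setdiff(gene_ids, target_genes)
    # decoys: breed-differential genes without any seed site, and genes
    # carrying a seed site but no differential expression
    n_decoy <- min(20L, length(remaining) %/% 4)
    decoy_de <- sample(remaining, n_decoy)
    remaining <- setdiff(remaining, decoy_de)
    n_siteonly <- min(10L, length(remaining) %/% 4)
    site_only <- sample(remaining, n_siteonly)
    decoy_de_genes <- data.frame(
      gene_id = decoy_de,
      direction = sample(c("broiler_up", "layer_up"), n_decoy, replace = TRUE),
      stringsAsFactors = FALSE
    )
    site_only_genes <- if (n_de > 0 && n_siteonly > 0) {
      data.frame(gene_id = site_only,
                 mirna_id = rep_len(de_ids, n_siteonly),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = character(0), mirna_id = character(0),
                 stringsAsFactors = FALSE)
    }

    # co-expressed PPI pairs among target genes (so they can survive into the
    # final network as target-target edges); pairing within a breed-direction
    # group keeps paired profiles identical, breed effects included
    coexpr_pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                               stringsAsFactors = FALSE)
    if (nrow(true_targets) > 0) {
      mir_dir <- setNames(de$direction, de$mirna_id)
      tgt_dir <- ifelse(mir_dir[true_targets$mirna_id] == "broiler_up",
                        "layer_up", "broiler_up")
      for (grp in split(true_targets$gene_id, tgt_dir)) {
        if (length(grp) < 2) next
        k <- length(grp) %/% 2
        coexpr_pairs <- rbind(coexpr_pairs, data.frame(
          gene_a = grp[seq_len(k)], gene_b = grp[k + seq_len(k)],
          stringsAsFactors = FALSE))
      }
      if (nrow(coexpr_pairs) > config$n_ppi_edges %/% 2) {
        coexpr_pairs <- coexpr_pairs[seq_len(config$n_ppi_edges %/% 2), ]
      }
    }

    # conservation classes: roughly half vertebrate-conserved, a third
    # avian-specific, the rest chicken-specific
    homolog_map <- setNames(vector("list", n), ids)
    if (n > 0) {
      cls <- sample(c("vertebrate", "avian", "chicken"), n, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2))
      for (i in seq_len(n)) {
        homolog_map[[i]] <- switch(
          cls[i],
          vertebrate = c(sample(SIM_VERTEBRATES, sample(1:4, 1)), "zebra_finch"),
          avian = "zebra_finch",
          chicken = character(0)
        )
      }
    }

    truth <- list(
      mirna_ids = ids,
      gene_ids = gene_ids,
      abundance = w,
      de = de,
      star_dominant_ids = star_dom,
      true_targets = true_targets,
      decoy_de_genes = decoy_de_genes,
      site_only_genes = site_only_genes,
      coexpr_pairs = coexpr_pairs,
      contaminant_weights = c(rRNA = 0.30, tRNA = 0.15, snoRNA = 0.07,
                              snRNA = 0.05, mRNA = 0.35, "repeat" = 0.08),
      planted_homolog_map = homolog_map
    )
    class(truth) <- "ground_truth"
    validate_ground_truth(truth, catalog)
    truth
  })
}

#' Check referential integrity of a ground truth against its catalog
#'
#' Every identifier referenced by the truth must resolve against the
#' generated catalog, and planted DE directions must be well-formed.
#'
#' @param truth a `ground_truth`.
#' @param catalog the `ref_catalog` it was planned against.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_ground_truth <- function(truth, catalog) {
  ok_mirna <- function(x) all(x %in% catalog$mirnas$id)
  if (!ok_mirna(truth$de$mirna_id)) stop("DE miRNA id not in catalog")
  if (!ok_mirna(truth$star_dominant_ids)) stop("star-dominant id not in catalog")
  if (!ok_mirna(truth$true_targets$mirna_id)) stop("target miRNA id not in catalog")
  if (!all(truth$de$direction %in% c("broiler_up", "layer_up"))) {
    stop("DE direction must be broiler_up or layer_up")
  }
  if (!all(truth$true_targets$gene_id %in% truth$gene_ids)) {
    stop("target gene id not in gene set")
  }
  if (!all(unlist(truth$planted_homolog_map) %in% SIM_SPECIES)) {
    stop("homolog map references unknown species")
  }
  invisible(TRUE)
}
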