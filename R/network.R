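# Interaction-network construction: canonical seed-match target prediction
# (8mer, 7mer-m8, 7mer-1A), opposite-expression filtering of predicted
# miRNA-target edges, and Pearson-correlation filtering of PPI-derived
# target-target edges, assembled into one graph.

SITE_PRIORITY <- c("8mer" = 3L, "7mer-m8" = 2L, "7mer-1A" = 1L)

#' Find canonical seed sites of a miRNA in a 3'UTR
#'
#' Site definitions against miRNA positions 1-8 (5' to 3'): 7mer-m8 is an
#' exact reverse-complement match to positions 2-8; 7mer-1A is an exact
#' reverse-complement match to positions 2-7 followed by an A in the UTR;
#' 8mer is both (positions 2-8 matched and trailing A). Overlapping sites
#' are reported once, at the strongest type (8mer > 7mer-m8 > 7mer-1A).
#'
#' @param mirna_sequence miRNA sequence (>= 8 nt, DNA or RNA alphabet).
#' @param utr_sequence UTR sequence.
#' @return data frame: site `type`, `start` (0-based position in the UTR),
#'   `end` (half-open) -- ordered by position.
#' @export
find_seed_sites <- function(mirna_sequence, utr_sequence) {
  m <- as_dna(mirna_sequence)
  utr <- as_dna(utr_sequence)
  if (nchar(m) < 8L) stop("miRNA sequence must be >= 8 nt")
  if (grepl("[^ACGT]", m) || grepl("[^ACGT]", utr)) {
    stop("sequences must be over the A/C/G/T (or U) alphabet")
  }
  seed78 <- revcomp(substr(m, 2L, 8L))  # 7 nt
  seed67 <- revcomp(substr(m, 2L, 7L))  # 6 nt

  find_all <- function(pattern) {
    hits <- gregexpr(pattern, utr, fixed = TRUE)[[1]]
    if (hits[1] == -1L) integer(0) else as.integer(hits)
  }

  sites <- list()
  for (p in find_all(seed78)) {
    trailing_a <- p + 7L <= nchar(utr) && substr(utr, p + 7L, p + 7L) == "A"
    if (trailing_a) {
      sites[[length(sites) + 1L]] <- data.frame(type = "8mer", start = p - 1L,
                                                end = p + 7L)
    } else {
      sites[[length(sites) + 1L]] <- data.frame(type = "7mer-m8", start = p - 1L,
                                                end = p + 6L)
    }
  }
  for (p in find_all(seed67)) {
    if (p + 6L <= nchar(utr) && substr(utr, p + 6L, p + 6L) == "A") {
      sites[[length(sites) + 1L]] <- data.frame(type = "7mer-1A", start = p - 1L,
                                                end = p + 6L)
    }
  }
  if (length(sites) == 0) {
    return(data.frame(type = character(0), start = integer(0), end = integer(0)))
  }
  out <- do.call(rbind, sites)
  # overlap resolution: keep the strongest type at any overlapping location
  out <- out[order(-SITE_PRIORITY[out$type], out$start), , drop = FALSE]
  kept <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    overlaps_kept <- any(kept & out$start < out$end[i] & out$end > out$start[i])
    kept[i] <- !overlaps_kept
  }
  out <- out[kept, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict miRNA-target edges by seed matching over a UTR set
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param utrs named character vector of UTR sequences.
#' @return data frame of predicted edges: mirna_id, gene_id, n_sites,
#'   site_types (comma-collapsed, strongest first).
#' @export
predict_targets <- function(mirnas, utrs) {
  rows <- list()
  for (mid in names(mirnas)) {
    for (gid in names(utrs)) {
      s <- find_seed_sites(mirnas[[mid]], utrs[[gid]])
      if (nrow(s) > 0) {
        types <- names(sort(-SITE_PRIORITY[unique(s$type)]))
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = mid, gene_id = gid, n_sites = nrow(s),
          site_types = paste(types, collapse = ","),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(mirna_id = character(0), gene_id = character(0),
                      n_sites = integer(0), site_types = character(0)))
  }
  do.call(rbind, rows)
}

#' Filter predicted targets by differential and opposite expression
#'
#' A predicted miRNA-target edge survives iff the target is in the
#' microarray DE union and its breed direction is opposite to the miRNA's
#' sequencing-based direction at one or more time points where the target
#' was called differentially expressed.
#'
#' @param predictions data frame from [predict_targets()].
#' @param de_genes a `microarray_de` from [de_genes_microarray()].
#' @param mirna_directions named character vector (`broiler_up`/`layer_up`)
#'   for each miRNA; miRNAs without a direction have their edges dropped
#'   with a warning.
#' @return the retained edges.
#' @export
filter_targets_by_expression <- function(predictions, de_genes,
                                         mirna_directions) {
  if (nrow(predictions) == 0) return(predictions)
  known <- predictions$mirna_id %in% names(mirna_directions) &
    !is.na(mirna_directions[predictions$mirna_id])
  if (any(!known)) {
    warning(sum(!known), " predicted edges dropped: miRNA without a ",
            "direction call")
    predictions <- predictions[known, , drop = FALSE]
  }
  if (nrow(predictions) == 0) return(predictions)
  dirs <- de_genes$directions
  keep <- vapply(seq_len(nrow(predictions)), function(i) {
    g <- predictions$gene_id[i]
    if (!g %in% de_genes$union_nonredundant) return(FALSE)
    mdir <- mirna_directions[[predictions$mirna_id[i]]]
    gdirs <- dirs$direction[dirs$gene_id == g]
    any(gdirs != mdir)
  }, logical(1))
  out <- predictions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation of two expression profiles
#'
#' @param profile_a,profile_b numeric vectors over the same sample ordering.
#' @return the product-moment correlation.
#' @export
pcc <- function(profile_a, profile_b) {
  if (length(profile_a) != length(profile_b) || length(profile_a) < 3L) {
    stop("profiles must share length >= 3")
  }
  if (sd(profile_a) == 0 || sd(profile_b) == 0) {
    stop("zero-variance profile: correlation undefined")
  }
  cor(profile_a, profile_b)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the t transform t = r * sqrt(n - 2) / sqrt(1 - r^2) with n - 2
#' degrees of freedom.
#'
#' @param r correlation.
#' @param n number of paired observations (>= 3).
#' @return two-sided p-value.
#' @export
pcc_pvalue <- function(r, n) {
  stopifnot(n >= 3)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
}

#' Filter PPI edges by expression correlation
#'
#' An edge is retained iff both endpoints have expression profiles and
#' |PCC| >= `r_cut` (boundary inclusive). Edges with missing or
#' zero-variance profiles are skipped with a warning.
#'
#' @param ppi_edges data frame with `gene_a`, `gene_b`.
#' @param profiles numeric matrix, genes x samples.
#' @param r_cut absolute-correlation cutoff (default 0.3).
#' @return retained edges with a `pcc` column.
#' @export
filter_ppi <- function(ppi_edges, profiles, r_cut = 0.3) {
  if (nrow(ppi_edges) == 0) {
    ppi_edges$pcc <- numeric(0)
    return(ppi_edges)
  }
  have <- ppi_edges$gene_a %in% rownames(profiles) &
    ppi_edges$gene_b %in% rownames(profiles)
  if (any(!have)) {
    warning(sum(!have), " PPI edges skipped: endpoint without a profile")
  }
  edges <- ppi_edges[have, , drop = FALSE]
  r <- vapply(seq_len(nrow(edges)), function(i) {
    a <- profiles[edges$gene_a[i], ]
    b <- profiles[edges$gene_b[i], ]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
  if (anyNA(r)) {
    warning(sum(is.na(r)), " PPI edges skipped: zero-variance profile")
  }
  keep <- !is.na(r) & abs(r) >= r_cut
  out <- edges[keep, , drop = FALSE]
  out$pcc <- r[keep]
  rownames(out) <- NULL
  out
}

#' Assemble the miRNA-target interaction network
#'
#' miRNA nodes connect to targets that passed the opposite-expression
#' filter; target-target edges (correlation-filtered PPI pairs) are kept
#' only when both endpoints are retained targets. Node and edge order is
#' sorted so exports are byte-stable.
#'
#' @param mt_edges retained miRNA-target edges
#'   (from [filter_targets_by_expression()]).
#' @param tt_edges retained target-target edges (from [filter_ppi()]).
#' @return an object of class `interaction_network` wrapping an
#'   [igraph::graph] plus the edge tables.
#' @export
assemble_network <- function(mt_edges, tt_edges) {
  targets <- sort(unique(mt_edges$gene_id))
  if (nrow(tt_edges) > 0) {
    ok <- tt_edges$gene_a %in% targets & tt_edges$gene_b %in% targets
    if (any(!ok)) {
      warning(sum(!ok), " target-target edges dropped: endpoint is not a ",
              "retained target")
    }
    tt_edges <- tt_edges[ok, , drop = FALSE]
  }
  mirnas <- sort(unique(mt_edges$mirna_id))
  nodes <- data.frame(
    name = c(mirnas, targets),
    type = rep(c("miRNA", "target"), c(length(mirnas), length(targets))),
    stringsAsFactors = FALSE
  )
  mt <- mt_edges[order(mt_edges$mirna_id, mt_edges$gene_id), , drop = FALSE]
  tt <- tt_edges[order(tt_edges$gene_a, tt_edges$gene_b), , drop = FALSE]
  edge_df <- rbind(
    if (nrow(mt) > 0) data.frame(from = mt$mirna_id, to = mt$gene_id,
                                 relation = "miRNA-target",
                                 weight = NA_real_) else NULL,
    if (nrow(tt) > 0) data.frame(from = tt$gene_a, to = tt$gene_b,
                                 relation = "target-target",
                                 weight = tt$pcc) else NULL
  )
  g <- if (nrow(nodes) > 0) {
    igraph::graph_from_data_frame(
      edge_df %||% data.frame(from = character(0), to = character(0)),
      directed = FALSE, vertices = nodes)
  } else {
    igraph::make_empty_graph(directed = FALSE)
  }
  out <- list(graph = g, mt_edges = mt, tt_edges = tt, nodes = nodes)
  class(out) <- "interaction_network"
  out
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("<interaction_network>",
      sum(x$nodes$type == "miRNA"), "miRNAs,",
      sum(x$nodes$type == "target"), "targets,",
      nrow(x$mt_edges), "miRNA-target edges,",
      nrow(x$tt_edges), "target-target edges\n")
  invisible(x)
}

#' Network summary statistics
#'
#' @param network an `interaction_network`.
#' @return list of node/edge counts per type and connected components.
#' @export
network_summary <- function(network) {
  comp <- if (igraph::vcount(network$graph) > 0) {
    igraph::components(network$graph)$no
  } else 0L
  list(
    n_mirnas = sum(network$nodes$type == "miRNA"),
    n_targets = sum(network$nodes$type == "target"),
    n_mt_edges = nrow(network$mt_edges),
    n_tt_edges = nrow(network$tt_edges),
    n_components = comp
  )
}

#' Export a network as SIF, GraphML, TSV and a JSON summary
#'
#' @param network an `interaction_network`.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sif <- file.path(dir, "network.sif")
  lines <- c(
    if (nrow(network$mt_edges) > 0)
      sprintf("%s\tmiRNA-target\t%s", network$mt_edges$mirna_id,
              network$mt_edges$gene_id),
    if (nrow(network$tt_edges) > 0)
      sprintf("%s\ttarget-target\t%s", network$tt_edges$gene_a,
              network$tt_edges$gene_b)
  )
  writeLines(lines %||% character(0), sif)
  graphml <- file.path(dir, "network.graphml")
  igraph::write_graph(network$graph, graphml, format = "graphml")
  edges_tsv <- file.path(dir, "edges.tsv")
  edge_df <- rbind(
    if (nrow(network$mt_edges) > 0)
      data.frame(from = network$mt_edges$mirna_id,
                 to = network$mt_edges$gene_id,
                 relation = "miRNA-target", pcc = NA_real_),
    if (nrow(network$tt_edges) > 0)
      data.frame(from = network$tt_edges$gene_a, to = network$tt_edges$gene_b,
                 relation = "target-target", pcc = network$tt_edges$pcc)
  )
  if (is.null(edge_df)) {
    edge_df <- data.frame(from = character(0), to = character(0),
                          relation = character(0), pcc = numeric(0))
  }
  write.table(edge_df, edges_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  summary_json <- file.path(dir, "network_summary.json")
  jsonlite::write_json(network_summary(network), summary_json,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(sif, graphml, edges_tsv, summary_json))
}
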