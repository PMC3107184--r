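# One-call bundle generation and on-disk serialization of every synthetic
# input the pipeline consumes: genome FASTA, BED tracks, catalog FASTA +
# manifest, collapsed FASTA / raw FASTQ libraries, expression matrix, PPI
# edges, UTR FASTA and the ground truth tables.

#' Generate a complete synthetic input bundle
#'
#' Runs every generator in dependency order under one master seed and
#' returns all artifacts in memory with their ground truth.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_bundle` with elements `config`, `genome`
#'   (a `sim_genome`), `truth`, `libs` (a `sim_libraries`), `expression`,
#'   `ppi`, `utrs` and `species_genomes`.
#' @export
simulate_bundle <- function(config = sim_config()) {
  g <- gen_genome(config)
  truth <- plan_ground_truth(config, g$catalog)
  libs <- gen_read_libraries(config, g$catalog, truth, g$features)
  expression <- gen_expression_matrix(config, truth)
  ppi <- gen_ppi_edges(config, truth)
  utrs <- gen_utrs(config, g$catalog, truth)
  species <- gen_species_genomes(config, g$catalog, truth)
  out <- list(config = config, genome = g, truth = truth, libs = libs,
              expression = expression, ppi = ppi, utrs = utrs,
              species_genomes = species)
  class(out) <- "sim_bundle"
  out
}

write_bed <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$feature_id)) gr$feature_id else ".",
    score = 0L,
    strand = as.character(GenomicRanges::strand(gr))
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_bed <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end),
                         strand = df$strand, feature_id = df$name)
}

#' Write a synthetic bundle to disk
#'
#' Serializes all bundle artifacts as plain text: FASTA (genome, catalog,
#' UTRs, species genomes), BED6 tracks (0-based half-open), collapsed FASTA
#' and raw FASTQ read libraries, and TSV tables (catalog manifest, expression
#' matrix + sample manifest, PPI edges, ground truth).
#'
#' @param bundle a `sim_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- bundle$genome

  Biostrings::writeXStringSet(g$genome, file.path(dir, "genome.fa"))
  write_bed(g$tracks, file.path(dir, "tracks.bed"))

  cat_fa <- Biostrings::DNAStringSet(c(
    setNames(g$catalog$mirnas$sequence, g$catalog$mirnas$id),
    setNames(g$catalog$stars$sequence, g$catalog$stars$id),
    setNames(g$catalog$hairpins$sequence, g$catalog$hairpins$hairpin_id)
  ))
  Biostrings::writeXStringSet(cat_fa, file.path(dir, "catalog.fa"))
  hp <- g$catalog$hairpins
  manifest <- data.frame(
    id = c(g$catalog$mirnas$id, g$catalog$stars$id),
    arm = rep(c("mature", "star"), c(nrow(g$catalog$mirnas), nrow(g$catalog$stars))),
    hairpin_id = c(g$catalog$mirnas$hairpin_id, g$catalog$stars$hairpin_id),
    chrom = hp$chrom[match(c(g$catalog$mirnas$hairpin_id, g$catalog$stars$hairpin_id),
                           hp$hairpin_id)],
    start0 = hp$start0[match(c(g$catalog$mirnas$hairpin_id, g$catalog$stars$hairpin_id),
                             hp$hairpin_id)],
    strand = hp$strand[match(c(g$catalog$mirnas$hairpin_id, g$catalog$stars$hairpin_id),
                             hp$hairpin_id)]
  )
  write.table(manifest, file.path(dir, "catalog_manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  for (lib in names(bundle$libs$libraries)) {
    df <- bundle$libs$libraries[[lib]]
    tab <- table(df$sequence)
    write_collapsed_fasta(
      data.frame(sequence = names(tab), count = as.integer(tab)),
      file.path(dir, paste0(lib, "_collapsed.fa"))
    )
  }
  write_raw_fastq(bundle$libs, bundle$config, dir)

  em <- bundle$expression
  write.table(data.frame(gene_id = rownames(em$matrix), em$matrix,
                         check.names = FALSE),
              file.path(dir, "expression_matrix.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(em$manifest, file.path(dir, "sample_manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$ppi, file.path(dir, "ppi_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(bundle$utrs),
                              file.path(dir, "utrs.fa"))
  for (sp in names(bundle$species_genomes)) {
    Biostrings::writeXStringSet(bundle$species_genomes[[sp]],
                                file.path(dir, paste0("species_", sp, ".fa")))
  }

  write.table(bundle$truth$de, file.path(dir, "truth_de_mirnas.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$truth$true_targets, file.path(dir, "truth_targets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
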