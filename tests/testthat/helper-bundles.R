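# Shared fixtures: synthetic bundles are generated once per session and
# cached; every test that needs one reuses the same object.

.fixture_cache <- new.env(parent = emptyenv())

tiny_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, genome_length = 40000L, n_mirnas = 12L,
               n_de_mirnas = 4L,
               library_sizes = c(layer = 4000L, broiler = 4000L),
               n_genes = 60L, n_ppi_edges = 20L, n_true_targets = 9L)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

tiny_bundle <- function(seed = 1L) {
  key <- paste0("tiny", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_bundle(tiny_config(seed))
  }
  .fixture_cache[[key]]
}

default_bundle <- function() {
  if (is.null(.fixture_cache$default)) {
    .fixture_cache$default <- simulate_bundle(sim_config(seed = 1L))
  }
  .fixture_cache$default
}

# preprocess + annotate a bundle, cached by label
analyzed_bundle <- function(bundle, label) {
  key <- paste0("analyzed_", label)
  if (is.null(.fixture_cache[[key]])) {
    tags <- collapse_reads(lapply(bundle$libs$libraries,
                                  function(df) df$sequence))
    mapped <- map_exact(tags, bundle$genome$genome)
    ann <- suppressMessages(
      annotate_cascade(mapped$tags, bundle$genome$catalog, mapped$loci))
    .fixture_cache[[key]] <- list(
      tags = mapped$tags, loci = mapped$loci, annotation = ann,
      expr_tab = build_expression_table(ann, mapped$tags),
      star_tab = build_expression_table(ann, mapped$tags,
                                        category = "chicken_miRNA_star"),
      n_mapped = vapply(names(bundle$libs$libraries), function(lib) {
        summarize_library(mapped$tags, lib)$mapped_reads
      }, numeric(1))
    )
  }
  .fixture_cache[[key]]
}
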