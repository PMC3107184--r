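# Read preprocessing: adapter trimming, length filtering, collapsing to
# unique tags with per-library counts, exact genome mapping and library
# summaries. Coordinates are 0-based half-open internally and in BED output;
# all sequences live in the DNA alphabet.

#' Trim the 3' adapter from raw reads
#'
#' Removes the longest read suffix that exactly matches a prefix of the
#' adapter, provided the match is at least `min_overlap` nt. Reads with no
#' adapter occurrence are kept whole. Reads containing N are dropped: the
#' sequencer's own low-quality filter is unspecified upstream, so the
#' N-content rule stands in for it (flagged in logs).
#'
#' @param reads character vector of raw read sequences.
#' @param adapter adapter sequence (non-empty).
#' @param min_overlap minimum adapter prefix length to trim (>= 1).
#' @return character vector of trimmed reads (N-containing reads removed).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L) {
  adapter <- as_dna(adapter)
  if (nchar(adapter) == 0) stop("adapter must be non-empty")
  if (min_overlap < 1L || min_overlap > nchar(adapter)) {
    stop("min_overlap must satisfy 1 <= min_overlap <= nchar(adapter)")
  }
  reads <- as_dna(reads)
  has_n <- grepl("N", reads, fixed = TRUE)
  if (any(has_n)) {
    message(sum(has_n), " reads dropped for containing N ",
            "(stand-in low-quality filter; no quality threshold specified)")
    reads <- reads[!has_n]
  }
  len <- nchar(reads)
  trimmed_at <- rep(NA_integer_, length(reads))
  k_hi <- min(nchar(adapter), if (length(len)) max(len) else 0L)
  # longest suffix first: scan k from long to short, record first (longest) hit
  if (k_hi >= min_overlap) {
    for (k in seq(k_hi, min_overlap, by = -1L)) {
      cand <- is.na(trimmed_at) & len >= k
      if (!any(cand)) next
      hit <- cand & substr(reads, len - k + 1L, len) == substr(adapter, 1L, k)
      trimmed_at[hit] <- len[hit] - k
    }
  }
  out <- ifelse(is.na(trimmed_at), reads, substr(reads, 1L, trimmed_at))
  out[nchar(out) > 0]
}

#' Filter reads by insert length
#'
#' @param reads character vector.
#' @param min_len,max_len inclusive length bounds (default the 16-30 nt
#'   insert range of the library protocol).
#' @return reads within bounds.
#' @export
filter_length <- function(reads, min_len = 16L, max_len = 30L) {
  if (min_len > max_len) stop("min_len must not exceed max_len")
  reads[nchar(reads) >= min_len & nchar(reads) <= max_len]
}

#' Collapse reads into unique tags with per-library counts
#'
#' @param reads named list: one character vector of read sequences per
#'   library id.
#' @return data frame with one row per distinct sequence and one integer
#'   count column per library (named after the library ids).
#' @export
collapse_reads <- function(reads) {
  stopifnot(is.list(reads), !is.null(names(reads)))
  all_seq <- sort(unique(unlist(reads, use.names = FALSE)))
  tags <- data.frame(sequence = all_seq, stringsAsFactors = FALSE)
  for (lib in names(reads)) {
    tab <- table(reads[[lib]])
    cnt <- integer(length(all_seq))
    idx <- match(names(tab), all_seq)
    cnt[idx] <- as.integer(tab)
    tags[[lib]] <- cnt
  }
  tags
}

# expand a tag table back into per-library read vectors (inverse of collapse)
expand_tags <- function(tags) {
  libs <- setdiff(names(tags), c("sequence", "n_loci"))
  lapply(setNames(nm = libs), function(lib) {
    rep(tags$sequence, tags[[lib]])
  })
}

#' Map unique tags to a genome by exact matching
#'
#' Finds all exact occurrences of every tag on both strands (minus-strand
#' loci match the reverse complement of the genome slice). Coordinates are
#' 0-based half-open. Tags without a perfect hit keep zero loci.
#'
#' @param tags tag data frame from [collapse_reads()].
#' @param genome a [Biostrings::DNAStringSet].
#' @return list with `tags` (input plus an `n_loci` column) and `loci`
#'   (data frame: tag index, chrom, start, end, strand).
#' @export
map_exact <- function(tags, genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  seqs <- tags$sequence
  loci <- list()
  by_width <- split(seq_along(seqs), nchar(seqs))
  for (chrom in names(genome)) {
    subject <- genome[[chrom]]
    for (idx in by_width) {
      dict_fwd <- Biostrings::PDict(seqs[idx])
      m <- Biostrings::matchPDict(dict_fwd, subject)
      starts <- IRanges::start(m)
      n_hit <- lengths(starts)
      if (sum(n_hit) > 0) {
        loci[[length(loci) + 1L]] <- data.frame(
          tag = rep(idx, n_hit),
          chrom = chrom,
          start = unlist(starts) - 1L,
          end = unlist(starts) - 1L + rep(nchar(seqs[idx]), n_hit),
          strand = "+",
          stringsAsFactors = FALSE
        )
      }
      dict_rev <- Biostrings::PDict(revcomp(seqs[idx]))
      m <- Biostrings::matchPDict(dict_rev, subject)
      starts <- IRanges::start(m)
      n_hit <- lengths(starts)
      if (sum(n_hit) > 0) {
        loci[[length(loci) + 1L]] <- data.frame(
          tag = rep(idx, n_hit),
          chrom = chrom,
          start = unlist(starts) - 1L,
          end = unlist(starts) - 1L + rep(nchar(seqs[idx]), n_hit),
          strand = "-",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  loci <- if (length(loci) > 0) do.call(rbind, loci) else {
    data.frame(tag = integer(0), chrom = character(0), start = integer(0),
               end = integer(0), strand = character(0))
  }
  loci <- loci[order(loci$tag, loci$chrom, loci$start, loci$strand), , drop = FALSE]
  rownames(loci) <- NULL
  tags$n_loci <- tabulate(loci$tag, nbins = nrow(tags))
  list(tags = tags, loci = loci)
}

#' Summarize a mapped library
#'
#' @param tags tag data frame with an `n_loci` column (from [map_exact()]).
#' @param library_id which count column to summarize.
#' @return an object of class `library_summary`: total reads, unique tags,
#'   mapped reads, mapped fraction and the read-weighted length histogram.
#' @export
summarize_library <- function(tags, library_id) {
  cnt <- tags[[library_id]]
  if (is.null(cnt)) stop("no count column for library ", library_id)
  present <- cnt > 0
  total <- sum(cnt)
  mapped <- sum(cnt[tags$n_loci > 0])
  lens <- nchar(tags$sequence)
  hist <- tapply(cnt[present], lens[present], sum)
  out <- list(
    library_id = library_id,
    total_reads = total,
    unique_tags = sum(present),
    mapped_reads = mapped,
    mapped_fraction = if (total > 0) mapped / total else NA_real_,
    length_histogram = setNames(as.integer(hist), names(hist))
  )
  class(out) <- "library_summary"
  out
}

#' @export
print.library_summary <- function(x, ...) {
  cat(sprintf("<library_summary> %s: %d reads, %d unique tags, %d mapped (%.1f%%)\n",
              x$library_id, x$total_reads, x$unique_tags, x$mapped_reads,
              100 * x$mapped_fraction))
  invisible(x)
}

#' Pool mapped-read statistics over several library summaries
#'
#' @param ... `library_summary` objects.
#' @return list with pooled `total_reads`, `mapped_reads` and
#'   `mapped_fraction`.
#' @export
pool_summaries <- function(...) {
  xs <- list(...)
  total <- sum(vapply(xs, `[[`, numeric(1), "total_reads"))
  mapped <- sum(vapply(xs, `[[`, numeric(1), "mapped_reads"))
  list(total_reads = total, mapped_reads = mapped,
       mapped_fraction = mapped / total)
}

#' Read a FASTQ or FASTA file into a character vector of sequences
#'
#' @param path file path (FASTQ when the extension contains "fastq"/"fq").
#' @return character vector of DNA sequences.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", path)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  as_dna(as.character(x))
}

#' Write a collapsed-FASTA tag file
#'
#' Header dialect: `>tag_<serial>_x<count>`.
#'
#' @param tags data frame with `sequence` and `count` columns.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_collapsed_fasta <- function(tags, path) {
  writeLines(paste0(">tag_", seq_len(nrow(tags)), "_x", tags$count, "\n",
                    tags$sequence), path)
  invisible(path)
}

#' Read a collapsed-FASTA tag file
#'
#' @param path file written by [write_collapsed_fasta()].
#' @return data frame with `sequence` and `count`.
#' @export
read_collapsed_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  counts <- as.integer(sub(".*_x(\\d+)$", "\\1", names(x)))
  data.frame(sequence = unname(as_dna(as.character(x))), count = counts,
             stringsAsFactors = FALSE)
}
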