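# Novel miRNA candidate discovery. The probabilistic scoring of the external
# predictor the published analysis used is deliberately NOT re-implemented;
# candidate calling is a documented rule triple -- stem-loop structure with
# the modal read footprint on one arm, arm-consistency of the read stack,
# and 5'-end homogeneity -- applied to precursor windows excised around
# genome-mapped read clusters. Candidate lists therefore differ from the
# original publication's by construction. A mononucleotide-preserving
# per-tag shuffle provides the permuted-dataset signal-to-noise control.

#' Filter tags by mapping multiplicity and repeat overlap
#'
#' A tag is retained iff it maps to between 1 and `max_loci` genomic
#' positions and none of its loci overlaps a repeat interval. Idempotent.
#'
#' @param mapped result of [map_exact()] (list of `tags`, `loci`).
#' @param repeat_track [GenomicRanges::GRanges] of repeat intervals (may be
#'   empty).
#' @param max_loci maximum number of genomic positions (default 5).
#' @return a filtered `list(tags, loci)` in the same shape.
#' @export
filter_mappings <- function(mapped, repeat_track = NULL, max_loci = 5L) {
  tags <- mapped$tags
  loci <- mapped$loci
  keep <- tags$n_loci >= 1L & tags$n_loci <= max_loci
  if (!is.null(repeat_track) && length(repeat_track) > 0 && nrow(loci) > 0) {
    gr <- GenomicRanges::GRanges(loci$chrom,
                                 IRanges::IRanges(loci$start + 1L, loci$end))
    ov <- GenomicRanges::findOverlaps(gr, repeat_track, ignore.strand = TRUE)
    in_repeat <- unique(loci$tag[S4Vectors::queryHits(ov)])
    keep[in_repeat] <- FALSE
  }
  idx <- which(keep)
  new_loci <- loci[loci$tag %in% idx, , drop = FALSE]
  new_loci$tag <- match(new_loci$tag, idx)
  tags <- tags[idx, , drop = FALSE]
  rownames(tags) <- rownames(new_loci) <- NULL
  list(tags = tags, loci = new_loci)
}

#' Excise candidate precursor windows around mapped read clusters
#'
#' Overlapping same-strand loci are clustered; each cluster is anchored on
#' its highest-count tag locus and excised twice -- once assuming the reads
#' sit on the 5' arm (window extends `flank` nt downstream) and once
#' assuming the 3' arm (window extends upstream) -- then clipped at
#' chromosome ends and deduplicated by (chrom, start, end, strand).
#'
#' @param filtered result of [filter_mappings()].
#' @param genome [Biostrings::DNAStringSet].
#' @param flank flank length in nt (default 70).
#' @return data frame of windows: window_id, chrom, start, end (0-based
#'   half-open), strand, anchor_start, anchor_end, cluster_id.
#' @export
excise_precursors <- function(filtered, genome, flank = 70L) {
  loci <- filtered$loci
  tags <- filtered$tags
  if (nrow(loci) == 0) {
    return(data.frame(window_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), anchor_start = integer(0),
                      anchor_end = integer(0), cluster_id = integer(0)))
  }
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  libs <- setdiff(names(tags), c("sequence", "n_loci"))
  tag_total <- rowSums(tags[, libs, drop = FALSE])

  gr <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$start + 1L, loci$end),
                               strand = loci$strand)
  clusters <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  chrom_len <- setNames(Biostrings::width(genome), names(genome))

  rows <- lapply(seq_along(clusters), function(ci) {
    members <- clusters$revmap[[ci]]
    counts <- tag_total[loci$tag[members]]
    anchor <- loci[members[which.max(counts)], ]
    G <- chrom_len[[anchor$chrom]]
    w5 <- c(max(0L, anchor$start - 10L), min(G, anchor$end + flank))
    w3 <- c(max(0L, anchor$start - flank), min(G, anchor$end + 10L))
    data.frame(chrom = anchor$chrom,
               start = c(w5[1], w3[1]), end = c(w5[2], w3[2]),
               strand = anchor$strand,
               anchor_start = anchor$start, anchor_end = anchor$end,
               cluster_id = ci, stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, rows)
  win <- win[!duplicated(win[, c("chrom", "start", "end", "strand")]), , drop = FALSE]
  win$window_id <- sprintf("win-%04d", seq_len(nrow(win)))
  rownames(win) <- NULL
  win[, c("window_id", "chrom", "start", "end", "strand",
          "anchor_start", "anchor_end", "cluster_id")]
}

#' Build the read stack of each excised window
#'
#' @param windows data frame from [excise_precursors()].
#' @param filtered result of [filter_mappings()].
#' @param genome [Biostrings::DNAStringSet].
#' @return named list of `read_stack` objects: window row, window sequence
#'   (strand-oriented), and member tags with window-relative 1-based
#'   coordinates and per-library counts.
#' @export
build_read_stacks <- function(windows, filtered, genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  loci <- filtered$loci
  tags <- filtered$tags
  libs <- setdiff(names(tags), c("sequence", "n_loci"))
  stacks <- lapply(seq_len(nrow(windows)), function(wi) {
    w <- windows[wi, ]
    inside <- loci$chrom == w$chrom & loci$strand == w$strand &
      loci$start >= w$start & loci$end <= w$end
    mem <- loci[inside, , drop = FALSE]
    wseq <- substr(as.character(genome[[w$chrom]]), w$start + 1L, w$end)
    if (w$strand == "-") {
      wseq <- revcomp(wseq)
      rel_start <- w$end - mem$end + 1L
      rel_end <- w$end - mem$start
    } else {
      rel_start <- mem$start - w$start + 1L
      rel_end <- mem$end - w$start
    }
    members <- data.frame(rel_start = rel_start, rel_end = rel_end,
                          sequence = tags$sequence[mem$tag],
                          stringsAsFactors = FALSE)
    for (lib in libs) members[[lib]] <- tags[[lib]][mem$tag]
    members$total <- rowSums(members[, libs, drop = FALSE])
    out <- list(window = w, sequence = wseq, members = members)
    class(out) <- "read_stack"
    out
  })
  names(stacks) <- windows$window_id
  stacks
}

# Stem support of a read footprint under a fold: the largest number of
# footprint bases paired into one star window of footprint-like width
# (footprint + 10 nt of slack for bulges), together with that window.
footprint_stem <- function(fold, footprint) {
  pos <- footprint[1]:footprint[2]
  p <- fold$pairs[pos]
  partners <- p[!is.na(p) & (p < footprint[1] | p > footprint[2])]
  if (length(partners) == 0) return(NULL)
  width <- length(pos) + 10L
  best <- 0L
  best_lo <- NA_integer_
  for (lo in partners) {
    cnt <- sum(partners >= lo & partners <= lo + width - 1L)
    if (cnt > best) { best <- cnt; best_lo <- lo }
  }
  list(paired = best, star = c(best_lo, min(best_lo + width - 1L, length(fold$pairs))))
}

# Stem rule with precursor-trimmed refolds: the full window is folded first;
# if the footprint does not pair into one star window there, precursor-sized
# subwindows (footprint plus a loop + star-length flank on one side) are
# refolded, since flanking sequence can distract a maximum-pairing fold from
# the true stem. Returns NULL or list(paired fraction, star interval in
# window coordinates).
stem_support <- function(wseq, m_iv, threshold) {
  m_len <- diff(m_iv) + 1L
  n <- nchar(wseq)
  try_fold <- function(lo, hi) {
    f <- fold_hairpin(substr(wseq, lo, hi))
    stem <- footprint_stem(f, m_iv - lo + 1L)
    if (is.null(stem)) return(NULL)
    frac <- stem$paired / m_len
    if (frac > threshold) list(frac = frac, star = stem$star + lo - 1L)
    else NULL
  }
  hit <- try_fold(1L, n)
  if (!is.null(hit)) return(hit)
  for (tt in c(45L, 36L)) {
    for (w in list(c(max(1L, m_iv[1] - 5L), min(n, m_iv[2] + tt)),
                   c(max(1L, m_iv[1] - tt), min(n, m_iv[2] + 5L)))) {
      hit <- try_fold(w[1], w[2])
      if (!is.null(hit)) return(hit)
    }
  }
  NULL
}

#' Call novel miRNA candidates from read stacks
#'
#' A window passes iff (a) its fold pairs more than `pairing_threshold` of
#' the modal tag footprint into one star window of footprint-like width
#' outside the footprint (stem rule), (b) at
#' least `arm_consistency` of the stack's reads (count-weighted) lie on the
#' mature or star arm, and (c) at least `homogeneity` of mature-arm reads
#' share one 5' start. All thresholds are configurable.
#'
#' @param stacks list of `read_stack` objects from [build_read_stacks()].
#' @param pairing_threshold stem rule threshold (default 0.7).
#' @param arm_consistency minimum fraction of reads on the two arms
#'   (default 0.9).
#' @param homogeneity minimum fraction of mature-arm reads sharing the modal
#'   5' start (default 0.8).
#' @param arm_slop nt of isomiR slack around each arm footprint (default 4).
#' @return data frame: one row per window with per-rule flags, `passes`,
#'   mature arm sequence and per-library mature-arm counts.
#' @export
call_candidates <- function(stacks, pairing_threshold = 0.7,
                            arm_consistency = 0.9, homogeneity = 0.8,
                            arm_slop = 4L) {
  rows <- lapply(stacks, function(st) {
    mem <- st$members
    if (nrow(mem) == 0) return(NULL)
    libs <- setdiff(names(mem), c("rel_start", "rel_end", "sequence", "total"))
    modal <- mem[which.max(mem$total), ]
    m_iv <- c(modal$rel_start, modal$rel_end)

    stem <- stem_support(st$sequence, m_iv, pairing_threshold)
    rule_hairpin <- !is.null(stem)
    s_iv <- if (rule_hairpin) stem$star else NULL

    on_arm <- function(iv) {
      !is.na(iv[1]) &
        mem$rel_start >= iv[1] - arm_slop & mem$rel_end <= iv[2] + arm_slop
    }
    m_arm <- on_arm(m_iv)
    s_arm <- if (!is.null(s_iv)) on_arm(s_iv) else rep(FALSE, nrow(mem))
    rule_arms <- sum(mem$total[m_arm | s_arm]) / sum(mem$total) >= arm_consistency

    m_reads <- mem[m_arm, , drop = FALSE]
    rule_5p <- FALSE
    if (nrow(m_reads) > 0) {
      by_start <- tapply(m_reads$total, m_reads$rel_start, sum)
      rule_5p <- max(by_start) / sum(m_reads$total) >= homogeneity
    }

    counts <- if (nrow(m_reads) > 0) {
      colSums(m_reads[, libs, drop = FALSE])
    } else {
      setNames(rep(0, length(libs)), libs)
    }
    out <- data.frame(window_id = st$window$window_id,
                      chrom = st$window$chrom, start = st$window$start,
                      end = st$window$end, strand = st$window$strand,
                      cluster_id = st$window$cluster_id,
                      rule_hairpin = rule_hairpin, rule_arms = rule_arms,
                      rule_5p = rule_5p,
                      passes = rule_hairpin && rule_arms && rule_5p,
                      mature_sequence = modal$sequence,
                      stringsAsFactors = FALSE)
    for (lib in libs) out[[paste0("count_", lib)]] <- counts[[lib]]
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(window_id = character(0), passes = logical(0)))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# Candidate loci: overlapping passing windows (e.g. the mature-arm and
# star-arm views of one precursor) are merged into a single locus.
count_candidate_loci <- function(calls) {
  hits <- calls[calls$passes %in% TRUE, , drop = FALSE]
  if (nrow(hits) == 0) return(0L)
  gr <- GenomicRanges::GRanges(hits$chrom,
                               IRanges::IRanges(hits$start + 1L, hits$end),
                               strand = hits$strand)
  length(GenomicRanges::reduce(gr))
}

#' Shuffle tag sequences preserving mononucleotide composition
#'
#' Each tag's sequence is independently permuted; counts are untouched, so
#' per-library totals are preserved exactly. A dinucleotide-preserving
#' variant is available via `preserve = "dinucleotide"` (Altschul-Erickson
#' style swap shuffle).
#'
#' @param tags tag data frame.
#' @param seed RNG seed (shuffle is deterministic given the seed).
#' @param preserve `"mononucleotide"` (default) or `"dinucleotide"`.
#' @return the tag table with shuffled sequences.
#' @export
permute_reads <- function(tags, seed, preserve = "mononucleotide") {
  preserve <- match.arg(preserve, c("mononucleotide", "dinucleotide"))
  with_seed(as.integer(seed), {
    tags$sequence <- vapply(tags$sequence, function(s) {
      ch <- strsplit(s, "")[[1]]
      if (preserve == "mononucleotide") {
        paste(sample(ch), collapse = "")
      } else {
        # swap-based shuffle approximately preserving dinucleotide counts
        n <- length(ch)
        for (it in seq_len(4L * n)) {
          ij <- sample(n - 2L, 2L)
          i <- min(ij); j <- max(ij)
          if (ch[i] == ch[j]) {  # equal anchors: swapping successors keeps dinucleotide counts
            tmp <- ch[i + 1L]; ch[i + 1L] <- ch[j + 1L]; ch[j + 1L] <- tmp
          }
        }
        paste(ch, collapse = "")
      }
    }, character(1), USE.NAMES = FALSE)
    if ("n_loci" %in% names(tags)) tags$n_loci <- NULL
    tags
  })
}

#' Signal-to-noise ratio of candidate discovery
#'
#' @param n_real candidates called on the real dataset.
#' @param n_permuted candidates called on the permuted dataset.
#' @return list: `n_real`, `n_permuted`, `ratio` (= n_real /
#'   max(n_permuted, 1)), `ratio_rounded` (nearest integer) and
#'   `degenerate_denominator` flag when no permuted candidate was found.
#' @export
signal_to_noise <- function(n_real, n_permuted) {
  ratio <- n_real / max(n_permuted, 1L)
  list(n_real = as.integer(n_real),
       n_permuted = as.integer(n_permuted),
       ratio = ratio,
       ratio_rounded = as.integer(round_half_away(ratio)),
       degenerate_denominator = n_permuted == 0L)
}
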