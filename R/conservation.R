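# Cross-species conservation rules. A candidate's mature sequence is scanned
# against each target genome by ungapped sliding comparison; accepted hits
# must cover > 80% of the mature, hold at most one mismatch in the covered
# region, and be anchored at the mature's 5' end (the seed side). Accepted
# hits must additionally sit in a precursor that folds into a stem-loop
# pairing > 70% of the mature region to the star region. Secondary structure
# comes from a base-pair-maximization dynamic program (Nussinov-style, GU
# wobble allowed, minimum hairpin loop of 3), a deterministic, self-contained
# fold; externally computed dot-bracket structures can be supplied wherever a
# fold result is consumed.

BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, U = 4L)
CAN_PAIR <- matrix(FALSE, 4, 4)
CAN_PAIR[1, 4] <- CAN_PAIR[4, 1] <- TRUE  # A-U
CAN_PAIR[2, 3] <- CAN_PAIR[3, 2] <- TRUE  # C-G
CAN_PAIR[3, 4] <- CAN_PAIR[4, 3] <- TRUE  # G-U wobble

MIN_LOOP <- 3L

#' Fold a sequence by base-pair maximization
#'
#' Computes a maximum-cardinality set of non-crossing base pairs over
#' {AU, UA, GC, CG, GU, UG} with a minimum hairpin loop of 3 unpaired bases,
#' by dynamic programming. Traceback is deterministic: pairing the 5'-most
#' open base is preferred over leaving it unpaired, and its smallest
#' admissible partner is chosen first.
#'
#' @param sequence one DNA or RNA string (<= 500 nt).
#' @return an object of class `fold_result`: `structure` (dot-bracket),
#'   `pairs` (integer partner vector, `NA` when unpaired) and `n_pairs`.
#' @export
fold_hairpin <- function(sequence) {
  s <- as_dna(sequence)
  n <- nchar(s)
  if (n > 500L) stop("fold_hairpin is limited to sequences of <= 500 nt")
  code <- BASE_CODE[strsplit(s, "")[[1]]]
  if (anyNA(code)) stop("invalid characters in sequence (A/C/G/T/U only)")

  partner <- rep(NA_integer_, n)
  if (n >= MIN_LOOP + 2L) {
    M <- matrix(0L, n + 1L, n + 1L)
    for (span in (MIN_LOOP + 2L):n) {
      for (i in seq_len(n - span + 1L)) {
        j <- i + span - 1L
        kvec <- (i + MIN_LOOP + 1L):j
        ok <- kvec[CAN_PAIR[code[i], code[kvec]]]
        best <- M[i + 1L, j]
        if (length(ok) > 0) {
          vals <- 1L + M[i + 1L, ok - 1L] + M[cbind(ok + 1L, j)]
          best <- max(best, vals)
        }
        M[i, j] <- best
      }
    }
    # traceback
    stack <- list(c(1L, n))
    while (length(stack) > 0) {
      ij <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- ij[1]; j <- ij[2]
      if (j - i < MIN_LOOP + 1L || M[i, j] == 0L) next
      kvec <- (i + MIN_LOOP + 1L):j
      ok <- kvec[CAN_PAIR[code[i], code[kvec]]]
      paired <- FALSE
      if (length(ok) > 0) {
        vals <- 1L + M[i + 1L, ok - 1L] + M[cbind(ok + 1L, j)]
        hit <- ok[vals == M[i, j]]
        if (length(hit) > 0) {
          k <- hit[1]
          partner[i] <- k
          partner[k] <- i
          stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
          stack[[length(stack) + 1L]] <- c(k + 1L, j)
          paired <- TRUE
        }
      }
      if (!paired) stack[[length(stack) + 1L]] <- c(i + 1L, j)
    }
  }

  db <- rep(".", n)
  db[!is.na(partner) & partner > seq_len(n)] <- "("
  db[!is.na(partner) & partner < seq_len(n)] <- ")"
  out <- list(structure = paste(db, collapse = ""),
              pairs = partner,
              n_pairs = sum(!is.na(partner)) %/% 2L)
  class(out) <- "fold_result"
  out
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$structure, "\n", x$n_pairs, "pairs\n")
  invisible(x)
}

#' Parse an externally supplied dot-bracket structure into a fold result
#'
#' Allows thermodynamic folds computed elsewhere to be used in place of the
#' built-in base-pair-maximization fold.
#'
#' @param structure dot-bracket string.
#' @return a `fold_result`.
#' @export
fold_from_dotbracket <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  if (!all(chars %in% c("(", ")", "."))) stop("invalid dot-bracket string")
  n <- length(chars)
  partner <- rep(NA_integer_, n)
  open <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") open <- c(open, i)
    else if (chars[i] == ")") {
      if (length(open) == 0) stop("unbalanced dot-bracket string")
      j <- open[length(open)]
      open <- open[-length(open)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(open) > 0) stop("unbalanced dot-bracket string")
  out <- list(structure = structure, pairs = partner,
              n_pairs = sum(!is.na(partner)) %/% 2L)
  class(out) <- "fold_result"
  out
}

#' Scan a genome for homologs of a mature miRNA
#'
#' Ungapped sliding comparison over both strands. A hit is accepted iff the
#' covered region (always a prefix of the mature -- the seed side must
#' anchor) spans more than `min_coverage` of the mature length and holds at
#' most `max_mismatches` mismatches; the covered length is maximized per
#' offset.
#'
#' @param mature mature miRNA sequence (>= 18 nt).
#' @param genome [Biostrings::DNAStringSet] or character vector.
#' @param species species label carried into the result.
#' @param min_coverage strict lower bound on covered fraction (default 0.8).
#' @param max_mismatches maximum mismatches in the covered region (default 1,
#'   reading "fewer than two mismatches" as <= 1).
#' @return data frame of accepted hits: species, chrom, start (0-based),
#'   end, strand, covered_length, coverage_fraction, mismatches, anchored_5p.
#' @export
scan_homology <- function(mature, genome, species = NA_character_,
                          min_coverage = 0.8, max_mismatches = 1L) {
  mature <- as_dna(mature)
  m <- nchar(mature)
  if (m < 18L) stop("mature sequence must be >= 18 nt")
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome))) names(genome) <- as.character(seq_along(genome))
  min_cov_len <- floor(min_coverage * m) + 1L

  scan_one <- function(gchars, m_codes) {
    G <- length(gchars)
    if (G < min_cov_len) return(NULL)
    n_off <- G - m + 1L
    hits <- NULL
    if (n_off >= 1L) {
      # full-fit offsets, vectorized: locate the first two mismatches
      f1 <- rep(Inf, n_off)
      f2 <- rep(Inf, n_off)
      cnt <- integer(n_off)
      for (p in seq_len(m)) {
        miss <- gchars[p:(p + n_off - 1L)] != m_codes[p]
        newly1 <- miss & cnt == 0L
        newly2 <- miss & cnt == 1L
        f1[newly1] <- p
        f2[newly2] <- p
        cnt <- cnt + miss
      }
      L <- pmin(m, ifelse(is.finite(f2), f2 - 1L, m))
      # the covered region ends at a match: a trailing mismatch adds no
      # coverage, so drop it (at most one, by construction)
      trail <- is.finite(f1) & f1 == L
      L <- L - trail
      mm <- as.integer(is.finite(f1) & f1 <= L)
      acc <- which(L / m > min_coverage & mm <= max_mismatches)
      if (length(acc) > 0) {
        hits <- data.frame(offset0 = acc - 1L, covered = L[acc],
                           mismatches = mm[acc])
      }
    }
    # tail offsets where only a prefix of the mature fits
    tail_off <- seq.int(max(G - m + 2L, 1L), G - min_cov_len + 1L)
    tail_off <- tail_off[tail_off >= 1L & tail_off > n_off]
    for (o in tail_off) {
      avail <- G - o + 1L
      miss <- which(gchars[o:(o + avail - 1L)] != m_codes[seq_len(avail)])
      L <- if (length(miss) >= 2L) miss[2] - 1L else avail
      if (L %in% miss) L <- L - 1L  # covered region ends at a match
      mm <- sum(miss <= L)
      if (L / m > min_coverage && mm <= max_mismatches) {
        hits <- rbind(hits, data.frame(offset0 = o - 1L, covered = L,
                                       mismatches = mm))
      }
    }
    hits
  }

  m_codes <- strsplit(mature, "")[[1]]
  m_codes_rc <- strsplit(revcomp(mature), "")[[1]]
  out <- list()
  for (chrom in names(genome)) {
    gchars <- strsplit(as.character(genome[[chrom]]), "")[[1]]
    G <- length(gchars)
    fwd <- scan_one(gchars, m_codes)
    if (!is.null(fwd)) {
      out[[length(out) + 1L]] <- data.frame(
        species = species, chrom = chrom,
        start = fwd$offset0, end = fwd$offset0 + fwd$covered,
        strand = "+", covered_length = fwd$covered,
        coverage_fraction = fwd$covered / m,
        mismatches = fwd$mismatches, anchored_5p = TRUE,
        stringsAsFactors = FALSE
      )
    }
    # minus strand: scan the reverse complement, map back to forward coords
    rev_chars <- strsplit(revcomp(paste(gchars, collapse = "")), "")[[1]]
    rev_hits <- scan_one(rev_chars, m_codes)
    if (!is.null(rev_hits)) {
      out[[length(out) + 1L]] <- data.frame(
        species = species, chrom = chrom,
        start = G - rev_hits$offset0 - rev_hits$covered,
        end = G - rev_hits$offset0,
        strand = "-", covered_length = rev_hits$covered,
        coverage_fraction = rev_hits$covered / m,
        mismatches = rev_hits$mismatches, anchored_5p = TRUE,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(species = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), covered_length = integer(0),
                      coverage_fraction = numeric(0), mismatches = integer(0),
                      anchored_5p = logical(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Check that a fold pairs the mature region into the star region
#'
#' @param fold a `fold_result`.
#' @param mature_interval,star_interval integer pairs (1-based, closed) of
#'   positions within the folded sequence; must not overlap.
#' @param threshold strict lower bound on the paired fraction (default 0.7).
#' @return `TRUE` iff the fraction of mature-interval bases whose pairing
#'   partner lies inside the star interval exceeds `threshold`.
#' @export
hairpin_check <- function(fold, mature_interval, star_interval,
                          threshold = 0.7) {
  if (mature_interval[1] <= star_interval[2] &&
      star_interval[1] <= mature_interval[2]) {
    stop("mature and star intervals must not overlap")
  }
  pos <- mature_interval[1]:mature_interval[2]
  p <- fold$pairs[pos]
  frac <- mean(!is.na(p) & p >= star_interval[1] & p <= star_interval[2])
  frac > threshold
}

# Partner hulls of a mature interval, split by side. A stem pairs one arm
# against the other, so the true star region lies entirely on one side of
# the mature; per-side hulls stay disjoint from the mature interval.
side_star_hulls <- function(fold, mature_interval) {
  pos <- mature_interval[1]:mature_interval[2]
  p <- fold$pairs[pos]
  left <- p[!is.na(p) & p < mature_interval[1]]
  right <- p[!is.na(p) & p > mature_interval[2]]
  out <- list()
  if (length(right) > 0) out$right <- range(right)
  if (length(left) > 0) out$left <- range(left)
  out
}

# Star region implied by a fold: the partner hull on the majority side.
# NULL when nothing pairs outside the mature.
infer_star_interval <- function(fold, mature_interval) {
  hulls <- side_star_hulls(fold, mature_interval)
  if (length(hulls) == 0) return(NULL)
  pos <- mature_interval[1]:mature_interval[2]
  p <- fold$pairs[pos]
  n_right <- sum(!is.na(p) & p > mature_interval[2])
  n_left <- sum(!is.na(p) & p < mature_interval[1])
  if (n_right >= n_left) hulls[["right"]] %||% hulls[["left"]]
  else hulls[["left"]]
}

#' Decide whether a genome carries an accepted homolog of a mature miRNA
#'
#' Combines [scan_homology()] with precursor excision and folding: each hit
#' is excised with `flank` nt towards either side (both arm orientations are
#' tried), folded, and checked for > 70% pairing of the hit region into a
#' star region on one side of it. Precursor-sized tight windows (45 nt
#' flank: loop + star + slack) are evaluated as well, since trimming away
#' flanking sequence removes spurious competing pairings from the
#' maximum-pairing fold.
#'
#' @param mature mature sequence.
#' @param genome target genome.
#' @param species label for reporting.
#' @param flank excision flank in nt (default 70).
#' @param max_hits cap on hits examined per genome.
#' @param ... passed to [scan_homology()].
#' @return `TRUE` iff at least one hit passes the fold + pairing rule.
#' @export
homolog_in_genome <- function(mature, genome, species = NA_character_,
                              flank = 70L, max_hits = 10L, ...) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome))) names(genome) <- as.character(seq_along(genome))
  hits <- scan_homology(mature, genome, species = species, ...)
  if (nrow(hits) == 0) return(FALSE)
  hits <- head(hits, max_hits)

  passes <- function(wseq, m_iv) {
    fold <- fold_hairpin(wseq)
    for (hull in side_star_hulls(fold, m_iv)) {
      if (hairpin_check(fold, m_iv, hull)) return(TRUE)
    }
    FALSE
  }

  # precursor-sized flanks: loop (variable) + a star of mature length;
  # several loop lengths are enumerated because foreign precursors vary
  tights <- c(33L, 36L, 40L, 45L)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    G <- nchar(as.character(genome[[h$chrom]]))
    windows <- c(
      list(c(max(0L, h$start - 10L), min(G, h$end + flank)),   # hit on 5' arm
           c(max(0L, h$start - flank), min(G, h$end + 10L))),  # hit on 3' arm
      unlist(lapply(tights, function(tt) {
        list(c(max(0L, h$start - 2L), min(G, h$end + tt)),
             c(max(0L, h$start - tt), min(G, h$end + 2L)))
      }), recursive = FALSE)
    )
    for (w in windows) {
      wseq <- substr(as.character(genome[[h$chrom]]), w[1] + 1L, w[2])
      if (h$strand == "-") {
        wseq <- revcomp(wseq)
        m_start <- w[2] - h$end + 1L
      } else {
        m_start <- h$start - w[1] + 1L
      }
      m_iv <- c(m_start, m_start + h$covered_length - 1L)
      if (passes(wseq, m_iv)) return(TRUE)
    }
  }
  FALSE
}

#' Presence/absence conservation matrix
#'
#' @param matures named character vector of mature sequences.
#' @param genomes named list of target genomes.
#' @param ... passed to [homolog_in_genome()].
#' @return 0/1 integer matrix, miRNA x species.
#' @export
conservation_matrix <- function(matures, genomes, ...) {
  res <- vapply(names(genomes), function(sp) {
    vapply(matures, function(m) {
      as.integer(homolog_in_genome(m, genomes[[sp]], species = sp, ...))
    }, integer(1))
  }, integer(length(matures)))
  if (is.null(dim(res))) res <- matrix(res, nrow = length(matures),
                                       dimnames = list(names(matures), names(genomes)))
  res
}

#' Classify a miRNA's lineage from per-species presence calls
#'
#' @param vertebrate_presence named logical over the six non-avian vertebrate
#'   genomes.
#' @param zebra_finch_present logical.
#' @return `"vertebrate_conserved"` when any non-avian vertebrate carries an
#'   accepted homolog; otherwise `"avian_specific"` when zebra finch does;
#'   otherwise `"chicken_specific"`.
#' @export
classify_lineage <- function(vertebrate_presence, zebra_finch_present) {
  if (any(as.logical(vertebrate_presence))) "vertebrate_conserved"
  else if (isTRUE(as.logical(zebra_finch_present))) "avian_specific"
  else "chicken_specific"
}
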