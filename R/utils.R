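# Shared low-level helpers: alphabet handling, seeded RNG scoping, rounding.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()];
#' everything internal to the package lives in the DNA alphabet.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Normalize sequences to the internal DNA alphabet
#'
#' Uppercases and converts U to T. Sequences are held as DNA internally and
#' rendered as RNA only in human-readable reports.
#'
#' @param x character vector.
#' @return character vector over A/C/G/T/N.
#' @export
as_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Render a DNA sequence as RNA for reports
#' @param x character vector.
#' @return character vector over A/C/G/U.
#' @export
as_rna <- function(x) {
  chartr("T", "U", toupper(x))
}

# Evaluate `expr` under a fixed RNG state without touching the caller's
# global stream. All generator randomness goes through this.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage sub-seed, so independent stages draw from
# independent streams while remaining reproducible from one master seed.
# Kept below 2^31 - 1 (R integers are 32-bit).
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# Random DNA of given widths.
random_dna <- function(widths) {
  vapply(widths, function(w) {
    paste(sample(DNA_BASES, w, replace = TRUE), collapse = "")
  }, character(1))
}

# Round half away from zero (base round() is banker's rounding).
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Display rounding for broiler/layer count ratios
#'
#' Count-ratio tables print two decimals for ratios below 10 and three
#' significant digits (one decimal) at 10 and above, with ties rounded half
#' away from zero. This is the convention the package uses everywhere a B/L
#' ratio is printed.
#'
#' @param x numeric vector of ratios.
#' @return numeric vector, rounded for display.
#' @export
ratio_display <- function(x) {
  ifelse(is.na(x), NA_real_,
         ifelse(abs(x) >= 10, round_half_away(x, 1), round_half_away(x, 2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
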