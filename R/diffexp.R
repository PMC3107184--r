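# Two-library differential expression. Counts x_i from libraries of size
# N_i are modelled as x_i ~ Poisson(N_i * lambda_i); the likelihood-ratio
# statistic for H0: lambda_A = lambda_B is
#   2 * [ x_A log(x_A / (N_A lambda0)) + x_B log(x_B / (N_B lambda0)) ],
# lambda0 = (x_A + x_B) / (N_A + N_B), with 0 log 0 := 0, referred to a
# chi-square distribution with one degree of freedom. Library sizes default
# to genome-mapped read counts (the quantity whose per-read rates the
# comparison is about); raw totals can be supplied instead.

#' Poisson likelihood-ratio test for one count pair
#'
#' Vectorized over count pairs.
#'
#' @param x_a,x_b non-negative counts in libraries A (layer) and B (broiler).
#' @param n_a,n_b positive library sizes (mapped read totals).
#' @param alpha significance cutoff (default 1e-4).
#' @return data frame: per-library rate MLEs, pooled null rate, statistic,
#'   p-value (upper chi-square tail, 1 df) and significance flag. A zero
#'   statistic always yields p = 1.
#' @export
lrt_two_library <- function(x_a, x_b, n_a, n_b, alpha = 1e-4) {
  stopifnot(all(n_a > 0), all(n_b > 0), all(x_a >= 0), all(x_b >= 0))
  lambda_a <- x_a / n_a
  lambda_b <- x_b / n_b
  lambda_0 <- (x_a + x_b) / (n_a + n_b)
  term <- function(x, n) ifelse(x > 0, x * log(x / (n * lambda_0)), 0)
  stat <- 2 * (term(x_a, n_a) + term(x_b, n_b))
  stat <- pmax(stat, 0)  # guard tiny negative rounding at the null
  p <- ifelse(stat == 0, 1, pchisq(stat, df = 1, lower.tail = FALSE))
  data.frame(lambda_a = lambda_a, lambda_b = lambda_b, lambda_0 = lambda_0,
             statistic = stat, p_value = p, significant = p < alpha)
}

#' Call differentially expressed miRNAs between the two libraries
#'
#' Applies [lrt_two_library()] to every row of an expression table. No
#' multiple-testing correction is applied by default: the published analysis
#' uses a raw cutoff of 1e-4. Setting `adjust = "BH"` switches the
#' significance call to Benjamini-Hochberg-adjusted p-values.
#'
#' @param expression_table data frame with `mirna_id`, `layer`, `broiler`.
#' @param n_a,n_b library sizes (mapped totals of the layer and broiler
#'   libraries).
#' @param alpha cutoff on the (possibly adjusted) p-value.
#' @param adjust `"none"` (default, reproducing the published rule) or a
#'   method accepted by [stats::p.adjust()].
#' @return the table augmented with test columns and a `direction` column
#'   (`broiler_up` / `layer_up` by sign of the rate difference; `NA` at
#'   exactly equal rates).
#' @export
call_de_mirnas <- function(expression_table, n_a, n_b, alpha = 1e-4,
                           adjust = "none") {
  res <- lrt_two_library(expression_table$layer, expression_table$broiler,
                         n_a, n_b, alpha = alpha)
  out <- cbind(expression_table, res)
  if (!identical(adjust, "none")) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
    out$significant <- out$p_adjusted < alpha
  }
  d <- out$lambda_b - out$lambda_a
  out$direction <- ifelse(d > 0, "broiler_up",
                          ifelse(d < 0, "layer_up", NA_character_))
  out
}

#' Differentially expressed genes from the developmental microarray matrix
#'
#' A gene enters a time point's list iff its broiler/layer mean intensity
#' ratio exceeds `fold` (or falls below 1/`fold`) AND an equal-variance
#' two-sample t-test on that time point's replicates gives p < `p_threshold`.
#' The union list pools the embryonic time points, deduplicated.
#'
#' @param mat linear-scale intensity matrix, genes x samples.
#' @param manifest sample manifest (sample_id, breed, timepoint, replicate).
#' @param timepoints time points to test (default the four embryonic stages).
#' @param fold fold-change gate (> fold or < 1/fold, strict).
#' @param p_threshold t-test cutoff.
#' @return an object of class `microarray_de`: per-time-point gene lists,
#'   `union_nonredundant`, and per-gene direction per time point.
#' @export
de_genes_microarray <- function(mat, manifest,
                                timepoints = c("E10", "E12", "E14", "E18"),
                                fold = 1.5, p_threshold = 0.05) {
  timepoints <- intersect(timepoints, unique(manifest$timepoint))
  per_tp <- list()
  directions <- list()
  for (tp in timepoints) {
    cols_b <- manifest$sample_id[manifest$timepoint == tp & manifest$breed == "broiler"]
    cols_l <- manifest$sample_id[manifest$timepoint == tp & manifest$breed == "layer"]
    if (length(cols_b) < 2 || length(cols_l) < 2) {
      stop("need >= 2 replicates per breed at ", tp)
    }
    b <- mat[, cols_b, drop = FALSE]
    l <- mat[, cols_l, drop = FALSE]
    mb <- rowMeans(b)
    ml <- rowMeans(l)
    ratio <- mb / ml
    pass_fold <- ratio > fold | ratio < 1 / fold
    pvals <- rep(1, nrow(mat))
    for (g in which(pass_fold)) {
      xb <- b[g, ]
      xl <- l[g, ]
      if (sd(xb) == 0 && sd(xl) == 0) {
        pvals[g] <- if (isTRUE(all.equal(mean(xb), mean(xl)))) 1 else 0
      } else {
        pvals[g] <- t.test(xb, xl, var.equal = TRUE)$p.value
      }
    }
    sel <- pass_fold & pvals < p_threshold
    genes <- rownames(mat)[sel]
    per_tp[[tp]] <- genes
    if (length(genes) > 0) {
      directions[[tp]] <- data.frame(
        gene_id = genes, timepoint = tp,
        direction = ifelse(mb[sel] > ml[sel], "broiler_up", "layer_up"),
        stringsAsFactors = FALSE
      )
    }
  }
  directions <- if (length(directions) > 0) {
    do.call(rbind, c(directions, list(make.row.names = FALSE)))
  } else {
    data.frame(gene_id = character(0), timepoint = character(0),
               direction = character(0))
  }
  out <- list(per_timepoint = per_tp,
              union_nonredundant = unique(unlist(per_tp, use.names = FALSE)),
              directions = directions)
  class(out) <- "microarray_de"
  out
}

#' Concordance rate between two sets of direction calls
#'
#' @param calls_a,calls_b named character vectors of `broiler_up`/`layer_up`
#'   calls over identical key sets.
#' @return list: `n_compared`, `n_agree`, `rate_percent` (one decimal).
#' @export
concordance_rate <- function(calls_a, calls_b) {
  if (!setequal(names(calls_a), names(calls_b)) ||
      length(calls_a) != length(calls_b)) {
    stop("direction maps must share an identical key set")
  }
  keys <- names(calls_a)
  n_agree <- sum(calls_a[keys] == calls_b[keys])
  list(n_compared = length(keys),
       n_agree = as.integer(n_agree),
       rate_percent = round_half_away(100 * n_agree / length(keys), 1))
}
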