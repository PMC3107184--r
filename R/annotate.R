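# Priority-cascade annotation. Categories are tried in a fixed, total order:
# chicken miRNA, chicken miRNA*, metazoan miRNA homolog, metazoan miRNA*
# homolog, snoRNA, snRNA, rRNA, tRNA, mRNA, repeat; a tag claimed by one
# step is invisible to all later steps. miRNA classes use the 20-25 nt /
# 5'-19-nt prefix rule; the remaining classes require a genomic locus fully
# contained in a feature interval on the feature's strand.

ANNOTATION_ORDER <- c("chicken_miRNA", "chicken_miRNA_star",
                      "metazoan_miRNA", "metazoan_miRNA_star",
                      "snoRNA", "snRNA", "rRNA", "tRNA", "mRNA", "repeat")

#' Prefix-rule match between a tag and a reference miRNA
#'
#' A tag is counted as a copy of a reference miRNA iff its length is 20-25 nt
#' and its 5' 19 nt equal the reference's 5' 19 nt; everything 3' of position
#' 19 is ignored, which tolerates the untemplated 3' additions common in
#' small RNA reads.
#'
#' @param tag_sequence character vector of tag sequences.
#' @param reference_sequence single reference mature/star sequence (>= 19 nt).
#' @return logical vector.
#' @export
match_mirna_prefix <- function(tag_sequence, reference_sequence) {
  if (nchar(reference_sequence) < 19L) {
    stop("reference sequence shorter than 19 nt; catalog invalid")
  }
  len <- nchar(tag_sequence)
  len >= 20L & len <= 25L &
    substr(tag_sequence, 1L, 19L) == substr(reference_sequence, 1L, 19L)
}

# prefix lookup table: 19-nt prefix -> collapsed reference ids
prefix_index <- function(ref_df) {
  if (nrow(ref_df) == 0) return(character(0))
  short <- nchar(ref_df$sequence) < 19L
  if (any(short)) {
    stop("catalog sequences shorter than 19 nt: ",
         paste(ref_df$id[short], collapse = ", "))
  }
  tapply(ref_df$id, substr(ref_df$sequence, 1L, 19L),
         function(x) paste(sort(x), collapse = ","))
}

#' Annotate unique tags through the fixed priority cascade
#'
#' @param tags tag data frame (from [collapse_reads()], with `n_loci` if
#'   mapped); unmapped tags can still be claimed by the sequence-based miRNA
#'   classes but never by interval classes.
#' @param catalog a `ref_catalog` (miRNA/star/homolog sequence sets plus
#'   interval tracks with a `category` column).
#' @param loci loci data frame from [map_exact()] (may be `NULL` when no tag
#'   is mapped).
#' @return list with `assignments` (tag sequence, category, matched_ids) and
#'   `category_totals` (reads per category per library, including
#'   `unannotated`; columns sum to library totals).
#' @export
annotate_cascade <- function(tags, catalog, loci = NULL) {
  n <- nrow(tags)
  category <- rep("unannotated", n)
  matched <- rep(NA_character_, n)
  len_ok <- nchar(tags$sequence) >= 20L & nchar(tags$sequence) <= 25L
  prefix <- substr(tags$sequence, 1L, 19L)

  seq_classes <- list(
    chicken_miRNA = catalog$mirnas,
    chicken_miRNA_star = catalog$stars,
    metazoan_miRNA = catalog$metazoan_mirnas,
    metazoan_miRNA_star = catalog$metazoan_stars
  )

  tag_gr <- NULL
  if (!is.null(loci) && nrow(loci) > 0) {
    tag_gr <- GenomicRanges::GRanges(
      loci$chrom, IRanges::IRanges(loci$start + 1L, loci$end),
      strand = loci$strand, tag = loci$tag)
  }
  tracks <- catalog$tracks

  for (cls in ANNOTATION_ORDER) {
    open <- category == "unannotated"
    if (!any(open)) break
    if (cls %in% names(seq_classes)) {
      ref <- seq_classes[[cls]]
      if (is.null(ref) || nrow(ref) == 0) next
      idx <- prefix_index(ref)
      hit <- open & len_ok & prefix %in% names(idx)
      if (any(hit)) {
        category[hit] <- cls
        matched[hit] <- idx[prefix[hit]]
        multi <- hit & grepl(",", matched)
        if (any(multi)) {
          message(sum(multi), " tags match multiple ", cls,
                  " references by 19-nt prefix; credited to every match")
        }
      }
    } else {
      feats <- tracks[tracks$category == cls]
      if (length(feats) == 0) {
        warning("no ", cls, " track in catalog; class skipped")
        next
      }
      if (is.null(tag_gr)) next
      ov <- GenomicRanges::findOverlaps(tag_gr, feats, type = "within")
      hit_tags <- unique(tag_gr$tag[S4Vectors::queryHits(ov)])
      hit <- open & seq_len(n) %in% hit_tags
      category[hit] <- cls
    }
  }

  libs <- setdiff(names(tags), c("sequence", "n_loci"))
  totals <- sapply(libs, function(lib) {
    tapply(tags[[lib]],
           factor(category, levels = c(ANNOTATION_ORDER, "unannotated")),
           sum, default = 0L)
  })

  list(
    assignments = data.frame(sequence = tags$sequence, category = category,
                             matched_ids = matched, stringsAsFactors = FALSE),
    category_totals = totals
  )
}

#' Build the per-miRNA expression table
#'
#' Sums counts of every tag credited to each chicken miRNA (a tag whose
#' 19-nt prefix matches several references is credited to each). The
#' broiler/layer ratio is reported unrounded (`ratio`) and in the table's
#' display rounding (`bl_display`, see [ratio_display()]); it is `NA` when
#' the layer count is zero.
#'
#' @param annotation result of [annotate_cascade()].
#' @param tags the tag data frame the cascade was run on.
#' @param layer,broiler names of the two library count columns.
#' @param category which annotation class to tabulate (default chicken
#'   miRNA; use `"chicken_miRNA_star"` for the star table).
#' @return data frame (mirna_id, layer, broiler, ratio, bl_display), sorted
#'   by pooled count.
#' @export
build_expression_table <- function(annotation, tags, layer = "layer",
                                   broiler = "broiler",
                                   category = "chicken_miRNA") {
  a <- annotation$assignments
  keep <- a$category == category & !is.na(a$matched_ids)
  if (!any(keep)) {
    return(data.frame(mirna_id = character(0), layer = integer(0),
                      broiler = integer(0), ratio = numeric(0),
                      bl_display = numeric(0)))
  }
  ids <- strsplit(a$matched_ids[keep], ",", fixed = TRUE)
  reps <- lengths(ids)
  idx <- which(keep)
  long <- data.frame(
    mirna_id = unlist(ids),
    layer = rep(tags[[layer]][idx], reps),
    broiler = rep(tags[[broiler]][idx], reps),
    stringsAsFactors = FALSE
  )
  tab <- aggregate(cbind(layer, broiler) ~ mirna_id, long, sum)
  tab$ratio <- ifelse(tab$layer == 0, NA_real_, tab$broiler / tab$layer)
  tab$bl_display <- ratio_display(tab$ratio)
  tab[order(-(tab$layer + tab$broiler)), , drop = FALSE]
}

#' Compare read counts between miRNA and miRNA* arms
#'
#' @param mature_table,star_table expression tables from
#'   [build_expression_table()] for the mature and star classes; star ids
#'   are expected as `<mirna_id>*`.
#' @param similar_fold maximum pooled-count ratio for the "similar levels"
#'   flag (the published analysis states no cutoff; 4 reproduces its
#'   qualitative miR-199 / miR-1329 calls).
#' @return data frame per locus with mature/star counts per library,
#'   `star_dominant` (mature silent, star observed) and `similar_levels`
#'   flags. Loci with no reads on either arm are excluded.
#' @export
arm_comparison <- function(mature_table, star_table, similar_fold = 4) {
  star_table$mirna_id <- sub("\\*$", "", star_table$mirna_id)
  ids <- union(mature_table$mirna_id, star_table$mirna_id)
  mi <- match(ids, mature_table$mirna_id)
  si <- match(ids, star_table$mirna_id)
  g0 <- function(x) ifelse(is.na(x), 0L, x)
  out <- data.frame(
    mirna_id = ids,
    mature_layer = g0(mature_table$layer[mi]),
    mature_broiler = g0(mature_table$broiler[mi]),
    star_layer = g0(star_table$layer[si]),
    star_broiler = g0(star_table$broiler[si]),
    stringsAsFactors = FALSE
  )
  m_sum <- out$mature_layer + out$mature_broiler
  s_sum <- out$star_layer + out$star_broiler
  out <- out[m_sum + s_sum > 0, , drop = FALSE]
  m_sum <- out$mature_layer + out$mature_broiler
  s_sum <- out$star_layer + out$star_broiler
  out$star_dominant <- m_sum == 0L & s_sum > 0L
  out$similar_levels <- m_sum > 0L & s_sum > 0L &
    pmax(m_sum, s_sum) / pmin(m_sum, s_sum) <= similar_fold
  rownames(out) <- NULL
  out
}

#' Profile the isomiR stack of one hairpin
#'
#' Aligns every tag that occurs exactly within the hairpin and reports its
#' 5'/3' offsets against the catalog mature interval. The most abundant row
#' is chosen by total count with ties broken by smaller |5' offset|, then
#' smaller |3' offset|, then lexicographic sequence; `nonref_dominant` is set
#' when that row is not the reference isoform.
#'
#' @param tags tag data frame.
#' @param hairpin one row of a catalog `hairpins` data frame (fields
#'   `hairpin_id`, `sequence`, `mature_start`, `mature_end`).
#' @return an object of class `isomir_stack` (data frame of aligned rows
#'   plus attributes), or `NULL` when no tag aligns.
#' @export
isomir_profile <- function(tags, hairpin) {
  libs <- setdiff(names(tags), c("sequence", "n_loci"))
  pos <- vapply(tags$sequence, function(s) {
    m <- gregexpr(s, hairpin$sequence, fixed = TRUE)[[1]]
    if (m[1] == -1L) NA_integer_ else {
      if (length(m) > 1L) {
        message("tag occurs ", length(m), "x in ", hairpin$hairpin_id,
                "; leftmost occurrence used")
      }
      as.integer(m[1])
    }
  }, integer(1), USE.NAMES = FALSE)
  keep <- !is.na(pos)
  if (!any(keep)) return(NULL)
  start <- pos[keep]
  seqs <- tags$sequence[keep]
  end <- start + nchar(seqs) - 1L
  stack <- data.frame(
    offset_5p = start - hairpin$mature_start,
    offset_3p = end - hairpin$mature_end,
    sequence = seqs,
    stringsAsFactors = FALSE
  )
  for (lib in libs) stack[[lib]] <- tags[[lib]][keep]
  stack$total <- rowSums(stack[, libs, drop = FALSE])
  stack <- stack[order(stack$offset_5p, stack$offset_3p, stack$sequence), ]
  rownames(stack) <- NULL
  stack$is_reference <- stack$offset_5p == 0L & stack$offset_3p == 0L

  ord <- order(-stack$total, abs(stack$offset_5p), abs(stack$offset_3p),
               stack$sequence)
  top <- ord[1]
  attr(stack, "hairpin_id") <- hairpin$hairpin_id
  attr(stack, "most_abundant") <- top
  attr(stack, "nonref_dominant") <- !stack$is_reference[top]
  class(stack) <- c("isomir_stack", "data.frame")
  stack
}

#' @export
print.isomir_stack <- function(x, ...) {
  cat("isomiR stack for", attr(x, "hairpin_id"),
      if (attr(x, "nonref_dominant")) "(dominant isoform differs from reference)\n" else "\n")
  libs <- setdiff(names(x), c("offset_5p", "offset_3p", "sequence", "total",
                              "is_reference"))
  pad <- max(0L, -min(x$offset_5p))
  for (i in seq_len(nrow(x))) {
    marker <- if (x$is_reference[i]) "*" else " "
    cat(sprintf("%s%s%s  %s\n",
                strrep(" ", pad + x$offset_5p[i]), as_rna(x$sequence[i]),
                marker,
                paste(sprintf("%s=%d", libs, unlist(x[i, libs])), collapse = " ")))
  }
  invisible(x)
}
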