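#' Group circRNAs into alternative-circularization loci
#'
#' Genic circRNAs (exonic or intronic) group by their parent gene; intergenic
#' circRNAs group by connected components of genomic-span overlap (>= 1 bp,
#' same chromosome). Every circRNA lands in exactly one locus. Loci with two
#' or more members are the alternative-circularization loci. The locus class
#' is `exon`, `intron` or `intergenic_region` when all members share that
#' origin, and `mixture` otherwise.
#'
#' @param circs Circ table.
#' @param origin_calls Output of [classify_origin()].
#' @return List with `loci` (data.frame: `locus_id`, `locus_class`,
#'   `isoform_count`, `members` comma-separated) and `membership`
#'   (data.frame: `circ_id`, `locus_id`).
#' @export
group_loci <- function(circs, origin_calls) {
  oc <- origin_calls
  idx <- match(oc$circ_id, circs$circ_id)
  locus <- rep(NA_character_, nrow(oc))

  genic <- oc$origin %in% c("exonic", "intronic")
  locus[genic] <- paste0("gene:", oc$parent_gene[genic])

  inter <- which(!genic)
  if (length(inter)) {
    df <- data.frame(i = inter, chrom = circs$chrom[idx[inter]],
                     start = circs$start[idx[inter]],
                     end = circs$end[idx[inter]], stringsAsFactors = FALSE)
    comp <- 0L
    for (ch in unique(df$chrom)) {
      d <- df[df$chrom == ch, ]
      d <- d[order(d$start, d$end), ]
      cur_end <- -Inf
      for (k in seq_len(nrow(d))) {
        if (d$start[k] > cur_end) comp <- comp + 1L
        cur_end <- max(cur_end, d$end[k])
        locus[d$i[k]] <- sprintf("intergenic:%s:%d", ch, comp)
      }
    }
  }

  origin_class <- c(exonic = "exon", intronic = "intron",
                    intergenic = "intergenic_region")
  loci <- lapply(split(seq_len(nrow(oc)), locus), function(ii) {
    cls <- unique(origin_class[oc$origin[ii]])
    data.frame(locus_id = locus[ii[1]],
               locus_class = if (length(cls) == 1) cls else "mixture",
               isoform_count = length(ii),
               members = paste(oc$circ_id[ii], collapse = ","),
               stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, loci)
  rownames(loci) <- NULL
  membership <- data.frame(circ_id = oc$circ_id, locus_id = locus,
                           stringsAsFactors = FALSE)
  list(loci = loci, membership = membership)
}

#' Histogram of isoforms per alternative-circularization locus
#'
#' Counts loci by isoform number, restricted to loci producing at least two
#' distinct circRNA isoforms.
#'
#' @param loci Locus table from [group_loci()].
#' @return data.frame with `isoform_count`, `n_loci`.
#' @export
isoform_histogram <- function(loci) {
  multi <- loci[loci$isoform_count >= 2, ]
  if (nrow(multi) == 0) {
    return(data.frame(isoform_count = integer(), n_loci = integer()))
  }
  tab <- table(multi$isoform_count)
  data.frame(isoform_count = as.integer(names(tab)),
             n_loci = as.integer(tab))
}

#' Dominantly expressed isoform per locus
#'
#' For each multi-isoform locus, finds the member whose expression (mean
#' SRPBM over all samples) is at least twofold that of *every* other member;
#' exactly twofold qualifies. A zero-expression comparator is always
#' satisfied by a positively expressed candidate; a locus whose members are
#' all zero has no dominant isoform. Singleton loci are excluded.
#'
#' @param grouping Output of [group_loci()].
#' @param srpbm_matrix SRPBM matrix (circ_id x sample).
#' @param min_fold Dominance fold threshold (default 2).
#' @return data.frame with `locus_id`, `isoform_count`, `dominant`
#'   (circ_id or `NA`), `dominance_ratio` (top / runner-up mean SRPBM,
#'   `Inf` when the runner-up is zero).
#' @export
dominant_isoforms <- function(grouping, srpbm_matrix, min_fold = 2) {
  loci <- grouping$loci[grouping$loci$isoform_count >= 2, , drop = FALSE]
  expr <- rowMeans(srpbm_matrix)
  rows <- lapply(seq_len(nrow(loci)), function(k) {
    members <- strsplit(loci$members[k], ",", fixed = TRUE)[[1]]
    e <- expr[members]
    e[is.na(e)] <- 0
    top <- which.max(e)
    others <- e[-top]
    dominant <- NA_character_
    ratio <- NA_real_
    if (e[top] > 0 && all(e[top] >= min_fold * others)) {
      dominant <- members[top]
    }
    if (e[top] > 0) {
      ratio <- if (max(others) == 0) Inf else e[top] / max(others)
    }
    data.frame(locus_id = loci$locus_id[k],
               isoform_count = loci$isoform_count[k],
               dominant = dominant, dominance_ratio = ratio,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_id = character(), isoform_count = integer(),
               dominant = character(), dominance_ratio = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
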