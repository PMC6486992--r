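.canonical_pairs <- c("GT/AG", "CT/AC")

# fetch [start..end] on the plus strand, padding out-of-range positions with N
.fetch_padded <- function(chrom_seq, chrom_len, start, end) {
  lo <- max(1L, start)
  hi <- min(chrom_len, end)
  core <- if (lo <= hi) {
    toupper(as.character(Biostrings::subseq(chrom_seq, lo, hi)))
  } else ""
  paste0(strrep("N", max(0L, lo - start)), core,
         strrep("N", max(0L, end - hi)))
}

#' Extract back-splice splice-signal dinucleotides
#'
#' For each circRNA the donor dinucleotide is read on the plus strand
#' immediately 3' of the back-splice end (`genome[end+1 .. end+2]`) and the
#' acceptor immediately 5' of the start (`genome[start-2 .. start-1]`). The
#' pair label is `donor/acceptor`; positions beyond the chromosome yield `N`
#' bases. No strand inference is attempted: `GT/AG` and its minus-strand
#' equivalent `CT/AC` are both counted as canonical.
#'
#' @param circs Circ table.
#' @param genome [Biostrings::DNAStringSet].
#' @return data.frame with `circ_id`, `donor`, `acceptor`, `pair_label`,
#'   `canonical`.
#' @export
extract_splice_signals <- function(circs, genome) {
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  donor <- character(nrow(circs))
  acceptor <- character(nrow(circs))
  for (i in seq_len(nrow(circs))) {
    ch <- circs$chrom[i]
    if (!ch %in% names(genome)) {
      donor[i] <- "NN"; acceptor[i] <- "NN"; next
    }
    donor[i] <- .fetch_padded(genome[[ch]], lens[[ch]],
                              circs$end[i] + 1L, circs$end[i] + 2L)
    acceptor[i] <- .fetch_padded(genome[[ch]], lens[[ch]],
                                 circs$start[i] - 2L, circs$start[i] - 1L)
  }
  pair <- paste0(donor, "/", acceptor)
  data.frame(circ_id = circs$circ_id, donor = donor, acceptor = acceptor,
             pair_label = pair, canonical = pair %in% .canonical_pairs,
             stringsAsFactors = FALSE)
}

#' Tally splice-signal pairs
#'
#' Counts per pair label (descending), the canonical count and percentage
#' (reported to 1 decimal, matching the field's reporting convention), and a
#' top-k view in which the remainder is collapsed into `Others`. Labels
#' containing `N` are never individually listed and fall under `Others`.
#'
#' @param signals Output of [extract_splice_signals()].
#' @param top_k Number of pair labels shown individually (default 10).
#' @return List with `table` (label, count, percent, canonical),
#'   `canonical_count`, `canonical_percent` (1 decimal), `top` (top-k plus
#'   an `Others` row), `n`.
#' @export
tally_signals <- function(signals, top_k = 10) {
  n <- nrow(signals)
  tab <- sort(table(signals$pair_label), decreasing = TRUE)
  df <- data.frame(pair_label = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df$percent <- pct(df$count, n)
  df$canonical <- df$pair_label %in% .canonical_pairs
  canonical_count <- sum(signals$canonical)
  has_n <- grepl("N", df$pair_label, fixed = TRUE)
  listed <- df[!has_n, , drop = FALSE]
  k <- min(top_k, nrow(listed))
  top <- listed[seq_len(k), , drop = FALSE]
  others <- n - sum(top$count)
  if (others > 0) {
    top <- rbind(top, data.frame(pair_label = "Others", count = others,
                                 percent = pct(others, n), canonical = FALSE,
                                 stringsAsFactors = FALSE))
  }
  rownames(top) <- NULL
  list(table = df, canonical_count = canonical_count,
       canonical_percent = pct(canonical_count, n, digits = 1),
       top = top, n = n)
}

#' Position frequency matrix around back-splice boundaries
#'
#' Per-position base frequencies over all circRNAs, spanning
#' `[start - half_window .. start + half_window - 1]` at the acceptor
#' boundary and `[end - half_window + 1 .. end + half_window]` at the donor
#' boundary (plus strand). Each column sums to 1 over the counted (non-`N`)
#' bases; `N`s are excluded from the denominator. Suitable as direct input
#' for sequence-logo rendering.
#'
#' @param circs Circ table.
#' @param genome [Biostrings::DNAStringSet].
#' @param half_window Half window in nt (default 5).
#' @return 4 x (4*half_window) matrix, rows `A,C,G,T`; columns named
#'   `start-5 ... start+4, end-4 ... end+5` style.
#' @export
boundary_pfm <- function(circs, genome, half_window = 5) {
  stopifnot(half_window >= 1)
  hw <- as.integer(half_window)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  width <- 4L * hw
  counts <- matrix(0, nrow = 4, ncol = width,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_len(nrow(circs))) {
    ch <- circs$chrom[i]
    if (!ch %in% names(genome)) next
    s_seq <- .fetch_padded(genome[[ch]], lens[[ch]],
                           circs$start[i] - hw, circs$start[i] + hw - 1L)
    e_seq <- .fetch_padded(genome[[ch]], lens[[ch]],
                           circs$end[i] - hw + 1L, circs$end[i] + hw)
    chars <- strsplit(paste0(s_seq, e_seq), "", fixed = TRUE)[[1]]
    for (j in seq_len(width)) {
      b <- chars[j]
      if (b %in% rownames(counts)) counts[b, j] <- counts[b, j] + 1
    }
  }
  colsum <- colSums(counts)
  freq <- sweep(counts, 2, pmax(colsum, 1), "/")
  rel <- c(sprintf("start%+d", c(-(hw:1), 0:(hw - 1))),
           sprintf("end%+d", c(-((hw - 1):0), 1:hw)))
  colnames(freq) <- rel
  freq
}
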