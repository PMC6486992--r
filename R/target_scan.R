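.check_nucs <- function(s, what) {
  if (grepl("[^ACGTU]", toupper(s))) {
    stop(what, " contains non-nucleotide symbols")
  }
}

.wc_pair <- function(m, t) {
  (m == "A" & t == "T") | (m == "C" & t == "G") |
    (m == "G" & t == "C") | (m == "T" & t == "A")
}

.wobble_pair <- function(m, t) {
  # G:U wobble: miRNA G with target U(T), or miRNA U(T) with target G
  (m == "G" & t == "T") | (m == "T" & t == "G")
}

#' Score a miRNA complementarity site
#'
#' Plant-style penalty scoring of a miRNA against a candidate target window.
#' Position `i` of the miRNA (counted from its 5' end) pairs antiparallel
#' with window position `L - i + 1`. Penalties: mismatch 1.0, G:U wobble
#' 0.5, gap 2.0 per unpaired nucleotide; penalties at miRNA positions 2-13
#' (the seed-proximal region) are doubled. A perfect complement scores 0;
#' lower scores are better. Window length may differ from the miRNA length
#' by at most 4 nt; the length difference is charged as gaps (miRNA-side
#' overhangs at their positions with seed doubling, target-side bulges
#' undoubled).
#'
#' `U` is accepted as a synonym of `T` on either sequence.
#'
#' @param mirna_seq Mature miRNA sequence, 5'->3' (18-24 nt).
#' @param target_window Target subsequence, 5'->3'.
#' @return List with `score` and `alignment` (one symbol per miRNA
#'   position: `|` Watson-Crick, `o` wobble, `x` mismatch, `-` gap).
#' @export
score_site <- function(mirna_seq, target_window) {
  .check_nucs(mirna_seq, "miRNA sequence")
  .check_nucs(target_window, "target window")
  m <- chartr("U", "T", toupper(mirna_seq))
  t <- chartr("U", "T", toupper(target_window))
  lm <- nchar(m)
  lt <- nchar(t)
  if (abs(lm - lt) > 4) stop("window length differs from miRNA by > 4 nt")
  mc <- strsplit(m, "", fixed = TRUE)[[1]]
  tc <- strsplit(t, "", fixed = TRUE)[[1]]
  score <- 0
  sym <- character(lm)
  for (i in seq_len(lm)) {
    seed <- i >= 2 && i <= 13
    j <- lt - i + 1
    if (j < 1) {
      score <- score + 2.0 * (if (seed) 2 else 1)
      sym[i] <- "-"
    } else if (.wc_pair(mc[i], tc[j])) {
      sym[i] <- "|"
    } else if (.wobble_pair(mc[i], tc[j])) {
      score <- score + 0.5 * (if (seed) 2 else 1)
      sym[i] <- "o"
    } else {
      score <- score + 1.0 * (if (seed) 2 else 1)
      sym[i] <- "x"
    }
  }
  if (lt > lm) score <- score + 2.0 * (lt - lm)  # target-side bulges
  list(score = score, alignment = paste(sym, collapse = ""))
}

#' Scan a target sequence for miRNA complementarity sites
#'
#' Slides a window of the miRNA's length along the target, scores every
#' window with [score_site()], and reports non-overlapping local-minimum
#' hits with score at most `cutoff` (best-scoring windows claimed first;
#' overlapping candidates suppressed). A target shorter than the miRNA
#' yields no hits.
#'
#' @param mirna_seq Mature miRNA sequence, 5'->3'.
#' @param target_seq Target sequence, 5'->3'.
#' @param cutoff Maximum penalty score (default 4).
#' @return data.frame with `target_start`, `target_end`, `score`,
#'   `alignment`.
#' @export
scan_target <- function(mirna_seq, target_seq, cutoff = 4) {
  empty <- data.frame(target_start = integer(), target_end = integer(),
                      score = numeric(), alignment = character(),
                      stringsAsFactors = FALSE)
  lm <- nchar(mirna_seq)
  lt <- nchar(target_seq)
  if (lt < lm) return(empty)
  target_seq <- toupper(target_seq)
  starts <- seq_len(lt - lm + 1)
  scored <- lapply(starts, function(s) {
    w <- substring(target_seq, s, s + lm - 1)
    if (grepl("N", w, fixed = TRUE)) return(NULL)
    sc <- score_site(mirna_seq, w)
    data.frame(target_start = s, target_end = s + lm - 1L,
               score = sc$score, alignment = sc$alignment,
               stringsAsFactors = FALSE)
  })
  scored <- do.call(rbind, scored[!vapply(scored, is.null, logical(1))])
  if (is.null(scored)) return(empty)
  cand <- scored[scored$score <= cutoff, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  cand <- cand[order(cand$score, cand$target_start), , drop = FALSE]
  taken <- logical(0)
  keep <- integer(0)
  occupied <- rep(FALSE, lt)
  for (r in seq_len(nrow(cand))) {
    span <- cand$target_start[r]:cand$target_end[r]
    if (!any(occupied[span])) {
      keep <- c(keep, r)
      occupied[span] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$target_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Back-splice-joined circRNA sequence
#'
#' Sequence of the mature circle read on the plus strand: for exonic
#' circRNAs with resolved parent, the concatenation of the circularized
#' exon segments (genomic order, introns removed); otherwise the genomic
#' span. To make junction-spanning sites detectable when scanning the
#' circle with a linear scanner, the first `wrap` nucleotides are appended
#' once at the end (use `wrap = miRNA length - 1`; `wrap = 0` disables).
#'
#' @param circ One-row circ table entry (or a row index into `circs`).
#' @param genome [Biostrings::DNAStringSet].
#' @param origin_call Matching row of [classify_origin()] output, or `NULL`.
#' @param genes Exon table (needed for exonic circs).
#' @param wrap Number of junction-wrap nucleotides (default 0).
#' @return Nucleotide string.
#' @export
circ_sequence <- function(circ, genome, origin_call = NULL, genes = NULL,
                          wrap = 0) {
  exonic <- !is.null(origin_call) && origin_call$origin == "exonic" &&
    !is.null(genes)
  if (exonic) {
    g <- genes[genes$gene_id == origin_call$parent_gene, ]
    hit <- g$start <= circ$end & g$end >= circ$start
    gh <- g[hit, , drop = FALSE]
    gh <- gh[order(gh$start), , drop = FALSE]
    segs <- vapply(seq_len(nrow(gh)), function(k) {
      fetch_sequence(genome, circ$chrom,
                     max(gh$start[k], circ$start),
                     min(gh$end[k], circ$end))
    }, character(1))
    s <- paste(segs, collapse = "")
  } else {
    s <- fetch_sequence(genome, circ$chrom, circ$start, circ$end)
  }
  if (wrap > 0) {
    w <- min(wrap, nchar(s))
    s <- paste0(s, substring(s, 1, w))
  }
  s
}

#' Predict miRNA hits over a set of target sequences
#'
#' Convenience wrapper running [scan_target()] for every miRNA/target
#' combination.
#'
#' @param mirnas Named character vector (or [Biostrings::DNAStringSet]) of
#'   mature miRNA sequences.
#' @param targets Named character vector of target sequences.
#' @param cutoff Penalty cut-off (default 4).
#' @return data.frame with `query_mirna`, `target_id`, `target_start`,
#'   `target_end`, `score`, `alignment`.
#' @export
predict_targets <- function(mirnas, targets, cutoff = 4) {
  if (methods::is(mirnas, "DNAStringSet") || methods::is(mirnas, "RNAStringSet")) {
    mirnas <- stats::setNames(as.character(mirnas), names(mirnas))
  }
  rows <- list()
  for (mi in names(mirnas)) {
    for (tg in names(targets)) {
      h <- scan_target(mirnas[[mi]], targets[[tg]], cutoff = cutoff)
      if (nrow(h)) {
        h$query_mirna <- mi
        h$target_id <- tg
        rows[[length(rows) + 1L]] <- h
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(query_mirna = character(), target_id = character(),
                      target_start = integer(), target_end = integer(),
                      score = numeric(), alignment = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[, c("query_mirna", "target_id", "target_start", "target_end",
          "score", "alignment")]
}

#' Assemble the circRNA-miRNA-mRNA edge table
#'
#' Builds the two-layer interaction network: circ-miRNA edges from the
#' circRNA hit table restricted to differentially expressed circRNAs, and
#' miRNA-mRNA edges from the mRNA hit table restricted to miRNAs retained
#' on the circ side. miRNAs with no mRNA hits still contribute their
#' circ-miRNA edges.
#'
#' @param circ_hits Hit table from [predict_targets()] with circRNA targets
#'   (`query_mirna`, `target_id`).
#' @param mrna_hits Hit table with mRNA targets.
#' @param de_circs Character vector of differentially expressed circ ids.
#' @return data.frame with `source`, `target`, `edge_type` (one of
#'   `circ-miRNA`, `miRNA-mRNA`).
#' @export
build_network <- function(circ_hits, mrna_hits, de_circs) {
  ce <- unique(circ_hits[circ_hits$target_id %in% de_circs,
                         c("target_id", "query_mirna")])
  circ_edges <- data.frame(source = ce$target_id, target = ce$query_mirna,
                           edge_type = rep("circ-miRNA", nrow(ce)),
                           stringsAsFactors = FALSE)
  retained <- unique(ce$query_mirna)
  me <- unique(mrna_hits[mrna_hits$query_mirna %in% retained,
                         c("query_mirna", "target_id")])
  mrna_edges <- data.frame(source = me$query_mirna, target = me$target_id,
                           edge_type = rep("miRNA-mRNA", nrow(me)),
                           stringsAsFactors = FALSE)
  out <- rbind(circ_edges, mrna_edges)
  rownames(out) <- NULL
  out
}
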