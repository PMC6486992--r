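#' Find reverse-complementary sequence pairs between two flanks
#'
#' Reports all maximal exact matches in which a substring of `up_seq` equals
#' the reverse complement of a substring of `down_seq`, with length at least
#' `min_len`. Matching is exact and ungapped; `N` never matches anything
#' (including another `N`). Maximality means a match cannot be extended on
#' either side while preserving equality, so sub-matches of a longer match
#' at the same alignment offset are suppressed and counts are stable.
#'
#' Implementation: seed-and-extend over a k-mer index of the
#' reverse-complemented downstream sequence, `k = min(min_len, 12)`, with
#' per-diagonal deduplication, then a containment filter.
#'
#' @param up_seq Upstream flank sequence (plus strand, 5'->3').
#' @param down_seq Downstream flank sequence (plus strand, 5'->3').
#' @param min_len Minimum match length (default 18).
#' @return data.frame with `up_start`, `up_end`, `down_start`, `down_end`
#'   (1-based positions within each flank), `length`.
#' @export
find_complementary <- function(up_seq, down_seq, min_len = 18) {
  stopifnot(min_len >= 1)
  empty <- data.frame(up_start = integer(), up_end = integer(),
                      down_start = integer(), down_end = integer(),
                      length = integer())
  up_seq <- toupper(up_seq)
  down_seq <- toupper(down_seq)
  n_up <- nchar(up_seq)
  n_down <- nchar(down_seq)
  if (n_up < min_len || n_down < min_len) return(empty)
  rd <- revcomp(down_seq)
  k <- min(min_len, 12L)

  up_chars <- strsplit(up_seq, "", fixed = TRUE)[[1]]
  rd_chars <- strsplit(rd, "", fixed = TRUE)[[1]]
  # N never matches: mask it to distinct sentinels on the two sides
  up_cmp <- ifelse(up_chars == "N", "!", up_chars)
  rd_cmp <- ifelse(rd_chars == "N", "?", rd_chars)

  up_kmers <- substring(up_seq, 1:(n_up - k + 1), k:n_up)
  rd_kmers <- substring(rd, 1:(n_down - k + 1), k:n_down)
  has_n_up <- grepl("N", up_kmers, fixed = TRUE)
  has_n_rd <- grepl("N", rd_kmers, fixed = TRUE)
  rd_index <- list2env(split(which(!has_n_rd), rd_kmers[!has_n_rd]),
                       hash = TRUE, parent = emptyenv())

  # per-diagonal extent already covered, to skip redundant seeds
  covered <- new.env(hash = TRUE, parent = emptyenv())
  res <- list()
  for (i in which(!has_n_up)) {
    hits <- get0(up_kmers[i], envir = rd_index, ifnotfound = NULL)
    if (is.null(hits)) next
    for (j in hits) {
      d <- as.character(i - j)
      cov <- covered[[d]]
      if (!is.null(cov) && i <= cov) next
      # extend left
      i0 <- i; j0 <- j
      while (i0 > 1 && j0 > 1 && up_cmp[i0 - 1] == rd_cmp[j0 - 1]) {
        i0 <- i0 - 1L; j0 <- j0 - 1L
      }
      # extend right
      i1 <- i + k - 1L; j1 <- j + k - 1L
      while (i1 < n_up && j1 < n_down && up_cmp[i1 + 1] == rd_cmp[j1 + 1]) {
        i1 <- i1 + 1L; j1 <- j1 + 1L
      }
      covered[[d]] <- i1
      len <- i1 - i0 + 1L
      if (len >= min_len) {
        res[[length(res) + 1L]] <- c(i0, i1, j0, j1, len)
      }
    }
  }
  if (!length(res)) return(empty)
  m <- do.call(rbind, res)
  m <- unique(m)
  out <- data.frame(up_start = m[, 1], up_end = m[, 2],
                    # rd position j corresponds to down position n_down-j+1
                    down_start = n_down - m[, 4] + 1L,
                    down_end = n_down - m[, 3] + 1L,
                    length = m[, 5])
  out <- out[order(out$up_start, out$up_end, out$down_start, out$down_end), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# fetch a flank window clamped to the chromosome, then truncated at N runs
# (keeping the part adjacent to the circ boundary); returns the sequence and
# its genomic start
.flank_window <- function(chrom_seq, chrom_len, from, to, side) {
  lo <- max(1L, from)
  hi <- min(chrom_len, to)
  if (lo > hi) return(list(seq = "", start = NA_integer_))
  s <- toupper(as.character(Biostrings::subseq(chrom_seq, lo, hi)))
  # truncate at spacer-style N runs (>= 5 N) so windows never span merged
  # scaffold boundaries
  runs <- gregexpr("N{5,}", s)[[1]]
  if (runs[1] != -1) {
    if (side == "up") {
      # keep suffix after the last N run
      last <- runs[length(runs)] + attr(runs, "match.length")[length(runs)]
      lo <- lo + last - 1L
      s <- if (last <= nchar(s)) substring(s, last) else ""
    } else {
      first <- runs[1]
      s <- substring(s, 1, first - 1)
    }
  }
  list(seq = s, start = lo)
}

#' Scan circRNA flanking windows for reverse-complementary pairs
#'
#' For each circRNA, the upstream window `[start - window .. start - 1]` and
#' downstream window `[end + 1 .. end + window]` are extracted (clamped at
#' chromosome edges; truncated at runs of `N`, so windows never reach across
#' merged-scaffold spacers) and searched with [find_complementary()].
#'
#' @param circs Circ table.
#' @param genome [Biostrings::DNAStringSet].
#' @param window Flank window size in bp (default 1000).
#' @param min_len Minimum complementary length (default 18).
#' @return List with `per_circ` (`circ_id`, `has_complementary_flanks`,
#'   `n_matches`, `max_length`), `matches` (per-match table with window
#'   coordinates), `count`, `percent`.
#' @export
scan_flanks <- function(circs, genome, window = 1000, min_len = 18) {
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  per <- vector("list", nrow(circs))
  match_rows <- list()
  for (i in seq_len(nrow(circs))) {
    ch <- circs$chrom[i]
    nm <- 0L; mx <- NA_integer_
    if (ch %in% names(genome)) {
      up <- .flank_window(genome[[ch]], lens[[ch]],
                          circs$start[i] - as.integer(window),
                          circs$start[i] - 1L, side = "up")
      down <- .flank_window(genome[[ch]], lens[[ch]],
                            circs$end[i] + 1L,
                            circs$end[i] + as.integer(window), side = "down")
      if (nchar(up$seq) >= min_len && nchar(down$seq) >= min_len) {
        m <- find_complementary(up$seq, down$seq, min_len = min_len)
        nm <- nrow(m)
        if (nm > 0) {
          mx <- max(m$length)
          m$circ_id <- circs$circ_id[i]
          match_rows[[length(match_rows) + 1L]] <- m
        }
      }
    }
    per[[i]] <- data.frame(circ_id = circs$circ_id[i],
                           has_complementary_flanks = nm > 0,
                           n_matches = nm, max_length = mx,
                           stringsAsFactors = FALSE)
  }
  per_circ <- do.call(rbind, per)
  if (is.null(per_circ)) {
    per_circ <- data.frame(circ_id = character(),
                           has_complementary_flanks = logical(),
                           n_matches = integer(), max_length = integer())
  }
  matches <- if (length(match_rows)) do.call(rbind, match_rows) else
    data.frame(up_start = integer(), up_end = integer(),
               down_start = integer(), down_end = integer(),
               length = integer(), circ_id = character())
  cnt <- sum(per_circ$has_complementary_flanks)
  list(per_circ = per_circ, matches = matches, count = cnt,
       percent = if (nrow(per_circ)) pct(cnt, nrow(per_circ)) else NA_real_)
}

#' MITE overlap of circRNA flanking windows
#'
#' A circRNA is flagged when its upstream window *and* its downstream window
#' each overlap at least one MITE interval by >= 1 bp. Intervals on
#' chromosomes absent from the circ table trigger a warning and are ignored.
#'
#' @param circs Circ table.
#' @param mites data.frame with 1-based inclusive `chrom`, `start`, `end`
#'   (see [read_mite_bed()]).
#' @param window Flank window size in bp (default 1000).
#' @param chroms Known chromosome names (default: genome chromosomes are
#'   unknown, so the circ table's chromosomes are used).
#' @return List with `per_circ` (`circ_id`, `mite_both_flanks`), `count`.
#' @export
mite_overlap <- function(circs, mites, window = 1000,
                         chroms = unique(circs$chrom)) {
  known <- chroms
  bad <- !mites$chrom %in% known
  if (any(bad)) {
    warning("ignoring ", sum(bad), " MITE interval(s) on unknown chromosome(s): ",
            paste(unique(mites$chrom[bad]), collapse = ", "))
    mites <- mites[!bad, , drop = FALSE]
  }
  flag <- logical(nrow(circs))
  if (nrow(mites)) {
    mgr <- GenomicRanges::GRanges(mites$chrom,
                                  IRanges::IRanges(mites$start, mites$end))
    up <- GenomicRanges::GRanges(
      circs$chrom,
      IRanges::IRanges(pmax(1L, circs$start - as.integer(window)),
                       pmax(1L, circs$start - 1L)))
    down <- GenomicRanges::GRanges(
      circs$chrom,
      IRanges::IRanges(circs$end + 1L, circs$end + as.integer(window)))
    up_hit <- GenomicRanges::countOverlaps(up, mgr) > 0
    down_hit <- GenomicRanges::countOverlaps(down, mgr) > 0
    # a circ starting at position 1 has an empty upstream window
    up_hit[circs$start <= 1L] <- FALSE
    flag <- up_hit & down_hit
  }
  list(per_circ = data.frame(circ_id = circs$circ_id,
                             mite_both_flanks = flag,
                             stringsAsFactors = FALSE),
       count = sum(flag))
}
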