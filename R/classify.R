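.exon_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(genes$start, genes$end),
    gene_id = genes$gene_id,
    exon_rank = genes$exon_rank
  )
}

.gene_spans <- function(genes) {
  sp <- lapply(split(genes, genes$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               strand = g$strand[1], start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, sp)
  rownames(out) <- NULL
  out
}

.intron_granges <- function(genes) {
  per_gene <- lapply(split(genes, genes$gene_id), function(g) {
    g <- g[order(g$start), ]
    if (nrow(g) < 2) return(NULL)
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               start = g$end[-nrow(g)] + 1L, end = g$start[-1] - 1L,
               stringsAsFactors = FALSE)
  })
  introns <- do.call(rbind, per_gene)
  if (is.null(introns) || nrow(introns) == 0) {
    return(GenomicRanges::GRanges())
  }
  introns <- introns[introns$start <= introns$end, ]
  GenomicRanges::GRanges(seqnames = introns$chrom,
                         ranges = IRanges::IRanges(introns$start, introns$end),
                         gene_id = introns$gene_id)
}

#' Classify circRNAs by genomic origin
#'
#' Deterministic three-way call per back-splice junction against a gene
#' annotation, in order of precedence:
#' 1. **exonic** — both back-splice coordinates fall inside exon intervals of
#'    one and the same gene;
#' 2. **intronic** — the whole span lies inside a single intron of one gene;
#' 3. **intergenic** — everything else, including spans crossing gene
#'    boundaries or multiple genes.
#'
#' When several genes qualify (nested/overlapping genes), the gene with the
#' largest overlap with the circRNA span wins; exact ties break by
#' lexicographically smallest `gene_id`.
#'
#' @param circs Circ table (`circ_id`, `chrom`, `start`, `end`).
#' @param genes Exon table (see [read_gene_models()]).
#' @return data.frame with `circ_id`, `origin` (one of `exonic`, `intronic`,
#'   `intergenic`), `parent_gene` (`NA` for intergenic).
#' @export
classify_origin <- function(circs, genes) {
  n <- nrow(circs)
  origin <- rep("intergenic", n)
  parent <- rep(NA_character_, n)
  if (n == 0) {
    return(data.frame(circ_id = character(), origin = character(),
                      parent_gene = character(), stringsAsFactors = FALSE))
  }
  exons <- .exon_granges(genes)
  introns <- .intron_granges(genes)
  starts <- GenomicRanges::GRanges(circs$chrom,
                                   IRanges::IRanges(circs$start, circs$start))
  ends <- GenomicRanges::GRanges(circs$chrom,
                                 IRanges::IRanges(circs$end, circs$end))
  spans <- GenomicRanges::GRanges(circs$chrom,
                                  IRanges::IRanges(circs$start, circs$end))

  hs <- GenomicRanges::findOverlaps(starts, exons)
  he <- GenomicRanges::findOverlaps(ends, exons)
  genes_at_start <- split(exons$gene_id[S4Vectors::subjectHits(hs)],
                          S4Vectors::queryHits(hs))
  genes_at_end <- split(exons$gene_id[S4Vectors::subjectHits(he)],
                        S4Vectors::queryHits(he))
  hi <- GenomicRanges::findOverlaps(spans, introns, type = "within")
  genes_intron <- split(introns$gene_id[S4Vectors::subjectHits(hi)],
                        S4Vectors::queryHits(hi))

  pick_parent <- function(cand, i) {
    cand <- unique(cand)
    if (length(cand) == 1) return(cand)
    # largest overlap of the gene's exons with the circ span; ties lexicographic
    ov <- vapply(cand, function(g) {
      ge <- genes[genes$gene_id == g & genes$chrom == circs$chrom[i], ]
      sum(pmax(0L, pmin(ge$end, circs$end[i]) -
                     pmax(ge$start, circs$start[i]) + 1L))
    }, numeric(1))
    cand <- cand[ov == max(ov)]
    sort(cand)[1]
  }

  for (i in seq_len(n)) {
    key <- as.character(i)
    both <- intersect(genes_at_start[[key]], genes_at_end[[key]])
    if (length(both)) {
      origin[i] <- "exonic"
      parent[i] <- pick_parent(both, i)
    } else if (!is.null(genes_intron[[key]])) {
      origin[i] <- "intronic"
      parent[i] <- sort(unique(genes_intron[[key]]))[1]
    }
  }
  data.frame(circ_id = circs$circ_id, origin = origin, parent_gene = parent,
             stringsAsFactors = FALSE)
}

#' Exon architecture of exonic circRNAs
#'
#' For each exonic circRNA, the parent-gene exons intersecting the
#' back-splice span are collected and indexed in *transcript* orientation
#' (exon 1 = 5'-most exon of the gene, so genomically last on minus-strand
#' genes). The position class is:
#' * `first` — the covered exons include exon 1 (but not the last exon);
#' * `last` — they include the gene's last exon (but not exon 1);
#' * `first_and_last` — both;
#' * `middle` — neither.
#'
#' Exon lengths are the spans of each exon intersected with the circ span,
#' and `spliced_length` is their sum.
#'
#' @param circs Circ table.
#' @param origin_calls Output of [classify_origin()] (only exonic rows are
#'   used).
#' @param genes Exon table.
#' @return data.frame with `circ_id`, `position_class`, `exon_count`,
#'   `spliced_length`, `exon_lengths` (comma-separated string).
#' @export
exon_architecture <- function(circs, origin_calls, genes) {
  calls <- origin_calls[origin_calls$origin == "exonic", ]
  rows <- lapply(seq_len(nrow(calls)), function(k) {
    cid <- calls$circ_id[k]
    i <- match(cid, circs$circ_id)
    g <- genes[genes$gene_id == calls$parent_gene[k], ]
    hit <- g$start <= circs$end[i] & g$end >= circs$start[i]
    if (!any(hit)) {
      stop("exonic circ ", cid, " intersects no parent exon")
    }
    gh <- g[hit, ]
    lens <- pmin(gh$end, circs$end[i]) - pmax(gh$start, circs$start[i]) + 1L
    ranks <- gh$exon_rank
    max_rank <- max(g$exon_rank)
    has_first <- 1L %in% ranks
    has_last <- max_rank %in% ranks
    cls <- if (has_first && has_last) "first_and_last"
           else if (has_first) "first"
           else if (has_last) "last"
           else "middle"
    # report lengths in transcript order
    ord <- order(ranks)
    data.frame(circ_id = cid, position_class = cls,
               exon_count = length(lens),
               spliced_length = sum(lens),
               exon_lengths = paste(lens[ord], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(circ_id = character(), position_class = character(),
               exon_count = integer(), spliced_length = integer(),
               exon_lengths = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Percentage helper
#'
#' `100 * count / total`, rounded to `digits` decimals. Used for all cohort
#' percentages in reports.
#'
#' @param count Numerator count(s).
#' @param total Denominator.
#' @param digits Decimal places (default 2).
#' @return Numeric percentage(s).
#' @export
#' @examples
#' pct(2216, 2787)  # 79.51
pct <- function(count, total, digits = 2) {
  round(100 * count / total, digits)
}

#' Summary report of circRNA characterization
#'
#' Origin counts with percentages (2 decimals), per-chromosome counts, a
#' length histogram, and the median length. The length of an exonic circRNA
#' with resolved exon structure is its spliced length (sum of circularized
#' exon spans, introns excluded); all other circRNAs use the genomic span
#' `end - start + 1`.
#'
#' @param origin_calls Output of [classify_origin()].
#' @param architectures Output of [exon_architecture()].
#' @param circs Circ table.
#' @param bin_width Length-histogram bin width in nt (default 200).
#' @return List with `n`, `origin_table` (`origin`, `count`, `percent`),
#'   `per_chromosome`, `length_hist` (`bin_start`, `bin_end`, `count`),
#'   `median_length`, `lengths` (named vector).
#' @export
summarize_circs <- function(origin_calls, architectures, circs,
                            bin_width = 200) {
  n <- nrow(origin_calls)
  lev <- c("exonic", "intergenic", "intronic")
  cnt <- vapply(lev, function(l) sum(origin_calls$origin == l), integer(1))
  origin_table <- data.frame(
    origin = lev, count = cnt,
    percent = if (n > 0) pct(cnt, n) else rep(NA_real_, 3),
    stringsAsFactors = FALSE)
  if (n == 0) {
    return(list(n = 0L, origin_table = origin_table,
                per_chromosome = data.frame(chrom = character(),
                                            count = integer()),
                length_hist = data.frame(bin_start = integer(),
                                         bin_end = integer(),
                                         count = integer()),
                median_length = NA_real_, lengths = numeric()))
  }
  idx <- match(origin_calls$circ_id, circs$circ_id)
  lens <- circs$end[idx] - circs$start[idx] + 1L
  names(lens) <- origin_calls$circ_id
  if (nrow(architectures)) {
    hit <- match(architectures$circ_id, names(lens))
    lens[hit[!is.na(hit)]] <- architectures$spliced_length[!is.na(hit)]
  }
  per_chrom <- as.data.frame(table(chrom = circs$chrom[idx]),
                             stringsAsFactors = FALSE)
  names(per_chrom) <- c("chrom", "count")
  breaks <- seq(0, ceiling(max(lens) / bin_width) * bin_width, by = bin_width)
  h <- hist(lens, breaks = breaks, plot = FALSE, right = TRUE)
  length_hist <- data.frame(bin_start = utils::head(breaks, -1) + 1L,
                            bin_end = breaks[-1],
                            count = h$counts)
  list(n = n, origin_table = origin_table, per_chromosome = per_chrom,
       length_hist = length_hist, median_length = stats::median(lens),
       lengths = lens)
}
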