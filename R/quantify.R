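#' SRPBM normalization of junction-read counts
#'
#' Spliced reads per billion mapped bases:
#' `SRPBM = junction_reads / (mapped_reads / 1e9) / read_length`.
#' Linear in the read count, and zero exactly when the count is zero.
#'
#' @param junction_reads Junction read count(s).
#' @param mapped_reads Mapped reads of the library (must be > 0).
#' @param read_length Read length in bases (must be > 0).
#' @return SRPBM value(s).
#' @export
#' @examples
#' srpbm(10, 5e7, 150)  # 1.3333...
srpbm <- function(junction_reads, mapped_reads, read_length) {
  if (any(mapped_reads <= 0)) stop("mapped_reads must be positive")
  if (any(read_length <= 0)) stop("read_length must be positive")
  junction_reads / (mapped_reads / 1e9) / read_length
}

#' Build multi-sample raw-count and SRPBM matrices
#'
#' Takes one junction table per sample (named list, names = sample ids) and
#' the per-sample library statistics, and assembles matrices over the union
#' of observed circRNAs. A circRNA absent from a sample's table gets raw
#' count 0 and SRPBM 0. Column order follows the row order of `stats`.
#'
#' @param tables Named list of junction tables (see [read_junction_table()]).
#'   Every name must appear in `stats$sample_id`.
#' @param stats data.frame with `sample_id`, `total_reads`, `mapped_reads`,
#'   `read_length`.
#' @return List with `counts` (integer matrix), `srpbm` (numeric matrix),
#'   `circs` (data.frame of the union of circRNA records, one row per
#'   circ_id), and `stats`.
#' @export
build_expression_matrix <- function(tables, stats) {
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop("tables must be a named list (names = sample ids)")
  }
  unknown <- setdiff(names(tables), stats$sample_id)
  if (length(unknown)) {
    stop("sample(s) with junction tables but no stats: ",
         paste(unknown, collapse = ", "))
  }
  missing_tab <- setdiff(stats$sample_id, names(tables))
  if (length(missing_tab)) {
    stop("sample(s) in stats without a junction table: ",
         paste(missing_tab, collapse = ", "))
  }
  all_circs <- do.call(rbind, lapply(tables, function(t)
    t[, c("circ_id", "chrom", "start", "end", "strand", "reported_type",
          "gene_id")]))
  if (is.null(all_circs) || nrow(all_circs) == 0) {
    circs <- .empty_circ_table()
    circs$junction_reads <- NULL
    counts <- matrix(0L, nrow = 0, ncol = nrow(stats),
                     dimnames = list(NULL, stats$sample_id))
    return(list(counts = counts, srpbm = counts + 0, circs = circs,
                stats = stats))
  }
  circs <- all_circs[!duplicated(all_circs$circ_id), ]
  circs <- circs[order(circs$chrom, circs$start, circs$end), ]
  rownames(circs) <- NULL
  counts <- matrix(0L, nrow = nrow(circs), ncol = nrow(stats),
                   dimnames = list(circs$circ_id, stats$sample_id))
  for (s in names(tables)) {
    t <- tables[[s]]
    if (nrow(t)) counts[t$circ_id, s] <- as.integer(t$junction_reads)
  }
  sr <- counts
  for (j in seq_len(ncol(counts))) {
    sr[, j] <- srpbm(counts[, j], stats$mapped_reads[j], stats$read_length[j])
  }
  list(counts = counts, srpbm = sr, circs = circs, stats = stats)
}

#' Correlate circRNA abundance with parental-gene abundance
#'
#' Pearson correlation of `log2(mean SRPBM + 1)` against
#' `log2(mean gene abundance + 1)` over circRNAs with a resolved parent
#' gene. Means are taken over the selected samples. With `sample_groups`
#' (a named list of sample-id vectors, e.g. one per tissue) one correlation
#' is returned per group; otherwise all samples are pooled.
#'
#' @param srpbm_matrix SRPBM matrix (circ_id x sample).
#' @param gene_abundance Gene abundance matrix (gene_id x sample) with the
#'   same sample columns, or a named vector of per-gene mean abundances.
#' @param parent_map data.frame with `circ_id`, `gene_id`.
#' @param sample_groups Optional named list of sample-id vectors.
#' @return data.frame with `group`, `r`, `n`.
#' @export
correlate_with_parents <- function(srpbm_matrix, gene_abundance, parent_map,
                                   sample_groups = NULL) {
  if (is.null(sample_groups)) {
    sample_groups <- list(all = colnames(srpbm_matrix))
  }
  one <- function(samples, group) {
    pm <- parent_map[parent_map$circ_id %in% rownames(srpbm_matrix) &
                       !is.na(parent_map$gene_id), ]
    circ_mean <- rowMeans(srpbm_matrix[pm$circ_id, samples, drop = FALSE])
    if (is.matrix(gene_abundance)) {
      ok <- pm$gene_id %in% rownames(gene_abundance)
      pm <- pm[ok, ]
      circ_mean <- circ_mean[ok]
      gene_mean <- rowMeans(gene_abundance[pm$gene_id, samples, drop = FALSE])
    } else {
      ok <- pm$gene_id %in% names(gene_abundance)
      pm <- pm[ok, ]
      circ_mean <- circ_mean[ok]
      gene_mean <- gene_abundance[pm$gene_id]
    }
    if (length(circ_mean) < 3) stop("fewer than 3 circ/parent pairs")
    r <- stats::cor(log2(circ_mean + 1), log2(gene_mean + 1),
                    method = "pearson")
    data.frame(group = group, r = r, n = length(circ_mean),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, Map(one, sample_groups, names(sample_groups)))
  rownames(out) <- NULL
  out
}
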