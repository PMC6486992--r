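#' Hypergeometric term enrichment
#'
#' Classic one-term-at-a-time over-representation analysis of annotation
#' terms among a gene set of interest (typically the parent genes of
#' differentially expressed circRNAs) against a background (typically all
#' parent genes of detected circRNAs). For each term with at least one gene
#' in the DE set, the p-value is the upper-tail hypergeometric probability
#' `P(X >= k)` of drawing `k` or more term genes when sampling `n` genes
#' from a universe of `N` containing `K` term genes; BH-adjusted FDR values
#' are added and results are sorted by ascending p.
#'
#' No term-graph decorrelation (elim/weight style) is performed; terms are
#' treated independently.
#'
#' @param de_genes Character vector, the gene set of interest (must be a
#'   subset of `background_genes`).
#' @param background_genes Character vector, the gene universe.
#' @param gene_to_terms data.frame with columns `gene_id`, `term_id` and
#'   optionally `term_name`.
#' @return data.frame with `term_id`, `term_name`, `k`, `K`, `n`, `N`,
#'   `p_value`, `fdr`, sorted by `p_value`.
#' @export
enrich_terms <- function(de_genes, background_genes, gene_to_terms) {
  de_genes <- unique(de_genes)
  background_genes <- unique(background_genes)
  if (!all(de_genes %in% background_genes)) {
    stop("de_genes must be a subset of background_genes")
  }
  empty <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE)
  if (length(de_genes) == 0) return(empty)
  map <- gene_to_terms[gene_to_terms$gene_id %in% background_genes, ,
                       drop = FALSE]
  map <- unique(map[, intersect(c("gene_id", "term_id", "term_name"),
                                names(map))])
  if (!"term_name" %in% names(map)) map$term_name <- NA_character_
  N <- length(background_genes)
  n <- length(de_genes)
  rows <- lapply(split(map, map$term_id), function(tm) {
    K <- length(unique(tm$gene_id))
    k <- length(unique(intersect(tm$gene_id, de_genes)))
    if (k == 0) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tm$term_id[1],
               term_name = tm$term_name[1],
               k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  out
}
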