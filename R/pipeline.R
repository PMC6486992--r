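#' Per-sample sequencing summary report
#'
#' Builds the conventional per-sample summary table of a circRNA-seq run:
#' total reads, mapped reads with percentage of total (2 decimals), junction
#' reads with percentage of total (3 decimals), and detected circRNA count,
#' plus an `All` row of column sums whose percentages are recomputed from
#' the summed integers. A self-consistency check (each percentage
#' recomputes from its own row's integers) runs automatically.
#'
#' @param stats data.frame with `sample_id`, `total_reads`, `mapped_reads`,
#'   `junction_reads`, `n_circ`.
#' @return data.frame with added `mapped_pct`, `junction_pct` and an `All`
#'   row (its `n_circ` is the number of distinct circRNAs if attribute
#'   `n_circ_all` is supplied, else the column sum).
#' @param n_circ_all Optional distinct-circRNA count for the `All` row
#'   (the union across samples rather than the column sum).
#' @export
sample_summary <- function(stats, n_circ_all = NULL) {
  req <- c("sample_id", "total_reads", "mapped_reads", "junction_reads",
           "n_circ")
  missing <- setdiff(req, names(stats))
  if (length(missing)) stop("missing column(s): ",
                            paste(missing, collapse = ", "))
  out <- stats[, req]
  all_row <- data.frame(sample_id = "All",
                        total_reads = sum(out$total_reads),
                        mapped_reads = sum(out$mapped_reads),
                        junction_reads = sum(out$junction_reads),
                        n_circ = if (is.null(n_circ_all))
                          sum(out$n_circ) else n_circ_all,
                        stringsAsFactors = FALSE)
  out <- rbind(out, all_row)
  out$mapped_pct <- pct(out$mapped_reads, out$total_reads, digits = 2)
  out$junction_pct <- pct(out$junction_reads, out$total_reads, digits = 3)
  stopifnot(identical(out$mapped_pct,
                      round(100 * out$mapped_reads / out$total_reads, 2)),
            identical(out$junction_pct,
                      round(100 * out$junction_reads / out$total_reads, 3)))
  out
}

#' Tissue overlap (Venn) counts
#'
#' Counts circRNAs by tissue-membership pattern. For every non-empty
#' combination of the named sets, the number of elements belonging to
#' exactly that combination is reported; `|A exclusive| + |shared patterns
#' containing A|` always sums to `|A|`.
#'
#' @param sets Named list (>= 2 entries) of character vectors.
#' @return data.frame with `pattern` (set names joined by `&`), `count`.
#' @export
tissue_overlap <- function(sets) {
  if (length(sets) < 2 || is.null(names(sets))) {
    stop("sets must be a named list with at least two entries")
  }
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1,
                                                  dimnames = list(NULL,
                                                                  names(sets)))
  pattern <- apply(membership, 1, function(row)
    paste(names(sets)[row], collapse = "&"))
  tab <- table(pattern)
  out <- data.frame(pattern = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  # stable order: singletons first, then larger combinations
  out[order(nchar(out$pattern), out$pattern), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Run the full characterization pipeline
#'
#' Orchestrates every stage over an in-memory input bundle (as produced by
#' [simulate_circ_dataset()], or assembled from files with the readers in
#' this package): expression matrix, origin and architecture classification,
#' characterization summary, alternative-circularization statistics, splice
#' signals, flanking-sequence and MITE searches, per-tissue differential
#' expression with the global abundance-shift test, optional parent-gene
#' correlation, optional term enrichment, optional miRNA target network, and
#' the per-sample summary report. The run is fully deterministic (no random
#' numbers are drawn).
#'
#' @param inputs List with `genome`, `genes`, `junction_tables`,
#'   `sample_stats` (needing `tissue`, `condition` columns for the DE
#'   stage), and optionally `mites`, `gene_abundance`, `mirnas`, `mrnas`.
#' @param window,min_len Flank-scan parameters.
#' @param lfc_cutoff,fdr_cutoff,pseudocount DE parameters.
#' @param target_cutoff miRNA-site penalty cut-off.
#' @param bin_width,half_window Summary and PFM parameters.
#' @param gene_to_terms Optional gene-to-term map for enrichment.
#' @param outdir Optional directory; when given, every stage table is also
#'   written as TSV.
#' @return Named list of all stage results.
#' @export
run_pipeline <- function(inputs, window = 1000, min_len = 18,
                         lfc_cutoff = 1, fdr_cutoff = 0.05,
                         pseudocount = 0.01, target_cutoff = 4,
                         bin_width = 200, half_window = 5,
                         gene_to_terms = NULL, outdir = NULL) {
  for (k in c("genome", "genes", "junction_tables", "sample_stats")) {
    if (is.null(inputs[[k]])) stop("missing input: ", k)
  }
  mat <- build_expression_matrix(inputs$junction_tables, inputs$sample_stats)
  origin <- classify_origin(mat$circs, inputs$genes)
  arch <- exon_architecture(mat$circs, origin, inputs$genes)
  summary <- summarize_circs(origin, arch, mat$circs, bin_width = bin_width)
  grouping <- group_loci(mat$circs, origin)
  iso_hist <- isoform_histogram(grouping$loci)
  dominants <- dominant_isoforms(grouping, mat$srpbm)
  signals <- extract_splice_signals(mat$circs, inputs$genome)
  signal_tally <- tally_signals(signals)
  pfm <- boundary_pfm(mat$circs, inputs$genome, half_window = half_window)
  flanks <- scan_flanks(mat$circs, inputs$genome, window = window,
                        min_len = min_len)
  mite <- if (!is.null(inputs$mites) && nrow(inputs$mites)) {
    mite_overlap(mat$circs, inputs$mites, window = window,
                 chroms = names(inputs$genome))
  } else NULL

  ## per-tissue DE
  st <- inputs$sample_stats
  de <- NULL
  shift <- NULL
  tissue_sets <- NULL
  if (all(c("tissue", "condition") %in% names(st))) {
    conds <- unique(st$condition)
    tissue_sets <- lapply(split(st$sample_id, st$tissue), function(ss) {
      rownames(mat$counts)[rowSums(mat$counts[, ss, drop = FALSE]) > 0]
    })
    if (length(conds) == 2) {
      control <- conds[1]
      treated_cond <- conds[2]
      de <- list()
      shift <- list()
      for (t in unique(st$tissue)) {
        trt <- st$sample_id[st$tissue == t & st$condition == treated_cond]
        ctl <- st$sample_id[st$tissue == t & st$condition == control]
        if (!length(trt) || !length(ctl)) next
        detected <- tissue_sets[[t]]
        res <- de_test(mat$counts[detected, , drop = FALSE], st,
                       treated = trt, control = ctl,
                       pseudocount = pseudocount)
        res <- de_call(res, lfc_cutoff = lfc_cutoff,
                       fdr_cutoff = fdr_cutoff)
        res$tissue <- t
        de[[t]] <- res
        lt <- log2(rowMeans(mat$srpbm[detected, trt, drop = FALSE]) + 1)
        lc <- log2(rowMeans(mat$srpbm[detected, ctl, drop = FALSE]) + 1)
        shift[[t]] <- global_shift(lt, lc)
      }
    }
  }
  de_summary <- if (!is.null(de)) de_report(do.call(rbind, de)) else NULL

  ## parent-gene abundance correlation
  parent_corr <- NULL
  if (!is.null(inputs$gene_abundance)) {
    pm <- origin[origin$origin %in% c("exonic", "intronic"),
                 c("circ_id", "parent_gene")]
    names(pm) <- c("circ_id", "gene_id")
    groups <- if (!is.null(tissue_sets) && length(tissue_sets) > 1) {
      split(st$sample_id, st$tissue)
    } else NULL
    parent_corr <- tryCatch(
      correlate_with_parents(mat$srpbm, inputs$gene_abundance, pm,
                             sample_groups = groups),
      error = function(e) NULL)
  }

  ## enrichment of DE parent genes
  enrichment <- NULL
  if (!is.null(gene_to_terms) && !is.null(de)) {
    enrichment <- list()
    for (t in names(de)) {
      res <- de[[t]]
      de_ids <- res$circ_id[res$call != "ns"]
      de_genes <- unique(stats::na.omit(
        origin$parent_gene[origin$circ_id %in% de_ids]))
      bg <- unique(stats::na.omit(
        origin$parent_gene[origin$circ_id %in% tissue_sets[[t]]]))
      if (length(de_genes)) {
        enrichment[[t]] <- enrich_terms(de_genes, bg, gene_to_terms)
      }
    }
  }

  ## miRNA target network over DE circRNAs
  network <- NULL
  circ_hits <- NULL
  if (!is.null(inputs$mirnas) && !is.null(de)) {
    de_ids <- unique(unlist(lapply(de, function(r)
      r$circ_id[r$call != "ns"])))
    if (length(de_ids)) {
      mir_len <- max(nchar(inputs$mirnas))
      targets <- vapply(de_ids, function(cid) {
        i <- match(cid, mat$circs$circ_id)
        circ_sequence(mat$circs[i, ], inputs$genome,
                      origin_call = origin[match(cid, origin$circ_id), ],
                      genes = inputs$genes, wrap = mir_len - 1)
      }, character(1))
      circ_hits <- predict_targets(inputs$mirnas, targets,
                                   cutoff = target_cutoff)
      mrna_hits <- if (!is.null(inputs$mrnas)) {
        predict_targets(inputs$mirnas, inputs$mrnas,
                        cutoff = target_cutoff)
      } else circ_hits[0, ]
      network <- build_network(circ_hits, mrna_hits, de_ids)
    }
  }

  junction_totals <- colSums(mat$counts)
  report <- sample_summary(
    data.frame(sample_id = st$sample_id,
               total_reads = st$total_reads,
               mapped_reads = st$mapped_reads,
               junction_reads = as.integer(junction_totals[st$sample_id]),
               n_circ = as.integer(colSums(mat$counts[, st$sample_id,
                                                      drop = FALSE] > 0)),
               stringsAsFactors = FALSE),
    n_circ_all = nrow(mat$counts))
  overlap <- if (!is.null(tissue_sets) && length(tissue_sets) >= 2) {
    tissue_overlap(tissue_sets)
  } else NULL

  out <- list(matrix = mat, origin = origin, architecture = arch,
              summary = summary, loci = grouping, isoform_hist = iso_hist,
              dominants = dominants, signals = signals,
              signal_tally = signal_tally, pfm = pfm, flanks = flanks,
              mite = mite, de = de, de_summary = de_summary,
              global_shift = shift, parent_correlation = parent_corr,
              enrichment = enrichment, circ_hits = circ_hits,
              network = network, report = report,
              tissue_overlap = overlap)
  if (!is.null(outdir)) .write_pipeline_tables(out, outdir)
  out
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.write_pipeline_tables <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(out$origin, file.path(outdir, "origin_calls.tsv"))
  .write_tsv(out$architecture, file.path(outdir, "exon_architecture.tsv"))
  .write_tsv(out$summary$origin_table, file.path(outdir, "origin_summary.tsv"))
  .write_tsv(out$summary$length_hist, file.path(outdir, "length_hist.tsv"))
  .write_tsv(out$loci$loci, file.path(outdir, "loci.tsv"))
  .write_tsv(out$isoform_hist, file.path(outdir, "isoform_hist.tsv"))
  .write_tsv(out$dominants, file.path(outdir, "dominant_isoforms.tsv"))
  .write_tsv(out$signal_tally$table, file.path(outdir, "splice_signals.tsv"))
  .write_tsv(as.data.frame(out$pfm), file.path(outdir, "boundary_pfm.tsv"))
  .write_tsv(out$flanks$per_circ, file.path(outdir, "flank_scan.tsv"))
  if (!is.null(out$mite)) {
    .write_tsv(out$mite$per_circ, file.path(outdir, "mite_overlap.tsv"))
  }
  if (!is.null(out$de)) {
    .write_tsv(do.call(rbind, out$de), file.path(outdir, "de_results.tsv"))
    .write_tsv(out$de_summary, file.path(outdir, "de_summary.tsv"))
  }
  if (!is.null(out$network)) {
    .write_tsv(out$network, file.path(outdir, "network_edges.tsv"))
  }
  .write_tsv(out$report, file.path(outdir, "sample_report.tsv"))
  if (!is.null(out$tissue_overlap)) {
    .write_tsv(out$tissue_overlap, file.path(outdir, "tissue_overlap.tsv"))
  }
  invisible(outdir)
}
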