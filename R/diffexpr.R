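#' Differential-expression test on pooled junction counts
#'
#' A documented stand-in for empirical-Bayes NB modelling: junction reads
#' are pooled over the replicates of each condition and compared with a
#' two-sided exact test of the two pooled counts against the pooled library
#' sizes (the conditional binomial test for comparing two rates, as in
#' [stats::poisson.test] for two samples). Because pooling treats replicate
#' variation as purely Poisson, p-values are well calibrated under shallow
#' biological variability and anticonservative under strong overdispersion;
#' externally computed p-values (e.g. from an NB package) can be substituted
#' via [de_call()].
#'
#' The fold change is computed on mean SRPBM with a pseudocount:
#' `log2fc = log2((mean SRPBM_treated + c) / (mean SRPBM_control + c))`,
#' `c = 0.01` by default, so zero counts give finite fold changes.
#'
#' @param counts Raw junction-count matrix (circ_id x sample).
#' @param stats Sample statistics (`sample_id`, `mapped_reads`,
#'   `read_length`).
#' @param treated,control Character vectors of sample ids for the two
#'   conditions.
#' @param pseudocount SRPBM pseudocount for fold changes (default 0.01).
#' @return data.frame with `circ_id`, `log2fc`, `p_value`.
#' @export
de_test <- function(counts, stats, treated, control, pseudocount = 0.01) {
  idx_t <- match(treated, stats$sample_id)
  idx_c <- match(control, stats$sample_id)
  if (anyNA(idx_t) || anyNA(idx_c)) stop("unknown sample id in groups")
  lib_t <- sum(stats$mapped_reads[idx_t])
  lib_c <- sum(stats$mapped_reads[idx_c])
  if (lib_t <= 0 || lib_c <= 0) stop("zero pooled library size")
  sr <- counts
  for (j in seq_len(ncol(counts))) {
    k <- match(colnames(counts)[j], stats$sample_id)
    sr[, j] <- srpbm(counts[, j], stats$mapped_reads[k], stats$read_length[k])
  }
  mean_t <- rowMeans(sr[, treated, drop = FALSE])
  mean_c <- rowMeans(sr[, control, drop = FALSE])
  log2fc <- log2((mean_t + pseudocount) / (mean_c + pseudocount))
  kt <- rowSums(counts[, treated, drop = FALSE])
  kc <- rowSums(counts[, control, drop = FALSE])
  p_rate <- lib_t / (lib_t + lib_c)
  p <- vapply(seq_along(kt), function(i) {
    n <- kt[i] + kc[i]
    if (n == 0) return(1)
    stats::binom.test(kt[i], n, p = p_rate,
                      alternative = "two.sided")$p.value
  }, numeric(1))
  data.frame(circ_id = rownames(counts), log2fc = log2fc, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (capped at 1, monotone in the p-value ranks);
#' a thin wrapper over [stats::p.adjust] with `method = "BH"`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Apply differential-expression cut-offs
#'
#' Adds BH-adjusted FDR values and the three-way call using the standard
#' cut-off rule: `up` iff `log2fc > lfc_cutoff` and `fdr <= fdr_cutoff`,
#' `down` iff `log2fc < -lfc_cutoff` and `fdr <= fdr_cutoff`, otherwise
#' `ns`. The fold-change bound is strict and the FDR bound non-strict, as
#' conventionally printed (`|log2FC| > 1`, `FDR <= 0.05`).
#'
#' @param results Output of [de_test()] (or any data.frame with `circ_id`,
#'   `log2fc`, `p_value`, e.g. from an external NB fit).
#' @param lfc_cutoff Absolute log2 fold-change cut-off (default 1).
#' @param fdr_cutoff FDR cut-off (default 0.05).
#' @return `results` with added `fdr` and `call` columns.
#' @export
de_call <- function(results, lfc_cutoff = 1, fdr_cutoff = 0.05) {
  results$fdr <- bh_adjust(results$p_value)
  results$call <- "ns"
  results$call[results$log2fc > lfc_cutoff &
                 results$fdr <= fdr_cutoff] <- "up"
  results$call[results$log2fc < -lfc_cutoff &
                 results$fdr <= fdr_cutoff] <- "down"
  results
}

#' Global abundance-shift comparison (Wilcoxon rank-sum)
#'
#' Two-sided rank-sum test between two groups of per-circRNA abundances
#' (conventionally `log2(SRPBM + 1)` values). The exact distribution is
#' enumerated when the combined sample size is at most 20 and the data are
#' tie-free; otherwise the normal approximation with continuity correction
#' is used.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @return List with `statistic` (W) and `p_value`.
#' @export
global_shift <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  use_exact <- (length(x) + length(y) <= 20) &&
    !anyDuplicated(c(x, y))
  w <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  list(statistic = unname(w$statistic), p_value = w$p.value)
}

#' Per-tissue differential-expression report
#'
#' @param calls Named list (tissue -> data.frame with a `call` column) or a
#'   single data.frame with a `tissue` column.
#' @return data.frame with `tissue`, `up`, `down`, `total` (= up + down).
#' @export
de_report <- function(calls) {
  if (is.data.frame(calls)) {
    calls <- split(calls, calls$tissue)
  }
  rows <- lapply(names(calls), function(t) {
    up <- sum(calls[[t]]$call == "up")
    down <- sum(calls[[t]]$call == "down")
    data.frame(tissue = t, up = up, down = down, total = up + down,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tissue = character(), up = integer(), down = integer(),
               total = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
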