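#' Simulation configuration
#'
#' Assembles the parameter list for [simulate_circ_dataset()]. Defaults
#' describe a desk-scale plant circRNA-seq experiment: a multi-chromosome
#' genome with unanchored scaffolds, multi-exon gene models, a circRNA
#' population with the canonical exonic/intronic/intergenic mix observed in
#' plant surveys (79.5/4.9/15.6), a minority of canonical GT/AG (plus CT/AC)
#' splice signals (11.7%), a small planted subset with >= 18-bp
#' inverted-repeat flanks, and negative-binomial junction counts over
#' 2 tissues x 2 conditions x 2 replicates with salt-induced fold changes.
#'
#' Origin, canonical-signal, planted-flank, MITE and DE subsets are assigned
#' by exact quota (`round(fraction * n_circs)`), so fixture composition is
#' deterministic; which circRNAs land in each subset is random under `seed`.
#'
#' @param seed Integer RNG seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @param n_chromosomes,chromosome_length Chromosome count and length (bp;
#'   recycled).
#' @param n_scaffolds,scaffold_length Unanchored scaffolds appended to the
#'   genome (no genes or circRNAs are placed on them).
#' @param n_genes Number of gene models.
#' @param exons_per_gene,exon_length,intron_length,intergenic_gap Ranges
#'   (min, max) for gene structure, in exons resp. bp.
#' @param n_circs Number of circRNAs.
#' @param origin_mix Named fractions `exonic`, `intronic`, `intergenic`
#'   (must sum to 1).
#' @param canonical_fraction Fraction of circRNAs with a canonical GT/AG or
#'   CT/AC signal pair.
#' @param planted_flank_fraction,flank_repeat_length Fraction of circRNAs
#'   carrying planted inverted-repeat flanks, and repeat length (bp).
#' @param flank_window Flank window (bp) within which repeats are planted
#'   and for which isolation of planted circRNAs is guaranteed.
#' @param mite_fraction Fraction of circRNAs given MITE intervals in both
#'   flanking windows.
#' @param tissues,conditions,replicates Sample layout; `conditions[1]` is
#'   the control.
#' @param tissue_pattern_probs Named probabilities `both`, `first_only`,
#'   `second_only` for the tissue-specificity of each circRNA (used when
#'   there are two tissues).
#' @param base_mean_log,base_mean_sd Lognormal (meanlog, sdlog) of the
#'   baseline junction-read mean at the reference depth of 5e7 mapped reads.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param de_fraction,de_fold Fraction of circRNAs differentially expressed
#'   under the stress condition, and the true fold change (up or down with
#'   equal probability).
#' @param de_second_tissue_bias Probability that a DE circRNA responds in
#'   the second tissue (the root, in the default layout) when expressed in
#'   both.
#' @param plant_dominant,dominant_fold Optionally make one isoform per
#'   multi-isoform gene locus `dominant_fold` times the strongest of its
#'   siblings.
#' @param read_length Read length (bp).
#' @param lib_size_meanlog,lib_size_sdlog Lognormal mapped-library sizes.
#' @param gene_abund_noise_sd Lognormal sdlog of the noise linking parental
#'   gene abundance to circRNA abundance.
#' @param n_mirnas,mirna_length Mature miRNA complement emitted with the
#'   dataset.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 3, chromosome_length = 300000,
                       n_scaffolds = 2, scaffold_length = 15000,
                       n_genes = 110,
                       exons_per_gene = c(5, 9),
                       exon_length = c(120, 400),
                       intron_length = c(150, 600),
                       intergenic_gap = c(1200, 3000),
                       n_circs = 500,
                       origin_mix = c(exonic = 0.795, intronic = 0.049,
                                      intergenic = 0.156),
                       canonical_fraction = 0.117,
                       planted_flank_fraction = 0.02,
                       flank_repeat_length = 18,
                       flank_window = 1000,
                       mite_fraction = 0.012,
                       tissues = c("leaf", "root"),
                       conditions = c("CK", "Na"),
                       replicates = 2,
                       tissue_pattern_probs = c(both = 0.17,
                                                first_only = 0.13,
                                                second_only = 0.70),
                       base_mean_log = log(8), base_mean_sd = 0.7,
                       dispersion = 0.2,
                       de_fraction = 0.2, de_fold = 4,
                       de_second_tissue_bias = 0.8,
                       plant_dominant = FALSE, dominant_fold = 4,
                       read_length = 150,
                       lib_size_meanlog = log(5e7), lib_size_sdlog = 0.1,
                       gene_abund_noise_sd = 0.35,
                       n_mirnas = 20, mirna_length = 21) {
  if (abs(sum(origin_mix) - 1) > 1e-8) stop("origin_mix must sum to 1")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# sample one element from a vector, immune to the sample(x, 1) scalar rule
.pick1 <- function(v) v[sample.int(length(v), 1L)]

.rand_seq <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

.noncanonical_labels <- data.frame(
  label = c("GA/AG", "CT/AT", "AT/AG", "CT/TC", "CT/AG"),
  weight = c(115, 113, 104, 95, 75),
  stringsAsFactors = FALSE)

.draw_noncanonical <- function() {
  # half the mass on the recurrent non-canonical labels, half on random pairs
  if (stats::runif(1) < 0.5) {
    lbl <- sample(.noncanonical_labels$label, 1,
                  prob = .noncanonical_labels$weight)
  } else {
    repeat {
      lbl <- paste0(paste(.rand_seq(2), collapse = ""), "/",
                    paste(.rand_seq(2), collapse = ""))
      if (!lbl %in% c("GT/AG", "CT/AC")) break
    }
  }
  lbl
}

#' Simulate a truth-labelled circRNA dataset
#'
#' Generates a genome (chromosomes plus unanchored scaffolds), multi-exon
#' gene models, a circRNA population with known origins and splice signals
#' (boundary dinucleotides are overwritten in the genome after placement, so
#' signal truth is exact by construction), planted inverted-repeat flanks for
#' a designated subset (placed in dedicated intergenic zones isolated from
#' every other circRNA's flank windows, so detection truth is unambiguous at
#' the configured window), MITE intervals, negative-binomial junction counts
#' per sample, per-sample library statistics, fabricated parental-gene
#' abundances, and a mature-miRNA set. All outputs are a deterministic
#' function of the configuration (including its seed).
#'
#' @param config A [sim_config()] list.
#' @return List with `genome` ([Biostrings::DNAStringSet]), `genes` (exon
#'   table), `circs` (circ table of all simulated circRNAs),
#'   `junction_tables` (named list per sample; only circRNAs with non-zero
#'   counts appear), `sample_stats`, `counts` (full truth count matrix),
#'   `gene_abundance` (matrix), `mites`, `mirnas` (named character vector),
#'   `truth` (per-circ truth labels), `config`.
#' @export
simulate_circ_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  chrom_names <- paste0("Chr", seq_len(cfg$n_chromosomes))
  chrom_len <- rep_len(cfg$chromosome_length, cfg$n_chromosomes)
  names(chrom_len) <- chrom_names
  seqs <- lapply(chrom_len, .rand_seq)

  n <- cfg$n_circs
  n_planted <- round(cfg$planted_flank_fraction * n)
  n_ex <- round(cfg$origin_mix[["exonic"]] * n)
  n_in <- round(cfg$origin_mix[["intronic"]] * n)
  n_ig <- n - n_ex - n_in
  if (n_planted > n_ig) {
    stop("planted_flank_fraction exceeds the intergenic quota")
  }

  ## ---- lay out genes and planted-flank zones along the chromosomes ----
  rng <- function(r) if (r[1] >= r[2]) r[1] else .pick1(r[1]:r[2])
  elements <- sample(c(rep("gene", cfg$n_genes), rep("zone", n_planted)))
  exon_rows <- list()
  gaps <- list()        # free intergenic intervals (chrom, start, end)
  zones <- list()       # dedicated planted-flank zones
  gi <- 0L
  ei <- 1L
  margin_zone <- 200L
  for (ch in chrom_names) {
    pos <- 1L
    repeat {
      if (ei > length(elements)) break
      gap <- rng(cfg$intergenic_gap)
      if (elements[ei] == "gene") {
        k <- rng(cfg$exons_per_gene)
        ex_len <- vapply(seq_len(k), function(x) rng(cfg$exon_length), 1L)
        in_len <- if (k > 1) {
          vapply(seq_len(k - 1), function(x) rng(cfg$intron_length), 1L)
        } else integer(0)
        span <- sum(ex_len) + sum(in_len)
        if (pos + gap + span + 1000L > chrom_len[[ch]]) break
        gaps[[length(gaps) + 1L]] <- c(ch, pos, pos + gap - 1L)
        gstart <- pos + gap
        gi <- gi + 1L
        gid <- sprintf("g%04d", gi)
        strand <- sample(c("+", "-"), 1)
        s <- gstart
        for (x in seq_len(k)) {
          exon_rows[[length(exon_rows) + 1L]] <- data.frame(
            gene_id = gid, chrom = ch, strand = strand,
            genomic_index = x, start = s, end = s + ex_len[x] - 1L,
            stringsAsFactors = FALSE)
          s <- s + ex_len[x] + (if (x < k) in_len[x] else 0L)
        }
        pos <- gstart + span
      } else {
        circ_len <- .pick1(300:600)
        zone_len <- 2L * cfg$flank_window + 2L * margin_zone + circ_len
        if (pos + gap + zone_len + 1000L > chrom_len[[ch]]) break
        zstart <- pos + gap
        zones[[length(zones) + 1L]] <- list(
          chrom = ch, start = zstart, end = zstart + zone_len - 1L,
          circ_start = zstart + cfg$flank_window + margin_zone,
          circ_end = zstart + cfg$flank_window + margin_zone + circ_len - 1L)
        pos <- zstart + zone_len
      }
      ei <- ei + 1L
    }
    if (pos < chrom_len[[ch]] - 200L) {
      gaps[[length(gaps) + 1L]] <- c(ch, pos, chrom_len[[ch]] - 200L)
    }
  }
  if (ei <= length(elements)) {
    stop("genome too small to place all genes and planted-flank zones; ",
         "increase chromosome_length or n_chromosomes, or reduce n_genes ",
         sprintf("(placed %d of %d elements)", ei - 1L, length(elements)))
  }
  genes <- do.call(rbind, exon_rows)
  genes <- do.call(rbind, lapply(split(genes, genes$gene_id), function(g) {
    g <- g[order(g$start), ]
    g$exon_rank <- if (g$strand[1] == "-") rev(seq_len(nrow(g))) else
      seq_len(nrow(g))
    g
  }))
  rownames(genes) <- NULL
  genes <- genes[, c("gene_id", "chrom", "strand", "exon_rank",
                     "start", "end", "genomic_index")]

  ## ---- place circRNAs ----
  used_start <- character(0)
  used_end <- character(0)
  circ_rows <- list()
  gene_split <- split(genes, genes$gene_id)
  gene_ids <- names(gene_split)
  add_circ <- function(ch, s, e, origin, parent) {
    circ_rows[[length(circ_rows) + 1L]] <<- data.frame(
      chrom = ch, start = s, end = e, origin = origin,
      parent_gene = parent, stringsAsFactors = FALSE)
    used_start <<- c(used_start, paste0(ch, ":", s))
    used_end <<- c(used_end, paste0(ch, ":", e))
  }
  try_place <- function(kind) {
    if (kind == "exonic") {
      g <- gene_split[[.pick1(gene_ids)]]
      g <- g[order(g$start), ]
      k <- nrow(g)
      a <- .pick1(seq_len(k))
      b <- .pick1(a:k)
      s <- g$start[a]; e <- g$end[b]
      ch <- g$chrom[1]
      if (paste0(ch, ":", s) %in% used_start) return(FALSE)
      if (paste0(ch, ":", e) %in% used_end) return(FALSE)
      add_circ(ch, s, e, "exonic", g$gene_id[1])
    } else if (kind == "intronic") {
      g <- gene_split[[.pick1(gene_ids)]]
      g <- g[order(g$start), ]
      if (nrow(g) < 2) return(FALSE)
      ii <- .pick1(seq_len(nrow(g) - 1))
      istart <- g$end[ii] + 1L
      iend <- g$start[ii + 1] - 1L
      ilen <- iend - istart + 1L
      if (ilen < 80L) return(FALSE)
      maxlen <- ilen - 20L
      len <- .pick1(50:min(maxlen, 500L))
      s <- istart + 10L + .pick1(0:(maxlen - len))
      e <- s + len - 1L
      ch <- g$chrom[1]
      if (paste0(ch, ":", s) %in% used_start) return(FALSE)
      if (paste0(ch, ":", e) %in% used_end) return(FALSE)
      add_circ(ch, s, e, "intronic", g$gene_id[1])
    } else {
      gp <- gaps[[.pick1(seq_along(gaps))]]
      ch <- gp[1]
      lo <- as.integer(gp[2]) + 50L
      hi <- as.integer(gp[3]) - 50L
      if (hi - lo + 1L < 260L) return(FALSE)
      len <- .pick1(200:min(1000L, hi - lo + 1L - 10L))
      s <- .pick1(lo:(hi - len + 1L))
      e <- s + len - 1L
      if (paste0(ch, ":", s) %in% used_start) return(FALSE)
      if (paste0(ch, ":", e) %in% used_end) return(FALSE)
      add_circ(ch, s, e, "intergenic", NA_character_)
    }
    TRUE
  }
  place_all <- function(kind, target) {
    placed <- 0L
    attempts <- 0L
    while (placed < target) {
      attempts <- attempts + 1L
      if (attempts > 500L * max(target, 1L)) {
        stop("could not place all ", kind, " circRNAs; the genome or gene ",
             "complement is too small for n_circs = ", n)
      }
      if (try_place(kind)) placed <- placed + 1L
    }
  }
  place_all("exonic", n_ex)
  place_all("intronic", n_in)
  # planted intergenic circs occupy their dedicated zones
  for (z in zones) {
    add_circ(z$chrom, z$circ_start, z$circ_end, "intergenic", NA_character_)
  }
  place_all("intergenic", n_ig - n_planted)

  circs <- do.call(rbind, circ_rows)
  circs$circ_id <- circ_id(circs$chrom, circs$start, circs$end)
  circs$planted_flank <- FALSE
  if (n_planted > 0) {
    zone_ids <- vapply(zones, function(z)
      circ_id(z$chrom, z$circ_start, z$circ_end), character(1))
    circs$planted_flank <- circs$circ_id %in% zone_ids
  }

  ## ---- plant splice signals (overwrite boundary dinucleotides) ----
  n_canon <- round(cfg$canonical_fraction * n)
  canon_idx <- sample(n, n_canon)
  pair <- character(n)
  for (i in seq_len(n)) {
    pair[i] <- if (i %in% canon_idx) {
      sample(c("GT/AG", "CT/AC"), 1)
    } else .draw_noncanonical()
  }
  donor <- substr(pair, 1, 2)
  acceptor <- substr(pair, 4, 5)
  for (i in seq_len(n)) {
    ch <- circs$chrom[i]
    seqs[[ch]][circs$start[i] - 2L] <- substr(acceptor[i], 1, 1)
    seqs[[ch]][circs$start[i] - 1L] <- substr(acceptor[i], 2, 2)
    seqs[[ch]][circs$end[i] + 1L] <- substr(donor[i], 1, 1)
    seqs[[ch]][circs$end[i] + 2L] <- substr(donor[i], 2, 2)
  }
  circs$donor <- donor
  circs$acceptor <- acceptor
  circs$pair_label <- pair
  circs$canonical <- pair %in% c("GT/AG", "CT/AC")

  ## ---- plant inverted-repeat flanks in the dedicated zones ----
  L <- cfg$flank_repeat_length
  for (z in zones) {
    s_rep <- .rand_seq(L)
    off_u <- .pick1(100:(cfg$flank_window - L - 100L))
    off_d <- .pick1(100:(cfg$flank_window - L - 100L))
    up_pos <- z$circ_start - off_u - L       # repeat occupies [up_pos+1 .. up_pos+L]
    down_pos <- z$circ_end + off_d
    seqs[[z$chrom]][(up_pos + 1L):(up_pos + L)] <- s_rep
    rc <- rev(chartr("ACGT", "TGCA", s_rep))
    seqs[[z$chrom]][(down_pos + 1L):(down_pos + L)] <- rc
  }

  ## ---- MITE intervals ----
  n_mite <- round(cfg$mite_fraction * n)
  mite_idx <- sample(n, n_mite)
  mite_rows <- list()
  for (i in mite_idx) {
    mite_rows[[length(mite_rows) + 1L]] <- data.frame(
      chrom = circs$chrom[i], start = circs$start[i] - 400L,
      end = circs$start[i] - 320L, stringsAsFactors = FALSE)
    mite_rows[[length(mite_rows) + 1L]] <- data.frame(
      chrom = circs$chrom[i], start = circs$end[i] + 320L,
      end = circs$end[i] + 400L, stringsAsFactors = FALSE)
  }
  # a few background MITEs, kept clear of every circRNA's flank windows
  boundary_pos <- data.frame(chrom = rep(circs$chrom, 2),
                             pos = c(circs$start, circs$end))
  for (b in seq_len(3)) {
    for (attempt in seq_len(200)) {
      ch <- sample(chrom_names, 1)
      p <- .pick1(2000:(chrom_len[[ch]] - 2000L))
      near <- boundary_pos$chrom == ch &
        abs(boundary_pos$pos - p) < cfg$flank_window + 200L
      if (!any(near)) {
        mite_rows[[length(mite_rows) + 1L]] <- data.frame(
          chrom = ch, start = p, end = p + 80L, stringsAsFactors = FALSE)
        break
      }
    }
  }
  mites <- if (length(mite_rows)) do.call(rbind, mite_rows) else
    data.frame(chrom = character(), start = integer(), end = integer())
  # truth flag: both flank windows of a circ overlap some MITE interval
  circs$mite_both_flanks <- vapply(seq_len(n), function(i) {
    m <- mites[mites$chrom == circs$chrom[i], , drop = FALSE]
    if (!nrow(m)) return(FALSE)
    up_ok <- any(m$end >= circs$start[i] - cfg$flank_window &
                   m$start <= circs$start[i] - 1L)
    down_ok <- any(m$end >= circs$end[i] + 1L &
                     m$start <= circs$end[i] + cfg$flank_window)
    up_ok && down_ok
  }, logical(1))

  ## ---- expression model ----
  tissues <- cfg$tissues
  conds <- cfg$conditions
  reps <- cfg$replicates
  base <- stats::rlnorm(n, cfg$base_mean_log, cfg$base_mean_sd)
  tf <- matrix(1, nrow = n, ncol = length(tissues),
               dimnames = list(circs$circ_id, tissues))
  pattern <- rep("both", n)
  if (length(tissues) == 2) {
    p <- cfg$tissue_pattern_probs
    pattern <- sample(c("both", "first_only", "second_only"), n,
                      replace = TRUE, prob = p[c("both", "first_only",
                                                 "second_only")])
    tf[pattern == "first_only", 2] <- 0
    tf[pattern == "second_only", 1] <- 0
    expressed <- tf > 0
    tf[expressed] <- tf[expressed] * stats::rlnorm(sum(expressed), 0, 0.3)
  }

  if (cfg$plant_dominant) {
    by_gene <- split(seq_len(n), circs$parent_gene)
    circs$planted_dominant <- FALSE
    for (ii in by_gene) {
      if (length(ii) < 2) next
      pick <- .pick1(ii)
      base[pick] <- cfg$dominant_fold * max(base[setdiff(ii, pick)])
      circs$planted_dominant[pick] <- TRUE
    }
  }

  n_de <- round(cfg$de_fraction * n)
  de_idx <- sample(n, n_de)
  circs$de_tissue <- NA_character_
  circs$de_direction <- NA_character_
  circs$de_fold <- 1
  for (i in de_idx) {
    expressed_t <- tissues[tf[i, ] > 0]
    if (!length(expressed_t)) next
    t_pick <- if (length(expressed_t) == 1) expressed_t else {
      if (stats::runif(1) < cfg$de_second_tissue_bias)
        expressed_t[length(expressed_t)] else expressed_t[1]
    }
    dir <- sample(c("up", "down"), 1)
    circs$de_tissue[i] <- t_pick
    circs$de_direction[i] <- dir
    circs$de_fold[i] <- if (dir == "up") cfg$de_fold else 1 / cfg$de_fold
  }

  sample_grid <- expand.grid(rep = seq_len(reps), condition = conds,
                             tissue = tissues, stringsAsFactors = FALSE)
  sample_grid$sample_id <- sprintf("%s-%s%d", sample_grid$condition,
                                   toupper(substr(sample_grid$tissue, 1, 1)),
                                   sample_grid$rep)
  ns <- nrow(sample_grid)
  mapped <- round(stats::rlnorm(ns, cfg$lib_size_meanlog, cfg$lib_size_sdlog))
  total <- round(mapped / stats::runif(ns, 0.88, 0.93))
  sample_stats <- data.frame(sample_id = sample_grid$sample_id,
                             tissue = sample_grid$tissue,
                             condition = sample_grid$condition,
                             replicate = sample_grid$rep,
                             total_reads = total, mapped_reads = mapped,
                             read_length = cfg$read_length,
                             stringsAsFactors = FALSE)

  counts <- matrix(0L, nrow = n, ncol = ns,
                   dimnames = list(circs$circ_id, sample_stats$sample_id))
  stress <- conds[length(conds)]
  for (j in seq_len(ns)) {
    t_j <- sample_stats$tissue[j]
    c_j <- sample_stats$condition[j]
    depth <- mapped[j] / 5e7
    fold <- ifelse(!is.na(circs$de_tissue) & circs$de_tissue == t_j &
                     c_j == stress, circs$de_fold, 1)
    mu <- base * tf[, t_j] * fold * depth
    counts[, j] <- if (cfg$dispersion > 0) {
      stats::rnbinom(n, mu = mu, size = 1 / cfg$dispersion)
    } else {
      stats::rpois(n, mu)
    }
  }

  origin_label <- c(exonic = "exon", intronic = "intron",
                    intergenic = "intergenic_region")
  gene_strand <- vapply(gene_split, function(g) g$strand[1], character(1))
  circ_strand <- ifelse(is.na(circs$parent_gene), "unknown",
                        gene_strand[circs$parent_gene])
  circ_table <- data.frame(circ_id = circs$circ_id, chrom = circs$chrom,
                           start = circs$start, end = circs$end,
                           strand = circ_strand,
                           reported_type = origin_label[circs$origin],
                           gene_id = circs$parent_gene,
                           stringsAsFactors = FALSE)
  junction_tables <- lapply(sample_stats$sample_id, function(s) {
    keep <- counts[, s] > 0
    t <- circ_table[keep, , drop = FALSE]
    t$junction_reads <- counts[keep, s]
    rownames(t) <- NULL
    t[, c("circ_id", "chrom", "start", "end", "strand", "junction_reads",
          "reported_type", "gene_id")]
  })
  names(junction_tables) <- sample_stats$sample_id

  ## ---- parental gene abundances (circ abundance x noise) ----
  sr <- counts
  for (j in seq_len(ns)) {
    sr[, j] <- srpbm(counts[, j], mapped[j], cfg$read_length)
  }
  gene_abund <- matrix(stats::rlnorm(length(gene_ids) * ns, log(5), 1),
                       nrow = length(gene_ids), ncol = ns,
                       dimnames = list(gene_ids, sample_stats$sample_id))
  genic <- !is.na(circs$parent_gene)
  for (g in unique(circs$parent_gene[genic])) {
    members <- circs$circ_id[genic & circs$parent_gene == g]
    prof <- colMeans(sr[members, , drop = FALSE])
    gene_abund[g, ] <- (prof + 0.05) *
      stats::rlnorm(ns, 0, cfg$gene_abund_noise_sd)
  }

  ## ---- miRNAs ----
  mirnas <- vapply(seq_len(cfg$n_mirnas), function(i)
    paste(.rand_seq(cfg$mirna_length), collapse = ""), character(1))
  names(mirnas) <- sprintf("sim-miR-%02d", seq_len(cfg$n_mirnas))

  genome_seqs <- vapply(seqs, paste, character(1), collapse = "")
  if (cfg$n_scaffolds > 0) {
    scaf <- vapply(seq_len(cfg$n_scaffolds), function(i)
      paste(.rand_seq(rep_len(cfg$scaffold_length,
                              cfg$n_scaffolds)[i]), collapse = ""),
      character(1))
    names(scaf) <- sprintf("scaffold%02d", seq_len(cfg$n_scaffolds))
    genome_seqs <- c(genome_seqs, scaf)
  }
  genome <- Biostrings::DNAStringSet(genome_seqs)

  truth_cols <- c("circ_id", "chrom", "start", "end", "origin",
                  "parent_gene", "donor", "acceptor", "pair_label",
                  "canonical", "planted_flank", "mite_both_flanks",
                  "de_tissue", "de_direction", "de_fold")
  if (cfg$plant_dominant) truth_cols <- c(truth_cols, "planted_dominant")
  truth <- circs[, truth_cols]
  truth$tissue_pattern <- pattern
  truth$base_mean <- base
  rownames(truth) <- NULL

  list(genome = genome,
       genes = genes[, c("gene_id", "chrom", "strand", "exon_rank",
                         "start", "end")],
       circs = circ_table,
       junction_tables = junction_tables,
       sample_stats = sample_stats,
       counts = counts,
       gene_abundance = gene_abund,
       mites = mites,
       mirnas = mirnas,
       truth = truth,
       config = cfg)
}

#' Bundled deterministic fixtures
#'
#' Small, fully reproducible datasets used throughout the test suite. Each
#' fixture carries its own fixed seed as part of its definition:
#' * `tiny` — 2 chromosomes, 10 genes, 12 circRNAs; every stage runs in
#'   well under a second.
#' * `paper_mix` — 500 circRNAs at the default origin and signal mixes
#'   (79.5/4.9/15.6 origins, 11.7% canonical signals), 2 tissues x 2
#'   conditions x 2 replicates.
#' * `null_de` — one tissue, no differentially expressed circRNAs in truth.
#' * `de_bench` — one tissue, 500 circRNAs, 20% differentially expressed at
#'   4-fold, NB dispersion 0.2, 2 replicates per condition; the benchmark
#'   for DE-caller sensitivity and empirical FDR.
#'
#' @param name One of `"tiny"`, `"paper_mix"`, `"null_de"`, `"de_bench"`.
#' @return A simulated dataset (see [simulate_circ_dataset()]).
#' @export
make_fixture <- function(name) {
  cfg <- switch(name,
    tiny = sim_config(seed = 101, n_chromosomes = 2,
                      chromosome_length = 80000, n_scaffolds = 1,
                      scaffold_length = 8000, n_genes = 10,
                      exons_per_gene = c(3, 6), n_circs = 12,
                      planted_flank_fraction = 1 / 12,
                      mite_fraction = 1 / 12),
    paper_mix = sim_config(seed = 202),
    null_de = sim_config(seed = 303, n_chromosomes = 2, n_genes = 80,
                         n_circs = 300, tissues = "root",
                         de_fraction = 0),
    de_bench = sim_config(seed = 404, tissues = "root",
                          n_circs = 500, de_fraction = 0.2, de_fold = 4,
                          dispersion = 0.2, replicates = 2,
                          planted_flank_fraction = 0,
                          mite_fraction = 0),
    stop("unknown fixture name: ", name)
  )
  simulate_circ_dataset(cfg)
}

#' Write a simulated dataset to standard-format files
#'
#' Emits genome FASTA, gene-model GFF3, one junction table per sample
#' (ciri2 dialect), sample statistics TSV, MITE BED (0-based half-open),
#' miRNA FASTA, gene-abundance TSV and the truth table TSV.
#'
#' @param sim Output of [simulate_circ_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of written paths.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, p)
  paths <- c(paths, p)
  p <- file.path(dir, "genes.gff3")
  write_gene_models(sim$genes, p)
  paths <- c(paths, p)
  for (s in names(sim$junction_tables)) {
    t <- sim$junction_tables[[s]]
    p <- file.path(dir, paste0("junctions_", s, ".tsv"))
    write_junction_table(t, p, dialect = "ciri2")
    paths <- c(paths, p)
  }
  p <- file.path(dir, "sample_stats.tsv")
  utils::write.table(sim$sample_stats, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  if (nrow(sim$mites)) {
    p <- file.path(dir, "mites.bed")
    utils::write.table(data.frame(sim$mites$chrom, sim$mites$start - 1L,
                                  sim$mites$end),
                       p, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "mirnas.fa")
  writeLines(paste0(">", names(sim$mirnas), "\n", unname(sim$mirnas)), p)
  paths <- c(paths, p)
  p <- file.path(dir, "gene_abundance.tsv")
  utils::write.table(data.frame(gene_id = rownames(sim$gene_abundance),
                                sim$gene_abundance, check.names = FALSE),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
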