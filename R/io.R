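#' Canonical circRNA identifier
#'
#' Builds the conventional `"<chrom>:<start>|<end>"` identifier used for
#' back-splice junctions (1-based inclusive coordinates on both ends).
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive back-splice coordinates.
#' @return Character vector of identifiers.
#' @export
#' @examples
#' circ_id("Chr2", 1524236, 1525777)
circ_id <- function(chrom, start, end) {
  sprintf("%s:%d|%d", chrom, as.integer(start), as.integer(end))
}

.valid_strands <- c("+", "-", "unknown")

.normalize_strand <- function(strand) {
  strand <- as.character(strand)
  strand[is.na(strand) | strand %in% c(".", "", "?", "*")] <- "unknown"
  bad <- !strand %in% .valid_strands
  if (any(bad)) {
    stop("invalid strand value(s): ", paste(unique(strand[bad]), collapse = ", "))
  }
  strand
}

.validate_circs <- function(circs, context = "junction table") {
  if (anyNA(circs$start) || anyNA(circs$end)) {
    bad <- which(is.na(circs$start) | is.na(circs$end))
    stop(sprintf("%s: malformed coordinate at line %d", context, bad[1]))
  }
  if (any(circs$start > circs$end)) {
    bad <- which(circs$start > circs$end)
    stop(sprintf("%s: start > end at line %d (%s)", context, bad[1],
                 circs$chrom[bad[1]]))
  }
  if (any(circs$start < 1)) {
    bad <- which(circs$start < 1)
    stop(sprintf("%s: non-positive coordinate at line %d", context, bad[1]))
  }
  if (any(circs$junction_reads < 0, na.rm = TRUE)) {
    stop(context, ": negative junction read count")
  }
  key <- paste(circs$chrom, circs$start, circs$end)
  if (anyDuplicated(key)) {
    stop(context, ": duplicate (chrom,start,end) row: ",
         key[duplicated(key)][1])
  }
  invisible(circs)
}

#' Read a per-sample back-splice junction table
#'
#' Two dialects are supported. `ciri2` is a tab-separated file with a header
#' and columns `circRNA_ID, chr, circRNA_start, circRNA_end, junction_reads,
#' circRNA_type, gene_id, strand` (1-based inclusive coordinates, as in the
#' `Chr2:1524236|1525777` identifier convention). `bedlike` is header-less
#' BED6 (`chrom, start, end, name, score, strand`) with 0-based half-open
#' coordinates and the junction-read count in the score column; coordinates
#' are converted to 1-based inclusive on read.
#'
#' Duplicate `(chrom, start, end)` rows within one sample are an error, as is
#' any row with `start > end` or a non-numeric coordinate.
#'
#' @param path Path to the table.
#' @param dialect `"ciri2"` (default) or `"bedlike"`.
#' @return A data.frame with columns `circ_id`, `chrom`, `start`, `end`,
#'   `strand`, `junction_reads`, `reported_type`, `gene_id`.
#' @export
read_junction_table <- function(path, dialect = c("ciri2", "bedlike")) {
  dialect <- match.arg(dialect)
  if (dialect == "ciri2") {
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character", check.names = FALSE)
    if (nrow(raw) == 0) {
      return(.empty_circ_table())
    }
    start <- suppressWarnings(as.integer(raw[[3]]))
    end <- suppressWarnings(as.integer(raw[[4]]))
    reads <- suppressWarnings(as.integer(raw[[5]]))
    circs <- data.frame(
      circ_id = circ_id(raw[[2]], start, end),
      chrom = raw[[2]],
      start = start,
      end = end,
      strand = .normalize_strand(raw[[8]]),
      junction_reads = reads,
      reported_type = raw[[6]],
      gene_id = ifelse(raw[[7]] %in% c("", ".", "n/a", "NA"), NA_character_, raw[[7]]),
      stringsAsFactors = FALSE
    )
  } else {
    raw <- tryCatch(
      utils::read.delim(path, header = FALSE, sep = "\t",
                        colClasses = "character"),
      error = function(e) NULL
    )
    if (is.null(raw) || nrow(raw) == 0) {
      return(.empty_circ_table())
    }
    start0 <- suppressWarnings(as.integer(raw[[2]]))
    end <- suppressWarnings(as.integer(raw[[3]]))
    circs <- data.frame(
      circ_id = circ_id(raw[[1]], start0 + 1L, end),
      chrom = raw[[1]],
      start = start0 + 1L,
      end = end,
      strand = .normalize_strand(raw[[6]]),
      junction_reads = suppressWarnings(as.integer(raw[[5]])),
      reported_type = NA_character_,
      gene_id = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  .validate_circs(circs, context = path)
}

.empty_circ_table <- function() {
  data.frame(circ_id = character(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             junction_reads = integer(), reported_type = character(),
             gene_id = character(), stringsAsFactors = FALSE)
}

#' Write a junction table
#'
#' Inverse of [read_junction_table()]; round trips are field-identical for
#' both dialects (modulo fields a dialect cannot carry).
#'
#' @param circs Circ table as returned by [read_junction_table()].
#' @param path Output path.
#' @param dialect `"ciri2"` or `"bedlike"`.
#' @export
write_junction_table <- function(circs, path, dialect = c("ciri2", "bedlike")) {
  dialect <- match.arg(dialect)
  if (dialect == "ciri2") {
    out <- data.frame(
      circRNA_ID = circs$circ_id,
      chr = circs$chrom,
      circRNA_start = circs$start,
      circRNA_end = circs$end,
      junction_reads = circs$junction_reads,
      circRNA_type = ifelse(is.na(circs$reported_type), ".", circs$reported_type),
      gene_id = ifelse(is.na(circs$gene_id), ".", circs$gene_id),
      strand = circs$strand,
      stringsAsFactors = FALSE
    )
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    out <- data.frame(
      chrom = circs$chrom,
      start = circs$start - 1L,
      end = circs$end,
      name = circs$circ_id,
      score = circs$junction_reads,
      strand = ifelse(circs$strand == "unknown", ".", circs$strand),
      stringsAsFactors = FALSE
    )
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Merge unanchored scaffolds into a ChrUn pseudo-chromosome
#'
#' Scaffolds (identified by a name pattern) are concatenated, separated by
#' runs of `N`, into a single pseudo-chromosome; annotation coordinates on
#' scaffolds are lifted by the scaffold offsets. The returned scaffold map
#' records, for each scaffold, its offset into the merged sequence and its
#' length, so positions can be lifted and inverse-lifted exactly.
#'
#' The default 100-nt `N` spacer ensures sequence-window computations cannot
#' silently span two scaffolds; windows overlapping spacer `N`s should be
#' truncated at the `N` boundary (see [scan_flanks()]).
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param annotation Optional exon table (as from [read_gene_models()]) whose
#'   `chrom` entries matching scaffolds are lifted onto the merged chromosome.
#' @param spacer_length Number of `N` bases between consecutive scaffolds.
#' @param scaffold_pattern Regular expression identifying scaffold names.
#' @param chrun_name Name of the merged pseudo-chromosome.
#' @return A list with `genome` (scaffolds replaced by one merged entry),
#'   `annotation` (lifted, or `NULL`), and `scaffold_map` (data.frame with
#'   `scaffold`, `offset`, `length`).
#' @export
merge_unanchored <- function(genome, annotation = NULL, spacer_length = 100,
                             scaffold_pattern = "^[Ss]caffold",
                             chrun_name = "ChrUn") {
  stopifnot(methods::is(genome, "DNAStringSet"))
  nm <- names(genome)
  is_scaf <- grepl(scaffold_pattern, nm)
  if (!any(is_scaf)) {
    return(list(genome = genome, annotation = annotation,
                scaffold_map = data.frame(scaffold = character(),
                                          offset = integer(),
                                          length = integer())))
  }
  if (chrun_name %in% nm[!is_scaf]) {
    stop("merged chromosome name '", chrun_name,
         "' collides with an existing chromosome")
  }
  scafs <- genome[is_scaf]
  lens <- Biostrings::width(scafs)
  # offset of scaffold i = total merged length before it (incl. spacers)
  offsets <- cumsum(c(0L, utils::head(lens + spacer_length, -1L)))
  map <- data.frame(scaffold = names(scafs), offset = as.integer(offsets),
                    length = as.integer(lens), stringsAsFactors = FALSE)
  spacer <- paste(rep("N", spacer_length), collapse = "")
  merged <- Biostrings::DNAStringSet(
    paste(as.character(scafs), collapse = spacer))
  names(merged) <- chrun_name
  out_genome <- c(genome[!is_scaf], merged)
  if (!is.null(annotation)) {
    idx <- match(annotation$chrom, map$scaffold)
    hit <- !is.na(idx)
    annotation$start[hit] <- annotation$start[hit] + map$offset[idx[hit]]
    annotation$end[hit] <- annotation$end[hit] + map$offset[idx[hit]]
    annotation$chrom[hit] <- chrun_name
  }
  list(genome = out_genome, annotation = annotation, scaffold_map = map)
}

#' Lift a scaffold position onto the merged pseudo-chromosome
#'
#' @param scaffold_map Map from [merge_unanchored()].
#' @param scaffold Scaffold name(s).
#' @param pos 1-based position(s) on the scaffold.
#' @return 1-based position(s) on the merged chromosome.
#' @export
lift_position <- function(scaffold_map, scaffold, pos) {
  idx <- match(scaffold, scaffold_map$scaffold)
  if (anyNA(idx)) stop("unknown scaffold: ", scaffold[is.na(idx)][1])
  if (any(pos < 1 | pos > scaffold_map$length[idx])) {
    stop("position outside scaffold")
  }
  scaffold_map$offset[idx] + as.integer(pos)
}

#' Inverse lift: merged-chromosome position back to (scaffold, position)
#'
#' @param scaffold_map Map from [merge_unanchored()].
#' @param pos 1-based position(s) on the merged chromosome.
#' @return data.frame with `scaffold` and `pos`; positions falling in spacer
#'   `N` runs are an error.
#' @export
unlift_position <- function(scaffold_map, pos) {
  pos <- as.integer(pos)
  idx <- findInterval(pos, scaffold_map$offset + 1L)
  if (any(idx == 0L)) stop("position before first scaffold")
  local <- pos - scaffold_map$offset[idx]
  if (any(local > scaffold_map$length[idx])) {
    stop("position falls in spacer padding")
  }
  data.frame(scaffold = scaffold_map$scaffold[idx], pos = local,
             stringsAsFactors = FALSE)
}

#' Fetch a genomic sequence slice
#'
#' Inclusive 1-based slice; `strand = "-"` returns the reverse complement.
#' Out-of-bounds requests are an error: callers that need clamping (e.g.
#' flank windows at chromosome edges) must clamp explicitly.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` (default) or `"-"`.
#' @return Upper-case nucleotide string.
#' @export
fetch_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (start < 1 || end > len || start > end) {
    stop(sprintf("out-of-bounds slice %s:%d-%d (length %d)",
                 chrom, start, end, len))
  }
  s <- toupper(as.character(Biostrings::subseq(genome[[chrom]], start, end)))
  if (identical(strand, "-")) s <- revcomp(s) else s
}

#' Reverse complement of a nucleotide string
#'
#' Plain-string reverse complement over the `ACGTN` alphabet (`N` maps to
#' `N`). An involution: `revcomp(revcomp(s)) == s`.
#'
#' @param s Character vector of sequences.
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTNacgtn", "TGCANtgcan",
           paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene` and `exon` features (exons linked to genes through the
#' `Parent`/`ID` attribute chain, tolerating an intervening mRNA layer) into
#' a flat exon table. Exon rank is assigned in transcript orientation: rank 1
#' is the 5'-most exon of the gene, i.e. genomically first on `+` genes and
#' genomically last on `-` genes.
#'
#' @param path GFF3 file path.
#' @return data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `exon_rank`, `start`, `end`.
#' @export
read_gene_models <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  genes <- gff[type == "gene"]
  exons <- gff[type == "exon"]
  # map exon Parent -> gene: direct, or through an mRNA layer
  mrna <- gff[type %in% c("mRNA", "transcript")]
  mrna_parent <- stats::setNames(
    vapply(mrna$Parent, function(p) as.character(p)[1], character(1)),
    as.character(mrna$ID))
  gene_ids <- as.character(genes$ID)
  ex_parent <- vapply(exons$Parent, function(p) as.character(p)[1], character(1))
  resolved <- ifelse(ex_parent %in% gene_ids, ex_parent,
                     unname(mrna_parent[ex_parent]))
  keep <- !is.na(resolved)
  exons <- exons[keep]
  resolved <- resolved[keep]
  df <- data.frame(
    gene_id = resolved,
    chrom = as.character(GenomicRanges::seqnames(exons)),
    strand = as.character(GenomicRanges::strand(exons)),
    start = GenomicRanges::start(exons),
    end = GenomicRanges::end(exons),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$gene_id, df$start), ]
  df <- do.call(rbind, lapply(split(df, df$gene_id), function(g) {
    g$exon_rank <- if (g$strand[1] == "-") rev(seq_len(nrow(g))) else seq_len(nrow(g))
    g
  }))
  rownames(df) <- NULL
  df[, c("gene_id", "chrom", "strand", "exon_rank", "start", "end")]
}

#' Write gene models to GFF3
#'
#' Emits one `gene` feature per gene plus its `exon` children (Parent = gene
#' ID); round trips with [read_gene_models()].
#'
#' @param genes Exon table as from [read_gene_models()].
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (gid in unique(genes$gene_id)) {
    g <- genes[genes$gene_id == gid, ]
    g <- g[order(g$start), ]
    writeLines(sprintf("%s\tcircbsj\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom[1], min(g$start), max(g$end), g$strand[1], gid),
               con)
    writeLines(sprintf("%s\tcircbsj\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                       g$chrom, g$start, g$end, g$strand, gid, g$exon_rank, gid),
               con)
  }
  invisible(path)
}

#' Read MITE intervals from a BED file
#'
#' BED intervals (0-based half-open) are converted to the package's 1-based
#' inclusive convention at the boundary.
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_mite_bed <- function(path) {
  raw <- tryCatch(
    utils::read.delim(path, header = FALSE, sep = "\t",
                      colClasses = "character"),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  data.frame(chrom = raw[[1]],
             start = as.integer(raw[[2]]) + 1L,
             end = as.integer(raw[[3]]),
             stringsAsFactors = FALSE)
}

#' Read per-sample library statistics
#'
#' Tab-separated table with columns `sample_id`, `total_reads`,
#' `mapped_reads`, `read_length` (additional columns are preserved).
#'
#' @param path TSV path.
#' @return data.frame of sample statistics.
#' @export
read_sample_stats <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("sample_id", "total_reads", "mapped_reads", "read_length")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("sample stats missing column(s): ",
                            paste(missing, collapse = ", "))
  if (any(df$mapped_reads > df$total_reads)) {
    stop("mapped_reads exceeds total_reads")
  }
  if (any(df$read_length <= 0)) stop("read_length must be positive")
  df
}
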