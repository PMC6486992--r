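# In-code fixtures and independent oracles shared across the suite.

# memoised simulator fixtures (built once per test run)
.fixture_cache <- new.env(parent = emptyenv())
get_fixture <- function(name) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- make_fixture(name)
  }
  .fixture_cache[[name]]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a small hand-built genome: one 600-bp chromosome
toy_genome <- function(seq) {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- "Chr1"
  g
}

# hand-built two-gene annotation used by the classification tests:
# gA: plus strand, 5 exons of 50 bp spaced by 50-bp introns, starting at 101
# gB: minus strand, 3 exons of 40 bp spaced by 60-bp introns, starting at 1301
toy_genes <- function() {
  gA <- data.frame(gene_id = "gA", chrom = "Chr1", strand = "+",
                   exon_rank = 1:5,
                   start = 101 + (0:4) * 100,
                   end = 150 + (0:4) * 100)
  gB <- data.frame(gene_id = "gB", chrom = "Chr1", strand = "-",
                   exon_rank = 3:1,
                   start = 1301 + (0:2) * 100,
                   end = 1340 + (0:2) * 100)
  rbind(gA, gB)
}

toy_circs <- function(chrom, start, end) {
  data.frame(circ_id = circ_id(chrom, start, end), chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             strand = "unknown", junction_reads = 1L,
             reported_type = NA_character_, gene_id = NA_character_,
             stringsAsFactors = FALSE)
}

# brute-force oracle: all maximal reverse-complement matches >= min_len
# between up and down, by scanning every diagonal of up vs revcomp(down)
oracle_complementary <- function(up, down, min_len) {
  rd <- revcomp(down)
  u <- strsplit(up, "", fixed = TRUE)[[1]]
  r <- strsplit(rd, "", fixed = TRUE)[[1]]
  nu <- length(u)
  nr <- length(r)
  out <- list()
  for (d in (-(nr - 1)):(nu - 1)) {
    i <- max(1, 1 + d)
    j <- i - d
    run <- 0L
    while (i <= nu + 1) {
      match <- i <= nu && j <= nr && u[i] == r[j] && u[i] != "N"
      if (match) {
        run <- run + 1L
      } else {
        if (run >= min_len) {
          out[[length(out) + 1L]] <- c(i - run, i - 1L, j - run, j - 1L, run)
        }
        run <- 0L
      }
      i <- i + 1L
      j <- j + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(up_start = integer(), up_end = integer(),
                      down_start = integer(), down_end = integer(),
                      length = integer()))
  }
  m <- do.call(rbind, out)
  res <- data.frame(up_start = m[, 1], up_end = m[, 2],
                    down_start = nchar(down) - m[, 4] + 1L,
                    down_end = nchar(down) - m[, 3] + 1L,
                    length = m[, 5])
  res[order(res$up_start, res$up_end, res$down_start, res$down_end), ]
}

# direct combinatorial upper-tail hypergeometric: P(X >= k)
oracle_hyper <- function(k, K, N, n) {
  sum(vapply(k:min(K, n), function(j)
    choose(K, j) * choose(N - K, n - j), numeric(1))) / choose(N, n)
}

# enumeration oracle for the two-sided rank-sum p-value (tie-free data)
oracle_ranksum <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  W_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(length(pooled), n)
  Ws <- apply(combs, 2, function(idx)
    sum(rank(pooled)[idx]) - n * (n + 1) / 2)
  mu <- n * length(y) / 2
  mean(abs(Ws - mu) >= abs(W_obs - mu))
}
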