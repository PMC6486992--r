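perfect_window <- function(mirna) revcomp(mirna)

test_that("site scoring follows the plant penalty scheme", {
  set.seed(61)
  mi <- random_dna(21)
  w <- perfect_window(mi)
  expect_equal(score_site(mi, w)$score, 0)

  # one mismatch at position 15 (outside the doubled 2-13 region) -> 1.0
  w15 <- w
  # miRNA position 15 pairs with window position 21 - 15 + 1 = 7
  mi_chars <- strsplit(mi, "")[[1]]
  other <- setdiff(c("A", "C", "G", "T"),
                   c(chartr("ACGT", "TGCA", mi_chars[15]), "G"))[1]
  substring(w15, 7, 7) <- other
  s15 <- score_site(mi, w15)
  expect_equal(s15$score, 1.0)
  expect_equal(substring(s15$alignment, 15, 15), "x")

  # one G:U wobble at position 3 (seed-doubled) -> 0.5 * 2 = 1.0
  mi3 <- mi
  substring(mi3, 3, 3) <- "G"
  w3 <- perfect_window(mi3)
  substring(w3, 21 - 3 + 1, 21 - 3 + 1) <- "T"  # target U against miRNA G
  s3 <- score_site(mi3, w3)
  expect_equal(s3$score, 1.0)
  expect_equal(substring(s3$alignment, 3, 3), "o")

  # mismatch at position 2 is doubled
  w2 <- w
  substring(w2, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                   c(chartr("ACGT", "TGCA", mi_chars[2]),
                                     "G"))[1]
  expect_equal(score_site(mi, w2)$score, 2.0)

  expect_error(score_site("ACGTX", "ACGTA"), "non-nucleotide")
  expect_error(score_site(mi, random_dna(10)), "> 4 nt")
  # U accepted as T
  expect_equal(score_site(chartr("T", "U", mi), w)$score, 0)
})

test_that("Watson-Crick pair structure is preserved under strand mirroring", {
  # reading the duplex from the other ends (revcomp of both sequences, with
  # the miRNA/target roles swapped) pairs exactly the same physical bases at
  # each miRNA index, so the Watson-Crick pattern is unchanged; penalties
  # can still differ because G:U wobbles complement to A:C mismatches and
  # the seed-proximal doubling is anchored at the miRNA 5' end by design
  set.seed(62)
  for (k in 1:10) {
    mi <- random_dna(21)
    w <- random_dna(21)
    a1 <- score_site(mi, w)$alignment
    a2 <- score_site(revcomp(w), revcomp(mi))$alignment
    wc1 <- which(strsplit(a1, "")[[1]] == "|")
    wc2 <- which(strsplit(a2, "")[[1]] == "|")
    expect_equal(wc2, wc1)
  }
})

test_that("target scanning finds planted sites and respects the cutoff", {
  set.seed(63)
  mi <- random_dna(21)
  site <- perfect_window(mi)
  target <- paste0(random_dna(100), site, random_dna(80), site,
                   random_dna(100))
  hits <- scan_target(mi, target, cutoff = 4)
  planted_at <- c(101, 101 + 21 + 80)
  expect_equal(sort(hits$target_start[hits$score == 0]), planted_at)

  # a random target at cutoff 0 is almost surely empty
  expect_equal(nrow(scan_target(mi, random_dna(500), cutoff = 0)), 0)
  # target shorter than the miRNA -> empty
  expect_equal(nrow(scan_target(mi, random_dna(10))), 0)

  # lowering the cutoff never adds hits
  h4 <- scan_target(mi, target, cutoff = 4)
  h2 <- scan_target(mi, target, cutoff = 2)
  expect_true(all(h2$target_start %in% h4$target_start))
  expect_lte(nrow(h2), nrow(h4))

  # planted sites with a known penalty are found at exactly that score
  site1 <- site
  substring(site1, 7, 7) <- setdiff(c("A", "C", "G", "T"),
                                    c(substring(site, 7, 7), "G"))[1]
  target2 <- paste0(random_dna(60), site1, random_dna(60))
  h <- scan_target(mi, target2, cutoff = 4)
  expect_equal(nrow(h), 1)
  expect_equal(h$target_start, 61)
  expect_equal(h$score, 1.0)  # position 15 from the 5' end, undoubled
})

test_that("junction wrapping exposes sites spanning the back-splice", {
  set.seed(64)
  mi <- random_dna(20)
  site <- perfect_window(mi)
  # circ sequence: last 10 nt of the site at the end, first 10 at the start
  circ_seq_core <- paste0(substring(site, 11, 20), random_dna(150),
                          substring(site, 1, 10))
  g <- toy_genome(paste0(random_dna(50), circ_seq_core, random_dna(50)))
  circ <- toy_circs("Chr1", 51, 50 + nchar(circ_seq_core))
  unwrapped <- circ_sequence(circ[1, ], g)
  expect_equal(nrow(scan_target(mi, unwrapped, cutoff = 0)), 0)
  wrapped <- circ_sequence(circ[1, ], g, wrap = nchar(mi) - 1)
  expect_equal(nchar(wrapped), nchar(unwrapped) + nchar(mi) - 1)
  expect_equal(nrow(scan_target(mi, wrapped, cutoff = 0)), 1)
})

test_that("exonic circ sequences splice out introns", {
  genes <- toy_genes()
  g <- toy_genome(random_dna(1700))
  circ <- toy_circs("Chr1", 201, 350)  # exons 2-3 of gA
  oc <- classify_origin(circ, genes)
  s <- circ_sequence(circ[1, ], g, origin_call = oc[1, ], genes = genes)
  expect_equal(nchar(s), 100)  # two 50-bp exons, 50-bp intron removed
  expect_identical(s, paste0(fetch_sequence(g, "Chr1", 201, 250),
                             fetch_sequence(g, "Chr1", 301, 350)))
})

test_that("network assembly keeps DE circs and retained miRNAs", {
  circ_hits <- data.frame(query_mirna = c("m1", "m2", "m3"),
                          target_id = c("c1", "c1", "c2"))
  mrna_hits <- data.frame(query_mirna = c("m1", "m2", "m3"),
                          target_id = c("r1", "r2", "r3"))
  net <- build_network(circ_hits, mrna_hits, de_circs = "c1")
  # 1 circ hitting 2 miRNAs, each hitting 1 mRNA -> 4 edges
  expect_equal(nrow(net), 4)
  expect_equal(sum(net$edge_type == "circ-miRNA"), 2)
  expect_equal(sum(net$edge_type == "miRNA-mRNA"), 2)
  expect_false("m3" %in% c(net$source, net$target))

  # no DE circs -> empty network
  expect_equal(nrow(build_network(circ_hits, mrna_hits, character(0))), 0)

  # conservation of edge counts
  net2 <- build_network(circ_hits, mrna_hits, c("c1", "c2"))
  expect_equal(nrow(net2),
               nrow(unique(circ_hits)) +
                 sum(mrna_hits$query_mirna %in% circ_hits$query_mirna))
})
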