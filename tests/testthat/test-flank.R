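test_that("planted inverted repeats are found at the length threshold", {
  set.seed(21)
  S <- random_dna(18)
  up <- paste0(random_dna(60), S, random_dna(40))
  down <- paste0(random_dna(30), revcomp(S), random_dna(70))
  m <- find_complementary(up, down, min_len = 18)
  expect_equal(nrow(m), 1)
  expect_gte(m$length, 18)
  # the reported substrings really are reverse complements
  up_sub <- substring(up, m$up_start, m$up_end)
  down_sub <- substring(down, m$down_start, m$down_end)
  expect_identical(up_sub, revcomp(down_sub))

  # a 17-mer misses an 18-bp threshold
  S17 <- substring(S, 1, 17)
  up2 <- paste0(strrep("A", 60), S17, strrep("A", 40))
  down2 <- paste0(strrep("C", 30), revcomp(S17), strrep("C", 70))
  expect_equal(nrow(find_complementary(up2, down2, min_len = 18)), 0)
  expect_equal(nrow(find_complementary(up2, down2, min_len = 17)), 1)
})

test_that("N never matches anything", {
  up <- paste0(strrep("G", 30), strrep("N", 20), strrep("G", 30))
  down <- paste0(strrep("C", 30), strrep("N", 20), strrep("C", 30))
  # revcomp of C-runs are G-runs; only the N-block could pair with N
  m <- find_complementary(up, down, min_len = 10)
  expect_true(all(m$length >= 10))
  for (r in seq_len(nrow(m))) {
    expect_false(grepl("N", substring(up, m$up_start[r], m$up_end[r])))
  }
})

test_that("search equals the brute-force oracle on random fixtures", {
  set.seed(1234)
  for (rep in 1:100) {
    min_len <- sample(c(4, 10, 18), 1)
    n1 <- sample(80:200, 1)
    n2 <- sample(80:200, 1)
    up <- random_dna(n1)
    down <- random_dna(n2)
    # occasionally plant a repeat so long matches are exercised
    if (rep %% 3 == 0) {
      S <- random_dna(min_len + sample(0:4, 1))
      pu <- sample(n1 - nchar(S), 1)
      pd <- sample(n2 - nchar(S), 1)
      substring(up, pu, pu + nchar(S) - 1) <- S
      substring(down, pd, pd + nchar(S) - 1) <- revcomp(S)
    }
    got <- find_complementary(up, down, min_len = min_len)
    want <- oracle_complementary(up, down, min_len)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want,
                 label = sprintf("fixture %d (min_len %d)", rep, min_len))
    # symmetry: swapping the flanks mirrors the match set
    swapped <- find_complementary(down, up, min_len = min_len)
    expect_equal(nrow(swapped), nrow(got))
    expect_equal(sort(swapped$length), sort(got$length))
  }
})

test_that("flank windows clamp at chromosome edges and N runs", {
  g <- toy_genome(random_dna(400))
  # circ at position 1: upstream window empty, nothing can match
  res <- scan_flanks(toy_circs("Chr1", 1, 100), g, window = 200,
                     min_len = 4)
  expect_false(res$per_circ$has_complementary_flanks)

  # spacer-style N run truncates the window before it
  S <- random_dna(12)
  seqs <- paste0(random_dna(50), strrep("N", 60), S, random_dna(20),
                 "AAAA", random_dna(20), revcomp(S), random_dna(50))
  gg <- toy_genome(seqs)
  start <- 50 + 60 + 12 + 20 + 1
  end <- start + 3
  res2 <- scan_flanks(toy_circs("Chr1", start, end), gg, window = 500,
                      min_len = 12)
  expect_true(res2$per_circ$has_complementary_flanks)
  # matches never extend past the N run into the first 50 bases
  expect_true(all(res2$matches$up_start >= 1))
})

test_that("widening the window never loses a detection", {
  sim <- get_fixture("tiny")
  mat <- build_expression_matrix(sim$junction_tables, sim$sample_stats)
  narrow <- scan_flanks(mat$circs, sim$genome, window = 500)
  wide <- scan_flanks(mat$circs, sim$genome, window = 1000)
  expect_true(all(wide$per_circ$has_complementary_flanks >=
                    narrow$per_circ$has_complementary_flanks))
})

test_that("planted flank truth is recovered exactly on the simulator", {
  sim <- get_fixture("paper_mix")
  mat <- build_expression_matrix(sim$junction_tables, sim$sample_stats)
  res <- scan_flanks(mat$circs, sim$genome, window = 1000, min_len = 18)
  truth <- sim$truth[match(mat$circs$circ_id, sim$truth$circ_id), ]
  detected <- res$per_circ$has_complementary_flanks
  expect_identical(detected, truth$planted_flank)
  # every reported match re-verifies by direct sequence comparison
  for (r in seq_len(nrow(res$matches))) {
    mrow <- res$matches[r, ]
    i <- match(mrow$circ_id, mat$circs$circ_id)
    win_up_start <- mat$circs$start[i] - 1000
    win_down_start <- mat$circs$end[i] + 1
    up_sub <- fetch_sequence(sim$genome, mat$circs$chrom[i],
                             win_up_start + mrow$up_start - 1,
                             win_up_start + mrow$up_end - 1)
    down_sub <- fetch_sequence(sim$genome, mat$circs$chrom[i],
                               win_down_start + mrow$down_start - 1,
                               win_down_start + mrow$down_end - 1)
    expect_identical(up_sub, revcomp(down_sub))
  }
})

test_that("MITE flagging needs both flanks", {
  circs <- toy_circs("Chr1", c(5000, 9000), c(6000, 9500))
  mites <- data.frame(chrom = "Chr1",
                      start = c(4500, 6200, 8500),
                      end = c(4600, 6300, 8600))
  res <- mite_overlap(circs, mites, window = 1000)
  expect_equal(res$per_circ$mite_both_flanks, c(TRUE, FALSE))
  expect_equal(res$count, 1)
  # empty MITE set -> all FALSE
  res0 <- mite_overlap(circs, mites[0, ], window = 1000)
  expect_false(any(res0$per_circ$mite_both_flanks))
  # unknown chromosome warns and is ignored
  expect_warning(
    res2 <- mite_overlap(circs, rbind(mites,
                                      data.frame(chrom = "ChrX",
                                                 start = 1, end = 10)),
                         window = 1000),
    "unknown")
  expect_equal(res2$per_circ, res$per_circ)

  # simulator truth agreement
  sim <- get_fixture("tiny")
  mat <- build_expression_matrix(sim$junction_tables, sim$sample_stats)
  mo <- mite_overlap(mat$circs, sim$mites, chroms = names(sim$genome))
  truth <- sim$truth[match(mat$circs$circ_id, sim$truth$circ_id), ]
  expect_identical(mo$per_circ$mite_both_flanks, truth$mite_both_flanks)
})
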