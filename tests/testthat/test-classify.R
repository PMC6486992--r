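test_that("origin precedence: exonic, intronic, intergenic", {
  genes <- toy_genes()
  circs <- rbind(
    toy_circs("Chr1", 201, 350),   # exon 2 start .. exon 3 end of gA
    toy_circs("Chr1", 155, 195),   # inside intron 1 of gA
    toy_circs("Chr1", 700, 900),   # overlaps nothing
    toy_circs("Chr1", 120, 175),   # start in exon, end in intron -> intergenic
    toy_circs("Chr1", 1301, 1540)) # whole gB (minus strand), exonic
  oc <- classify_origin(circs, genes)
  expect_equal(oc$origin,
               c("exonic", "intronic", "intergenic", "intergenic", "exonic"))
  expect_equal(oc$parent_gene, c("gA", "gA", NA, NA, "gB"))
  # partition invariant
  expect_equal(sum(table(oc$origin)), nrow(circs))
})

test_that("exon architecture classes follow transcript orientation", {
  genes <- toy_genes()
  # gA is plus strand with 5 exons at 101-150, 201-250, ..., 501-550
  circs <- rbind(
    toy_circs("Chr1", 201, 450),   # exons 2-4 -> middle, 3 exons
    toy_circs("Chr1", 501, 550),   # exon 5 alone -> last
    toy_circs("Chr1", 101, 150),   # exon 1 alone -> first
    toy_circs("Chr1", 101, 550),   # all -> first_and_last
    toy_circs("Chr1", 1501, 1540)) # genomically last exon of minus gB -> first
  oc <- classify_origin(circs, genes)
  arch <- exon_architecture(circs, oc, genes)
  expect_equal(arch$position_class,
               c("middle", "last", "first", "first_and_last", "first"))
  expect_equal(arch$exon_count, c(3L, 1L, 1L, 5L, 1L))
  expect_equal(arch$spliced_length[1], 150L)
  expect_equal(arch$exon_lengths[1], "50,50,50")
})

test_that("strand flip swaps first and last classes, middle unchanged", {
  genes <- toy_genes()
  circs <- rbind(toy_circs("Chr1", 201, 450),
                 toy_circs("Chr1", 501, 550),
                 toy_circs("Chr1", 101, 150))
  oc <- classify_origin(circs, genes)
  a1 <- exon_architecture(circs, oc, genes)
  flipped <- genes
  flipped$strand <- ifelse(genes$strand == "+", "-", "+")
  flipped <- do.call(rbind, lapply(split(flipped, flipped$gene_id), function(g) {
    g <- g[order(g$start), ]
    g$exon_rank <- if (g$strand[1] == "-") rev(seq_len(nrow(g))) else
      seq_len(nrow(g))
    g
  }))
  a2 <- exon_architecture(circs, oc, flipped)
  expect_equal(a2$position_class, c("middle", "first", "last"))
  expect_equal(sum(a1$position_class == "middle"),
               sum(a2$position_class == "middle"))
})

test_that("parent-gene tie-breaking picks the larger overlap", {
  # nested genes: gZ single huge exon inside which gA-like exons sit
  genes <- rbind(
    data.frame(gene_id = "gY", chrom = "Chr1", strand = "+", exon_rank = 1:2,
               start = c(100, 300), end = c(200, 400)),
    data.frame(gene_id = "gZ", chrom = "Chr1", strand = "+", exon_rank = 1L,
               start = 50, end = 500))
  circs <- toy_circs("Chr1", 100, 400)
  oc <- classify_origin(circs, genes)
  expect_equal(oc$origin, "exonic")
  expect_equal(oc$parent_gene, "gZ")  # full-span exon overlap beats gY
})

test_that("summary reproduces cohort percentages and lengths", {
  # the canonical three-way split: 2216 exonic, 434 intergenic, 137 intronic
  counts <- c(exonic = 2216, intergenic = 434, intronic = 137)
  oc <- data.frame(circ_id = sprintf("c%04d", seq_len(sum(counts))),
                   origin = rep(names(counts), counts),
                   parent_gene = NA_character_)
  circs <- data.frame(circ_id = oc$circ_id, chrom = "Chr1",
                      start = 1000L + seq_len(sum(counts)),
                      end = 1000L + seq_len(sum(counts)) + 569L)
  s <- summarize_circs(oc, data.frame(circ_id = character(),
                                      position_class = character(),
                                      exon_count = integer(),
                                      spliced_length = integer(),
                                      exon_lengths = character()), circs)
  expect_equal(s$origin_table$percent, c(79.51, 15.57, 4.92))
  expect_equal(sum(s$origin_table$count), 2787)
  expect_equal(s$median_length, 570)
  expect_equal(sum(s$length_hist$count), 2787)

  # single exonic circ -> 100% exonic; spliced length used when known
  oc1 <- data.frame(circ_id = "c1", origin = "exonic", parent_gene = "g")
  arch1 <- data.frame(circ_id = "c1", position_class = "middle",
                      exon_count = 2L, spliced_length = 300L,
                      exon_lengths = "150,150")
  circ1 <- data.frame(circ_id = "c1", chrom = "Chr1", start = 1L,
                      end = 1000L)
  s1 <- summarize_circs(oc1, arch1, circ1)
  expect_equal(s1$origin_table$percent[s1$origin_table$origin == "exonic"],
               100)
  expect_equal(unname(s1$lengths["c1"]), 300L)
  expect_equal(s1$median_length, 300)

  # empty input -> zero totals, no percentages
  s0 <- summarize_circs(oc1[0, ], arch1[0, ], circ1[0, ])
  expect_equal(s0$n, 0L)
  expect_true(all(is.na(s0$origin_table$percent)))
})

test_that("origin calls match simulator truth exactly", {
  sim <- get_fixture("paper_mix")
  mat <- build_expression_matrix(sim$junction_tables, sim$sample_stats)
  oc <- classify_origin(mat$circs, sim$genes)
  truth <- sim$truth[match(oc$circ_id, sim$truth$circ_id), ]
  expect_identical(oc$origin, truth$origin)
  genic <- oc$origin != "intergenic"
  expect_identical(oc$parent_gene[genic], truth$parent_gene[genic])
  # partition
  expect_equal(sum(table(oc$origin)), nrow(mat$circs))
})
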