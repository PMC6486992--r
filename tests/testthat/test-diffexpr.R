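.de_stats <- function(ids, mapped, read_length = 150) {
  data.frame(sample_id = ids, total_reads = mapped * 1.1,
             mapped_reads = mapped, read_length = read_length)
}

test_that("pooled exact test behaves at the null and for strong effects", {
  st <- .de_stats(c("t1", "t2", "c1", "c2"), rep(1e7, 4))
  counts <- rbind(null_circ = c(10L, 10L, 10L, 10L),
                  up_circ = c(10L, 10L, 0L, 0L),
                  zero = c(0L, 0L, 0L, 0L))
  colnames(counts) <- st$sample_id
  res <- de_test(counts, st, treated = c("t1", "t2"),
                 control = c("c1", "c2"))
  expect_equal(res$p_value[1], 1)            # identical pooled proportions
  expect_equal(res$log2fc[1], 0, tolerance = 1e-9)
  expect_lt(res$p_value[2], 0.01)            # 0 vs 20 at equal libraries
  expect_gt(res$log2fc[2], 1)
  expect_equal(res$p_value[3], 1)            # no reads at all
  expect_equal(res$log2fc[3], 0)

  # swapping group labels negates log2fc and preserves p
  swapped <- de_test(counts, st, treated = c("c1", "c2"),
                     control = c("t1", "t2"))
  expect_equal(swapped$log2fc, -res$log2fc, tolerance = 1e-12)
  expect_equal(swapped$p_value, res$p_value, tolerance = 1e-12)

  expect_error(de_test(counts, .de_stats(st$sample_id, rep(0, 4)),
                       treated = c("t1", "t2"), control = c("c1", "c2")),
               "mapped_reads|library")
})

test_that("exact test p equals the conditional binomial oracle", {
  st <- .de_stats(c("t1", "c1"), c(2e7, 3e7))
  counts <- matrix(c(14L, 6L), nrow = 1,
                   dimnames = list("c", c("t1", "c1")))
  res <- de_test(counts, st, treated = "t1", control = "c1")
  oracle <- stats::binom.test(14, 20, p = 2e7 / 5e7)$p.value
  expect_equal(res$p_value, oracle, tolerance = 1e-12)
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.03, 0.04, 0.05)),
               c(0.04, 0.05, 0.05, 0.05))
  expect_equal(bh_adjust(0.123), 0.123)           # single p unchanged
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))  # ties unchanged
  # never decreases any p, and preserves the input's rank order
  set.seed(5)
  p <- runif(40)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= 0))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("DE cut-offs are strict on fold change, non-strict on FDR", {
  res <- data.frame(circ_id = c("a", "b", "c", "d"),
                    log2fc = c(1.5, 1.0, -1.5, 2.0),
                    p_value = c(0.001, 0.001, 0.001, 0.9))
  called <- de_call(res, lfc_cutoff = 1, fdr_cutoff = 0.05)
  expect_equal(called$call, c("up", "ns", "down", "ns"))
  # boundary FDR exactly at the cut-off qualifies
  res2 <- data.frame(circ_id = "x", log2fc = 3, p_value = 0.05)
  expect_equal(de_call(res2)$call, "up")
})

test_that("rank-sum test matches enumeration and approximation branches", {
  g <- global_shift(c(1, 2, 3), c(4, 5, 6))
  expect_equal(g$p_value, 0.1)  # 2/20 rank splits as extreme
  expect_equal(g$p_value, oracle_ranksum(c(1, 2, 3), c(4, 5, 6)))

  # identical tied groups give the maximal p
  gid <- global_shift(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_equal(gid$p_value, 1)

  # exact and approximate branches agree within 0.01 at n = m = 10
  set.seed(31)
  for (k in 1:5) {
    x <- rnorm(10)
    y <- rnorm(10, mean = 0.5)
    p_exact <- global_shift(x, y)$p_value
    p_norm <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                  correct = TRUE))$p.value
    expect_lt(abs(p_exact - p_norm), 0.01)
  }
  expect_error(global_shift(numeric(0), 1), "non-empty")
})

test_that("per-tissue report totals are up + down", {
  calls <- data.frame(
    circ_id = sprintf("c%04d", 1:1978),
    call = c(rep("up", 991), rep("down", 943), rep("up", 19),
             rep("down", 25)),
    tissue = c(rep("root", 1934), rep("leaf", 44)))
  rep_tab <- de_report(calls)
  root <- rep_tab[rep_tab$tissue == "root", ]
  leaf <- rep_tab[rep_tab$tissue == "leaf", ]
  expect_equal(c(root$up, root$down, root$total), c(991, 943, 1934))
  expect_equal(c(leaf$up, leaf$down, leaf$total), c(19, 25, 44))
  empty <- de_report(calls[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("p-values are conservative under the test's Poisson null", {
  # 1000 null circs sampled from the pooled test's own model
  set.seed(77)
  st <- .de_stats(c("t1", "t2", "c1", "c2"), c(5e7, 4.5e7, 5.5e7, 5e7))
  mu <- rexp(1000, 1 / 10)
  counts <- sapply(seq_len(4), function(j)
    rpois(1000, mu * st$mapped_reads[j] / 5e7))
  dimnames(counts) <- list(sprintf("c%04d", 1:1000), st$sample_id)
  res <- de_test(counts, st, treated = c("t1", "t2"),
                 control = c("c1", "c2"))
  # super-uniform: empirical CDF never exceeds the uniform by more than
  # sampling noise at any conventional alpha
  for (alpha in c(0.01, 0.05, 0.1, 0.25)) {
    expect_lte(mean(res$p_value <= alpha), alpha + 0.02)
  }
})
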