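test_that("window enumeration matches brute force and the 1000 bp example", {
  w <- enumerate_windows(c(chr1 = 1000L))
  expect_equal(nrow(w), 9L)
  expect_equal(w$start, seq(0L, 800L, 100L))
  expect_equal(w$end, seq(200L, 1000L, 100L))
  for (len in c(50L, 199L, 200L, 950L, 1001L, 1050L, 12345L)) {
    got <- enumerate_windows(stats::setNames(len, "c"))
    want <- brute_windows(len)
    expect_equal(got$start, want$start, info = paste("len", len))
    expect_equal(got$end, want$end, info = paste("len", len))
    expect_equal(max(got$end), len)  # every base covered
  }
  expect_error(enumerate_windows(c(chr1 = 1000L), window = 50L, step = 100L),
               "window >= step")
  expect_error(enumerate_windows(c(chr1 = 1000L), step = 0L), "step > 0")
})

test_that("window pooling sums replicate counts exactly", {
  r1 <- data.table::data.table(chrom = "chr1", pos = c(50L, 150L), strand = "+",
                               context = "CG", mc_count = c(10L, 4L),
                               total_count = c(40L, 10L))
  r2 <- data.table::data.table(chrom = "chr1", pos = c(50L, 150L), strand = "+",
                               context = "CG", mc_count = c(20L, 1L),
                               total_count = c(60L, 10L))
  w <- build_windows(list(r1, r2), c(chr1 = 400L), "CG")
  first <- w[start == 0]
  expect_equal(first$mc, 35L)        # 10+20+4+1
  expect_equal(first$total, 120L)
  expect_equal(first$n_sites, 2L)
  # spec'd pooling example: replicate counts 10/40 and 20/60 pool to 0.30
  w1 <- build_windows(
    list(r1[pos == 50L], r2[pos == 50L]), c(chr1 = 200L), "CG")
  expect_equal(w1$level, 0.30)
})

test_that("windows without context sites are emitted empty", {
  calls <- data.table::data.table(chrom = "chr1", pos = 50L, strand = "+",
                                  context = "CHH", mc_count = 1L,
                                  total_count = 10L)
  w <- build_windows(calls, c(chr1 = 500L), "CG")
  expect_true(all(w$n_sites == 0L))
  expect_true(all(is.na(w$level)))
  expect_equal(nrow(w), nrow(enumerate_windows(c(chr1 = 500L))))
})

test_that("per-site coverage floor applies before pooling into windows", {
  calls <- data.table::data.table(chrom = "chr1", pos = c(10L, 20L),
                                  strand = "+", context = "CG",
                                  mc_count = c(1L, 5L),
                                  total_count = c(3L, 10L))
  w <- build_windows(calls, c(chr1 = 200L), "CG", min_coverage = 4L)
  expect_equal(w$n_sites, 1L)  # the 3x site is dropped
  expect_equal(w$mc, 5L)
})

test_that("chi-square matches the hand formula, an independent oracle, and Fisher ordering", {
  res <- chi_square_test(30, 70, 60, 40)
  expect_equal(res$chi2_stat, 200 * (30 * 40 - 70 * 60)^2 /
                 (100 * 100 * 90 * 110))
  expect_equal(res$chi2_stat, 18.1818, tolerance = 1e-4)
  expect_equal(res$p_value, 2.01e-5, tolerance = 1e-2)

  expect_equal(chi_square_test(50, 50, 50, 50)$chi2_stat, 0)
  expect_equal(chi_square_test(50, 50, 50, 50)$p_value, 1)
  # symmetry under sample swap
  expect_equal(chi_square_test(12, 34, 56, 8), chi_square_test(56, 8, 12, 34))

  set.seed(5)
  tabs <- matrix(sample(0:200, 4000, replace = TRUE), ncol = 4)
  got <- chi_square_test(tabs[, 1], tabs[, 2], tabs[, 3], tabs[, 4])
  for (i in seq_len(nrow(tabs))) {
    m <- matrix(tabs[i, ], 2, 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
      expect_true(is.na(got$p_value[i]))
      next
    }
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_lt(abs(got$p_value[i] - ref$p.value), 1e-10)
    expect_lt(abs(got$chi2_stat[i] - unname(ref$statistic)), 1e-8)
  }
  # rejection ordering agrees with Fisher's exact test on well-filled tables
  big <- tabs[apply(tabs, 1, min) >= 20, , drop = FALSE][1:50, ]
  chi_p <- chi_square_test(big[, 1], big[, 2], big[, 3], big[, 4])$p_value
  fis_p <- apply(big, 1, function(r)
    stats::fisher.test(matrix(r, 2, 2, byrow = TRUE))$p.value)
  expect_gt(stats::cor(rank(chi_p), rank(fis_p)), 0.99)
})

test_that("negative counts are rejected", {
  expect_error(chi_square_test(-1, 5, 5, 5), "non-negative")
})

make_window_pair <- function(level_a, level_b, n_sites = 10L, depth = 200L,
                             n_windows = 40L, seed = 9) {
  set.seed(seed)
  base <- enumerate_windows(stats::setNames(n_windows * 100L + 100L, "chr1"))
  wa <- data.table::copy(base)[, context := "CG"]
  wb <- data.table::copy(base)[, context := "CG"]
  wa[, `:=`(n_sites = n_sites, total = depth,
            mc = stats::rbinom(.N, depth, level_a))]
  wb[, `:=`(n_sites = n_sites, total = depth,
            mc = stats::rbinom(.N, depth, level_b))]
  wa[, level := mc / total]; wb[, level := mc / total]
  list(a = wa, b = wb)
}

test_that("DMR criteria boundaries reject under-powered windows", {
  p <- make_window_pair(0.1, 0.1)
  # one strongly differential window
  p$a[5, `:=`(mc = 20L, total = 200L, level = 0.1)]
  p$b[5, `:=`(mc = 120L, total = 200L, level = 0.6)]
  dmrs <- suppressMessages(call_dmrs(p$a, p$b, "CG"))
  expect_true(nrow(dmrs) >= 1L)

  # same signal but only 4 CG sites in the window: rejected by site count
  p$a[, n_sites := 4L]; p$b[, n_sites := 4L]
  expect_equal(nrow(suppressMessages(call_dmrs(p$a, p$b, "CG"))), 0L)

  # CHH window with delta below 0.15 is rejected regardless of q
  p2 <- make_window_pair(0.30, 0.44, n_sites = 20L, depth = 100000L)
  p2$a[, context := "CHH"]; p2$b[, context := "CHH"]
  d2 <- suppressMessages(call_dmrs(p2$a, p2$b, "CHH"))
  expect_true(all(abs(d2$delta) >= 0.15))
  expect_equal(nrow(d2), 0L)
})

test_that("swapping the sample order flips every DMR direction and nothing else", {
  p <- make_window_pair(0.1, 0.1)
  for (i in c(3L, 11L, 25L)) {
    p$a[i, `:=`(mc = 20L, total = 200L, level = 0.1)]
    p$b[i, `:=`(mc = 130L, total = 200L, level = 0.65)]
  }
  fwd <- suppressMessages(call_dmrs(p$a, p$b, "CG"))
  rev <- suppressMessages(call_dmrs(p$b, p$a, "CG"))
  expect_gt(nrow(fwd), 0L)
  expect_equal(fwd$start, rev$start)
  expect_equal(fwd$end, rev$end)
  expect_equal(fwd$delta, -rev$delta)
  expect_equal(fwd$q_value, rev$q_value)
  expect_true(all(fwd$direction == "hyper" & rev$direction == "hypo"))
})

test_that("overlapping surviving windows of one direction merge into one DMR", {
  p <- make_window_pair(0.1, 0.1)
  for (i in 5:7) {  # three consecutive overlapping windows
    p$a[i, `:=`(mc = 20L, total = 200L, level = 0.1)]
    p$b[i, `:=`(mc = 130L, total = 200L, level = 0.65)]
  }
  merged <- suppressMessages(call_dmrs(p$a, p$b, "CG"))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$n_windows, 3L)
  expect_equal(merged$start, p$a$start[5])
  expect_equal(merged$end, p$a$end[7])
  unmerged <- suppressMessages(call_dmrs(p$a, p$b, "CG", merge = FALSE))
  expect_equal(nrow(unmerged), 3L)
})

test_that("DMG annotation applies the > 1 nt overlap rule exactly", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 3000L,
                      end = 4000L)
  dmr <- function(s0, e) data.table::data.table(
    chrom = "chr1", start = s0, end = e, context = "CG", direction = "hyper",
    delta = 0.4, chi2_stat = 10, q_value = 0.01, n_windows = 1L, n_sites = 6L)
  # flank region is [1000,6000]; DMR [1000,1200] overlaps by 201 nt
  expect_equal(annotate_dmgs(dmr(999L, 1200L), genes)$gene_id, "g1")
  # 0-based [990,1001) = 1-based [991,1001]: overlap with [1000,...] is 2 nt
  expect_equal(nrow(annotate_dmgs(dmr(990L, 1001L), genes)), 1L)
  # 1-based [991,1000]: overlap exactly 1 nt -> not a DMG
  expect_equal(nrow(annotate_dmgs(dmr(990L, 1000L), genes)), 0L)
})

test_that("DMG annotation equals quadratic brute-force intersection", {
  set.seed(31)
  n_dmr <- 500L; n_gene <- 200L
  dmrs <- data.table::data.table(
    chrom = sample(c("chr1", "chr2"), n_dmr, TRUE),
    start = sample.int(2000000L, n_dmr))
  dmrs[, end := start + sample(100:1000, n_dmr, TRUE)]
  dmrs[, `:=`(context = "CG", direction = sample(c("hyper", "hypo"), n_dmr, TRUE),
              delta = 0.3, chi2_stat = 10, q_value = 0.01, n_windows = 1L,
              n_sites = 6L)]
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(n_gene)),
                      chrom = sample(c("chr1", "chr2"), n_gene, TRUE),
                      start = sample.int(2000000L, n_gene))
  genes$end <- genes$start + sample(500:5000, n_gene, TRUE)

  got <- annotate_dmgs(dmrs, genes)
  want_pairs <- brute_dmg(as.data.frame(dmrs), genes)
  want <- aggregate(direction ~ gene_id, want_pairs, function(d)
    if (length(unique(d)) > 1) "mixed" else d[1])
  want <- want[order(want$gene_id), ]
  expect_equal(got$gene_id, want$gene_id)
  expect_equal(got$direction, want$direction)
  expect_equal(got$n_dmrs,
               as.integer(table(want_pairs$gene_id)[got$gene_id]),
               ignore_attr = TRUE)
})

test_that("chromosome density conserves counts and bins correctly", {
  calls <- data.table::data.table(
    chrom = "chr1", pos = c(150L, 199L, 150050L), strand = "+",
    context = "CG", mc_count = 5L, total_count = 10L,
    p_value = 0, q_value = 0, is_methylated = TRUE)
  dens <- chromosome_density(calls, bin = 100L)
  expect_equal(dens[start == 100 & context == "CG"]$count, 2L)
  expect_equal(sum(dens$count), 3L)
  # empty input with seqlengths gives an all-zero full grid
  zero <- chromosome_density(calls[0], bin = 500L,
                             seqlengths = c(chr1 = 1000L))
  expect_equal(nrow(zero), 2L * 2L * 3L)
  expect_true(all(zero$count == 0L))
})
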