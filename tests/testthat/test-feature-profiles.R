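uniform_calls <- function(n, level_num, level_den, chrom = "chr1",
                          spacing = 10L, context = "CG") {
  data.table::data.table(chrom = chrom, pos = seq(1L, by = spacing,
                                                  length.out = n),
                         strand = "+", context = context,
                         mc_count = level_num, total_count = level_den)
}

simple_features <- function(kinds, starts, ends, gene_ids = NA,
                            te_class = NA_character_) {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, ends))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    feature_id = paste0("f", seq_along(gr)), kind = kinds, gene_id = gene_ids,
    te_class = te_class, te_superfamily = NA_character_)
  gr
}

test_that("feature levels pool counts within feature spans", {
  calls <- uniform_calls(20, 0L, 10L)
  f <- simple_features("gene_body", 1L, 500L)
  expect_equal(feature_levels(calls, f, "CG")$mean_level, 0)

  two <- data.table::data.table(chrom = "chr1", pos = c(10L, 20L),
                                strand = "+", context = "CG",
                                mc_count = c(3L, 7L), total_count = 10L)
  expect_equal(feature_levels(two, f, "CG")$mean_level, 0.5)
})

test_that("a whole-genome feature reproduces the genome-wide pooled level", {
  calls <- random_calls(2000, seed = 3, chroms = "chr1", max_pos = 50000L)
  calls <- calls[total_count >= 4]
  f <- simple_features("gene_body", 1L, 50000L)
  got <- feature_levels(calls, f, "ALL_C")
  expect_equal(got$mean_level,
               sum(calls$mc_count) / sum(calls$total_count))
  expect_equal(got$n_sites, nrow(calls))
})

test_that("TE-boosted synthetic genomes show elevated LTR methylation in every context", {
  cfg <- synthetic_config(seed = 17, genome_length = 400000L,
                          n_chromosomes = 1L, n_genes = 20L, n_tes = 40L,
                          te_methylation_boost = 0.3)
  st <- simulate_study(cfg)
  pooled <- pool_replicates(st$methylomes[[1]]$calls)
  feats <- derive_features(st$genes, st$tes, seqlengths = st$seqlengths)
  for (ctx in c("CG", "CHG", "CHH")) {
    fl <- suppressMessages(feature_levels(pooled, feats, ctx))
    ltr <- fl[kind == "TE" & te_class == "LTR"]$mean_level
    genome_wide <- {
      cc <- pooled[context == ctx & total_count >= 4]
      sum(cc$mc_count) / sum(cc$total_count)
    }
    expect_gt(ltr, genome_wide)
  }
})

test_that("metaprofiles are flat for uniform methylation and step-shaped by construction", {
  set.seed(2)
  n <- 3000L
  calls <- data.table::data.table(
    chrom = "chr1", pos = sort(sample.int(30000L, n)), strand = "+",
    context = "CG", mc_count = 3L, total_count = 10L)
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(5000L, 20000L), end = c(9000L, 24000L),
                      strand = c("+", "-"))
  mp <- metaprofile(calls, genes, "CG")
  expect_equal(nrow(mp), 60L)
  expect_true(all(abs(mp[n_sites > 0]$mean_level - 0.3) < 1e-12))

  # 0.8 inside bodies, 0.2 outside
  inside <- calls$pos %in% c(5000:9000, 20000:24000)
  calls2 <- data.table::copy(calls)
  calls2[, mc_count := data.table::fifelse(inside, 8L, 2L)]
  mp2 <- metaprofile(calls2, genes, "CG")
  expect_true(all(abs(mp2[region == "body"]$mean_level - 0.8) < 1e-12))
  expect_true(all(abs(mp2[region != "body" & n_sites > 0]$mean_level - 0.2) < 1e-12))
})

test_that("metaprofile binning matches a per-gene brute-force oracle", {
  set.seed(11)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
                      start = sort(sample(seq(3000L, 190000L, 9000L), 20)),
                      strand = sample(c("+", "-"), 20, TRUE))
  genes$end <- genes$start + sample(500:4000, 20, TRUE)
  calls <- random_calls(20000, seed = 12, chroms = "chr1", max_pos = 200000L)
  calls <- calls[total_count >= 4]
  got <- metaprofile(calls, genes, "ALL_C", body_bins = 10L, flank = 2000L,
                     flank_bin = 200L)

  # oracle: loop genes x sites, accumulate counts per bin
  fb <- 10L; bb <- 10L
  mc_acc <- tot_acc <- n_acc <- numeric(fb * 2 + bb)
  for (g in seq_len(nrow(genes))) {
    gs <- genes$start[g]; ge <- genes$end[g]; w <- ge - gs + 1
    minus <- genes$strand[g] == "-"
    for (i in seq_len(nrow(calls))) {
      p <- calls$pos[i]
      if (p < gs - 2000L || p > ge + 2000L) next
      if (p >= gs && p <= ge) {
        rel <- if (minus) (ge - p + 0.5) / w else (p - gs + 0.5) / w
        b <- fb + min(floor(rel * bb) + 1, bb)
      } else {
        before <- p < gs
        d5 <- if (minus) p - ge else gs - p
        if ((minus && !before) || (!minus && before)) {
          b <- fb - ((d5 - 1) %/% 200)
        } else {
          d3 <- if (minus) gs - p else p - ge
          b <- fb + bb + ((d3 - 1) %/% 200) + 1
        }
      }
      mc_acc[b] <- mc_acc[b] + calls$mc_count[i]
      tot_acc[b] <- tot_acc[b] + calls$total_count[i]
      n_acc[b] <- n_acc[b] + 1
    }
  }
  expect_equal(got$n_sites, as.integer(n_acc))
  want_level <- ifelse(tot_acc > 0, mc_acc / tot_acc, NA_real_)
  expect_equal(got$mean_level, want_level)
})

test_that("reversing feature strands reverses metaprofile bins and nothing else", {
  calls <- random_calls(5000, seed = 9, chroms = "chr1", max_pos = 100000L)
  # even body widths: odd-width features have a self-mirroring central base
  genes <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                      start = c(20000L, 60000L), end = c(25999L, 63999L),
                      strand = c("+", "-"))
  flipped <- genes
  flipped$strand <- c("-", "+")
  fwd <- metaprofile(calls, genes, "ALL_C", body_bins = 10L)
  rev <- metaprofile(calls, flipped, "ALL_C", body_bins = 10L)
  expect_equal(fwd$mean_level, rev(rev$mean_level))
  expect_equal(fwd$n_sites, rev(rev$n_sites))
})

test_that("level histogram bins with the stated edge conventions", {
  calls <- data.table::data.table(
    chrom = "chr1", pos = 1:4, strand = "+", context = "CG",
    mc_count = c(1L, 0L, 20L, 19L), total_count = 20L)  # 0.05, 0, 1.0, 0.95
  h <- level_histogram(calls, "CG")
  expect_equal(h[bin_index == 1]$n_sites, 2L)   # 0 and 0.05
  expect_equal(h[bin_index == 10]$n_sites, 2L)  # 0.95 and the closed 1.0 edge
  expect_equal(sum(h$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(h$n_sites), 4L)              # each site in exactly one bin
})

test_that("histogram low-bin mass recovers the configured CHH low-component mass", {
  cfg <- synthetic_config(seed = 23, genome_length = 400000L,
                          n_chromosomes = 1L, n_genes = 0L, n_tes = 0L,
                          te_methylation_boost = 0)
  st <- simulate_study(cfg)
  pooled <- pool_replicates(st$methylomes[[1]]$calls)
  h <- level_histogram(pooled, "CHH")
  expect_lt(abs(h[bin_index == 1]$fraction - 0.83), 0.02)
})

test_that("context proportions reproduce the published poplar site arithmetic", {
  # site abundances 59.65 : 96.05 : 904.5 (millions) with methylated fractions
  # 0.4764 / 0.2885 / 0.0485 give mC proportions 28.42 / 27.71 / 43.87%
  counts <- c(CG = 59.65 * 0.4764, CHG = 96.05 * 0.2885, CHH = 904.5 * 0.0485)
  cp <- context_proportions(counts)
  expect_equal(cp[context == "CHH"]$proportion, 0.4387, tolerance = 1e-3)
  expect_equal(cp[context == "CG"]$proportion, 0.2842, tolerance = 1e-3)
  expect_equal(cp[context == "CHG"]$proportion, 0.2771, tolerance = 1e-3)
  expect_equal(sum(cp$proportion), 1)

  simple <- context_proportions(c(CG = 28, CHG = 28, CHH = 44))
  expect_equal(simple$proportion, c(0.28, 0.28, 0.44))
  only_cg <- data.table::data.table(context = rep("CG", 5),
                                    is_methylated = TRUE)
  expect_equal(context_proportions(only_cg)$proportion, c(1, 0, 0))
  expect_error(context_proportions(c(CG = 0, CHG = 0, CHH = 0)), "undefined")
})

test_that("genome summary recovers the configured methylated fraction", {
  mix <- list(
    CG = list(weights = c(0.52, 0.48), means = c(0, 0.9), conc = c(1, 25)),
    CHG = list(weights = 1, means = 0, conc = 1),
    CHH = list(weights = 1, means = 0, conc = 1))
  cfg <- synthetic_config(seed = 19, genome_length = 400000L,
                          n_chromosomes = 1L, n_genes = 0L, n_tes = 0L,
                          context_methylation = mix, te_methylation_boost = 0)
  st <- simulate_study(cfg)
  pooled <- pool_replicates(st$methylomes[[1]]$calls)
  conv <- estimate_conversion(st$lambda[[1]]$calls)
  called <- call_sites(pooled, conv$non_conversion_rate)
  gs <- genome_summary(called, "S1")
  expect_lt(abs(gs[context == "CG"]$percent_methylated / 100 - 0.48), 0.01)
  expect_true(all(gs$percent_methylated >= 0 & gs$percent_methylated <= 100))
  # all-null contexts stay at (conservatively controlled) near-zero rates
  expect_lt(gs[context == "CHH"]$percent_methylated, 1)
})
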