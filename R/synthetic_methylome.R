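#' Generate per-replicate cytosine call tables for one condition
#'
#' Every cytosine on both strands receives a true methylation level drawn
#' from its context's Beta mixture; sites inside TE spans get the additive
#' TE boost; for condition index 1, sites inside a planted DMR of matching
#' context are shifted by the DMR's delta (all clamped to \[0,1\]). The
#' base levels are derived from the config seed alone, so both conditions
#' share them and planted DMRs are the only systematic difference. Per
#' replicate, the per-site read depth is Poisson(`depth_mean`) and the
#' methylated count is Binomial with success probability
#' `level*(1-nc) + (1-level)*nc`, `nc` the non-conversion rate (bisulfite
#' non-conversion inflates, sequencing of converted methylated strands
#' deflates, the observed level symmetrically). Sites with zero depth in a
#' replicate are omitted from that replicate's table, as in real
#' methylation-extractor output.
#'
#' @param config A [synthetic_config()].
#' @param genome `DNAStringSet` from [generate_genome()].
#' @param genes,tes Annotation `GRanges` from [generate_genome()] (`tes`
#'   drives the TE boost; `genes` is accepted for interface symmetry).
#' @param condition_index 0 (condition A) or 1 (condition B).
#' @return A list: `calls` (list of per-replicate call tables), `truth`
#'   (`data.table` of `chrom`, `pos`, `strand`, `context`, `true_level` for
#'   this condition).
#' @export
generate_methylome <- function(config, genome, genes = NULL, tes = NULL,
                               condition_index = 0L) {
  config <- validate_synthetic_config(config)
  stopifnot(condition_index %in% c(0L, 1L))
  truth <- methylome_truth(config, genome, tes, condition_index)
  nc <- config$non_conversion_rate
  p_obs <- truth$true_level * (1 - nc) + (1 - truth$true_level) * nc
  n <- nrow(truth)
  calls <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    set.seed(config$seed + SEED_COUNTS * (condition_index + 1L) + r)
    depth <- stats::rpois(n, config$depth_mean)
    mc <- stats::rbinom(n, depth, p_obs)
    tab <- data.table::data.table(
      chrom = truth$chrom, pos = truth$pos, strand = truth$strand,
      context = truth$context, mc_count = mc, total_count = depth)
    calls[[r]] <- tab[total_count > 0L]
  }
  names(calls) <- sprintf("rep%d", seq_len(config$n_replicates))
  list(calls = calls, truth = truth)
}

# true per-site methylation levels for one condition; base levels (mixture +
# TE boost) depend only on the config seed so conditions share them
methylome_truth <- function(config, genome, tes, condition_index) {
  sites <- classify_contexts(genome, drop_undefined = TRUE)
  set.seed(config$seed + SEED_LEVELS)
  lev <- numeric(nrow(sites))
  for (ctx in CONTEXTS) {
    idx <- which(sites$context == ctx)
    if (!length(idx)) next
    mix <- config$context_methylation[[ctx]]
    comp <- sample.int(length(mix$weights), length(idx), replace = TRUE,
                       prob = mix$weights)
    a <- mix$means * mix$conc
    b <- (1 - mix$means) * mix$conc
    l <- stats::rbeta(length(idx), a[comp], b[comp])
    # degenerate components: a mean of exactly 0 or 1 is a point mass
    l[mix$means[comp] == 0] <- 0
    l[mix$means[comp] == 1] <- 1
    lev[idx] <- l
  }
  if (!is.null(tes) && length(tes) && config$te_methylation_boost != 0) {
    site_gr <- GenomicRanges::GRanges(sites$chrom,
                                      IRanges::IRanges(sites$pos, sites$pos))
    in_te <- IRanges::overlapsAny(site_gr, tes, ignore.strand = TRUE)
    lev[in_te] <- pmin(pmax(lev[in_te] + config$te_methylation_boost, 0), 1)
  }
  if (condition_index == 1L && !is.null(config$planted_dmrs) &&
      nrow(config$planted_dmrs)) {
    pd <- config$planted_dmrs
    site_gr <- GenomicRanges::GRanges(sites$chrom,
                                      IRanges::IRanges(sites$pos, sites$pos))
    dmr_gr <- GenomicRanges::GRanges(pd$chrom, IRanges::IRanges(pd$start, pd$end))
    ov <- GenomicRanges::findOverlaps(site_gr, dmr_gr)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    match_ctx <- pd$context[sh] == "ALL_C" | pd$context[sh] == sites$context[qh]
    qh <- qh[match_ctx]; sh <- sh[match_ctx]
    lev[qh] <- pmin(pmax(lev[qh] + pd$delta[sh], 0), 1)
  }
  sites[, true_level := lev]
  sites[]
}

#' Generate the unmethylated lambda spike-in and its call table
#'
#' The lambda genome carries no 5mC, so every cytosine's true level is 0 and
#' methylated counts are pure non-conversion noise:
#' Binomial(depth, non_conversion_rate).
#'
#' @param config A [synthetic_config()].
#' @param condition_index 0 or 1; gives each condition's spike-in its own
#'   read noise (the sequence is shared).
#' @return A list: `sequence` (`DNAStringSet` named `lambda`), `calls`
#'   (call table over all lambda cytosines with positive depth).
#' @export
generate_lambda_calls <- function(config, condition_index = 0L) {
  config <- validate_synthetic_config(config)
  stopifnot(config$lambda_length > 0L)
  set.seed(config$seed + SEED_LAMBDA)
  seq <- paste(sample(c("A", "C", "G", "T"), config$lambda_length,
                      replace = TRUE), collapse = "")
  lambda <- Biostrings::DNAStringSet(stats::setNames(seq, "lambda"))
  sites <- classify_contexts(lambda, drop_undefined = TRUE)
  set.seed(config$seed + SEED_LAMBDA + 10L * (condition_index + 1L))
  depth <- stats::rpois(nrow(sites), config$depth_mean)
  mc <- stats::rbinom(nrow(sites), depth, config$non_conversion_rate)
  calls <- data.table::data.table(
    chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
    context = sites$context, mc_count = mc, total_count = depth)
  list(sequence = lambda, calls = calls[total_count > 0L])
}

#' Sample non-overlapping intervals to plant DMRs in
#'
#' Convenience helper for building `planted_dmrs` tables: draws `n`
#' non-overlapping intervals of the given width, separated by at least
#' `min_gap` bp (so windows of one planted region never touch another).
#'
#' @param seqlengths Named chromosome lengths.
#' @param n Number of intervals.
#' @param width Interval width in bp.
#' @param context Context label for the planted regions.
#' @param delta Level shift of the planted regions.
#' @param min_gap Minimum separation in bp (default 1000).
#' @param seed RNG seed.
#' @return A `data.table` usable as `planted_dmrs`.
#' @export
sample_planted_dmrs <- function(seqlengths, n, width = 300L, context = "CG",
                                delta = 0.4, min_gap = 1000L, seed = 1L) {
  set.seed(seed)
  placed <- lapply(names(seqlengths), function(ch) IRanges::IRanges())
  names(placed) <- names(seqlengths)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(1000L)) {
      ch <- sample(names(seqlengths), 1L,
                   prob = as.numeric(seqlengths) / sum(as.numeric(seqlengths)))
      hi <- seqlengths[[ch]] - width
      if (hi < 1L) next
      s <- sample.int(hi, 1L)
      cand <- IRanges::IRanges(s - min_gap, s + width - 1L + min_gap)
      if (!any(IRanges::overlapsAny(cand, placed[[ch]]))) {
        placed[[ch]] <- c(placed[[ch]], IRanges::IRanges(s, s + width - 1L))
        out[[i]] <- data.table::data.table(chrom = ch, start = s,
                                           end = s + width - 1L,
                                           context = context, delta = delta)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place the requested number of DMR intervals")
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, chrom, start)
  res[]
}
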