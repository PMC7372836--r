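#' Pooled methylation level per genomic feature kind
#'
#' For each feature kind (and TE class / superfamily within the `TE` kind),
#' computes the count-pooled methylation level `sum(mc)/sum(total)` over all
#' context cytosines falling inside the feature spans, together with the
#' number of contributing sites. Sites inside overlapping features count
#' toward every feature they fall in. Aggregation is count-pooled rather
#' than a mean of per-site ratios, so deep sites weigh more and the level of
#' a feature set covering the whole genome equals the genome-wide pooled
#' level exactly.
#'
#' @param calls Pooled call table for one sample.
#' @param features Feature `GRanges` from [derive_features()].
#' @param context `"CG"`, `"CHG"`, `"CHH"` or `"ALL_C"`.
#' @param min_coverage Per-site coverage floor (default 4).
#' @param by_te_class Also split the `TE` kind by `te_class` (default `TRUE`).
#' @return A `data.table`: `kind`, `te_class`, `context`, `mean_level`,
#'   `n_sites`. Kinds with zero covered sites are omitted (with a message).
#' @export
feature_levels <- function(calls, features, context = "ALL_C",
                           min_coverage = 4L, by_te_class = TRUE) {
  sites <- filter_context(as.data.table(calls), context, min_coverage)
  if (!nrow(sites) || !length(features)) {
    return(data.table::data.table(kind = character(), te_class = character(),
                                  context = character(), mean_level = numeric(),
                                  n_sites = integer()))
  }
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, sites$pos))
  ov <- GenomicRanges::findOverlaps(site_gr, features, ignore.strand = TRUE)
  hits <- data.table::data.table(
    kind = features$kind[S4Vectors::subjectHits(ov)],
    te_class = features$te_class[S4Vectors::subjectHits(ov)],
    mc = sites$mc_count[S4Vectors::queryHits(ov)],
    total = sites$total_count[S4Vectors::queryHits(ov)])
  if (!by_te_class) hits[, te_class := NA_character_]
  out <- hits[, .(mean_level = sum(mc) / sum(total), n_sites = .N),
              by = .(kind, te_class)]
  missing_kinds <- setdiff(unique(features$kind), out$kind)
  if (length(missing_kinds)) {
    message(sprintf("feature_levels: no covered %s site in kind(s): %s",
                    context, paste(missing_kinds, collapse = ", ")))
  }
  out[, context := context]
  data.table::setcolorder(out, c("kind", "te_class", "context",
                                 "mean_level", "n_sites"))
  data.table::setorder(out, kind, te_class, na.last = TRUE)
  out[]
}

# context + coverage filter shared by the profiling ops
filter_context <- function(calls, context, min_coverage) {
  ctx <- context  # plain name would be captured by the data.table column
  calls <- calls[total_count >= min_coverage]
  if (ctx != "ALL_C") {
    if (!ctx %in% CONTEXTS) stop(sprintf("unknown context '%s'", ctx))
    calls <- calls[which(calls$context == ctx)]
  }
  calls
}

#' Methylation metaprofile over scaled feature bodies and fixed flanks
#'
#' Bins every feature (gene or TE) into `body_bins` equal-width body bins
#' plus fixed-width flank bins covering `flank` bp on each side, orients
#' minus-strand features 5'->3', and pools counts per bin across all
#' features. Bin 1 is the far 5' end of the upstream flank; bins run
#' upstream flank, body, downstream flank.
#'
#' @param calls Pooled call table for one sample.
#' @param features A `GRanges` of feature bodies (strand used for
#'   orientation), or anything [genes_to_dt()] accepts.
#' @param context Sequence context (or `"ALL_C"`).
#' @param body_bins Number of scaled body bins (default 20).
#' @param flank Flank width in bp (default 2000).
#' @param flank_bin Flank bin width in bp (default 100).
#' @param min_coverage Per-site coverage floor (default 4).
#' @return A `data.table`: `region` (`upstream`/`body`/`downstream`),
#'   `bin_index` (global 5'->3' order), `context`, `mean_level`, `n_sites`.
#' @export
metaprofile <- function(calls, features, context = "ALL_C", body_bins = 20L,
                        flank = 2000L, flank_bin = 100L, min_coverage = 4L) {
  if (body_bins <= 0L) stop("body_bins must be positive")
  if (flank_bin <= 0L || flank %% flank_bin != 0L) {
    stop("flank must be a positive multiple of flank_bin")
  }
  fdt <- genes_to_dt(features)
  if (!"strand" %in% names(fdt)) fdt[, strand := "+"]
  sites <- filter_context(as.data.table(calls), context, min_coverage)
  flank_bins <- as.integer(flank / flank_bin)
  n_bins <- 2L * flank_bins + body_bins
  grid <- data.table::data.table(bin_index = seq_len(n_bins))
  grid[, region := c(rep("upstream", flank_bins), rep("body", body_bins),
                     rep("downstream", flank_bins))]
  if (!nrow(sites) || !nrow(fdt)) {
    grid[, `:=`(context = context, mean_level = NA_real_, n_sites = 0L)]
    return(grid[])
  }

  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, sites$pos))
  ext_gr <- GenomicRanges::GRanges(
    fdt$chrom, IRanges::IRanges(pmax(fdt$start - flank, 1L), fdt$end + flank))
  ov <- GenomicRanges::findOverlaps(site_gr, ext_gr, ignore.strand = TRUE)
  si <- S4Vectors::queryHits(ov); fi <- S4Vectors::subjectHits(ov)
  pos <- sites$pos[si]
  fs <- fdt$start[fi]; fe <- fdt$end[fi]
  minus <- fdt$strand[fi] == "-"
  width <- fe - fs + 1

  # oriented distance: d5 < 0 upstream of the 5' end, in [0,1) scaled body,
  # > 1 downstream (handled piecewise below)
  in_body <- pos >= fs & pos <= fe
  up <- ifelse(minus, pos > fe, pos < fs)       # 5' flank
  dist5 <- ifelse(minus, fe - pos, pos - fs)    # bp from 5' end (negative in flank)
  bin <- integer(length(pos))
  bin[up] <- flank_bins - ((-dist5[up] - 1L) %/% flank_bin)  # 1 = far 5'
  # midpoint offset keeps body binning mirror-symmetric under strand reversal
  rel <- (dist5[in_body] + 0.5) / width[in_body]
  bin[in_body] <- flank_bins + pmin(as.integer(rel * body_bins) + 1L, body_bins)
  down <- !up & !in_body
  dist3 <- ifelse(minus, fs - pos, pos - fe)    # bp past the 3' end
  bin[down] <- flank_bins + body_bins + ((dist3[down] - 1L) %/% flank_bin) + 1L

  hits <- data.table::data.table(bin_index = bin,
                                 mc = sites$mc_count[si],
                                 total = sites$total_count[si])
  agg <- hits[, .(mean_level = sum(mc) / sum(total), n_sites = .N),
              by = bin_index]
  out <- merge(grid, agg, by = "bin_index", all.x = TRUE)
  out[is.na(n_sites), n_sites := 0L]
  out[, context := context]
  data.table::setcolorder(out, c("region", "bin_index", "context",
                                 "mean_level", "n_sites"))
  data.table::setorder(out, bin_index)
  out[]
}

#' Distribution of per-site methylation levels in 10% bins
#'
#' Assigns each covered context site's level `mc/total` to ten bins
#' `[0,10%), [10,20%), ..., [90,100%]` (final bin closed) and reports the
#' fraction of sites per bin.
#'
#' @param calls Pooled call table for one sample.
#' @param context Sequence context (or `"ALL_C"`).
#' @param min_coverage Per-site coverage floor (default 4).
#' @return A `data.table`: `context`, `bin_index` (1-10), `lower`, `upper`,
#'   `n_sites`, `fraction` (sums to 1).
#' @export
level_histogram <- function(calls, context = "ALL_C", min_coverage = 4L) {
  sites <- filter_context(as.data.table(calls), context, min_coverage)
  lev <- sites$mc_count / sites$total_count
  bin <- pmin(as.integer(lev * 10) + 1L, 10L)
  out <- data.table::data.table(context = context, bin_index = 1:10,
                                lower = seq(0, 0.9, 0.1),
                                upper = seq(0.1, 1.0, 0.1),
                                n_sites = tabulate(bin, nbins = 10L))
  out[, fraction := if (length(lev)) n_sites / length(lev) else NA_real_]
  out[]
}

#' Relative proportions of methylated cytosines by context
#'
#' Among all called methylated cytosines, the fraction in each of the CG,
#' CHG and CHH contexts (three non-negative fractions summing to 1).
#'
#' @param calls Either the output of [call_sites()] (rows with
#'   `is_methylated == TRUE` are counted) or a named numeric vector of
#'   methylated-site counts with names `CG`, `CHG`, `CHH`.
#' @return A `data.table`: `context`, `n_methylated`, `proportion`.
#' @export
context_proportions <- function(calls) {
  counts <- if (is.numeric(calls)) {
    stopifnot(all(CONTEXTS %in% names(calls)))
    calls[CONTEXTS]
  } else {
    calls <- as.data.table(calls)
    if ("is_methylated" %in% names(calls)) calls <- calls[is_methylated == TRUE]
    vapply(CONTEXTS, function(cc) sum(calls$context == cc), numeric(1))
  }
  if (sum(counts) == 0) stop("no methylated cytosines: proportions undefined")
  data.table::data.table(context = CONTEXTS,
                         n_methylated = as.numeric(counts),
                         proportion = as.numeric(counts) / sum(counts))
}

#' Genome-wide methylation summary per sample
#'
#' Per context and overall: the number of covered (testable) cytosines, the
#' number called methylated, and the percentage methylated — the per-genome
#' table summarising a sample's methylome.
#'
#' @param calls Output of [call_sites()] for one sample.
#' @param sample_id Optional sample label.
#' @return A `data.table`: `sample_id`, `context` (`ALL_C`, `CG`, `CHG`,
#'   `CHH`), `n_sites`, `n_methylated`, `percent_methylated` (0-100).
#' @export
genome_summary <- function(calls, sample_id = NA_character_) {
  calls <- as.data.table(calls)
  if (!"is_methylated" %in% names(calls)) {
    stop("genome_summary expects called sites (run call_sites first)")
  }
  per_ctx <- calls[, .(n_sites = .N, n_methylated = sum(is_methylated)),
                   by = context]
  all_row <- data.table::data.table(context = "ALL_C", n_sites = nrow(calls),
                                    n_methylated = sum(calls$is_methylated))
  out <- rbind(all_row, per_ctx[order(match(context, CONTEXTS))])
  out[, percent_methylated := data.table::fifelse(
    n_sites > 0L, 100 * n_methylated / n_sites, NA_real_)]
  out[, sample_id := sample_id]
  data.table::setcolorder(out, c("sample_id", "context", "n_sites",
                                 "n_methylated", "percent_methylated"))
  out[]
}
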