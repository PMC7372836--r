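# context-specific DMR criteria: minimum covered context sites per window and
# minimum absolute methylation-level difference
DMR_CRITERIA <- list(
  CG    = list(min_sites = 5L,  min_delta = 0.25),
  CHG   = list(min_sites = 5L,  min_delta = 0.25),
  CHH   = list(min_sites = 15L, min_delta = 0.15),
  ALL_C = list(min_sites = 20L, min_delta = 0.20)
)

#' Pearson's chi-square test on a 2x2 methylation contingency table
#'
#' Tests association between sample and methylation state for pooled window
#' counts: rows are samples A and B, columns are methylated and unmethylated
#' read counts. The statistic is the standard 2x2 Pearson chi-square without
#' continuity correction, `N*(ad-bc)^2 / (r1*r2*c1*c2)`, with the p-value
#' from the upper tail of the chi-square distribution with 1 df. Vectorised
#' over windows. Tables with a zero row or column margin have no defined
#' statistic and return `NA` (such windows are skipped by [call_dmrs()]).
#'
#' @param mc_a,u_a Methylated / unmethylated read counts in sample A.
#' @param mc_b,u_b Methylated / unmethylated read counts in sample B.
#' @return A list with numeric vectors `chi2_stat` and `p_value`.
#' @examples
#' chi_square_test(30, 70, 60, 40)  # chi2 ~ 18.18
#' @export
chi_square_test <- function(mc_a, u_a, mc_b, u_b) {
  if (any(c(mc_a, u_a, mc_b, u_b) < 0, na.rm = TRUE)) {
    stop("counts must be non-negative")
  }
  a <- as.numeric(mc_a); b <- as.numeric(u_a)
  c_ <- as.numeric(mc_b); d <- as.numeric(u_b)
  n <- a + b + c_ + d
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  denom <- r1 * r2 * c1 * c2
  chi2 <- ifelse(denom > 0, n * (a * d - b * c_)^2 / denom, NA_real_)
  list(chi2_stat = chi2,
       p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Call differentially methylated regions between two samples
#'
#' Applies the per-window chi-square test to a pair of window tables built
#' with identical geometry ([build_windows()]), corrects p-values across all
#' tested windows of the context by Benjamini-Hochberg, and retains windows
#' meeting the context-specific criteria: covered context sites in the
#' window >= 5 (CG/CHG), >= 15 (CHH) or >= 20 (all-C); absolute
#' methylation-level difference >= 0.25, 0.15 or 0.20 respectively; and
#' q <= 0.05. Overlapping surviving windows of the same direction are merged
#' into one reported DMR spanning their union. The direction is relative to
#' sample B: `hyper` means B is more methylated than A.
#'
#' @param windows_a,windows_b Window tables for samples A and B.
#' @param context `"CG"`, `"CHG"`, `"CHH"` or `"ALL_C"`; defaults to the
#'   context recorded in `windows_a`.
#' @param q_threshold FDR threshold (default 0.05).
#' @param min_sites,min_delta Override the context defaults.
#' @param merge Merge overlapping same-direction windows (default `TRUE`).
#' @return A `data.table` of DMRs: `chrom`, `start` (0-based), `end`,
#'   `context`, `direction` (`hyper`/`hypo`), `delta` (level B - level A over
#'   pooled counts), `chi2_stat`, `q_value` (minimum across merged windows),
#'   `n_windows`, `n_sites`.
#' @export
call_dmrs <- function(windows_a, windows_b, context = NULL,
                      q_threshold = 0.05, min_sites = NULL, min_delta = NULL,
                      merge = TRUE) {
  windows_a <- as.data.table(windows_a)
  windows_b <- as.data.table(windows_b)
  if (is.null(context)) context <- windows_a$context[1]
  if (!context %in% names(DMR_CRITERIA)) {
    stop(sprintf("unknown context label '%s'", context))
  }
  crit <- DMR_CRITERIA[[context]]
  if (is.null(min_sites)) min_sites <- crit$min_sites
  if (is.null(min_delta)) min_delta <- crit$min_delta

  w <- merge(windows_a, windows_b, by = c("chrom", "start", "end"),
             suffixes = c("_a", "_b"))
  if (nrow(w) != nrow(windows_a) || nrow(w) != nrow(windows_b)) {
    stop("window tables do not share an identical window grid")
  }
  tested <- w[total_a > 0L & total_b > 0L &
                (mc_a + mc_b) > 0L &
                ((total_a - mc_a) + (total_b - mc_b)) > 0L]
  n_skipped <- nrow(w) - nrow(tested)
  if (n_skipped > 0L) {
    message(sprintf("call_dmrs: %d window(s) with a degenerate margin skipped",
                    n_skipped))
  }
  if (!nrow(tested)) return(empty_dmr_table())
  ct <- chi_square_test(tested$mc_a, tested$total_a - tested$mc_a,
                        tested$mc_b, tested$total_b - tested$mc_b)
  tested[, chi2_stat := ct$chi2_stat]
  tested[, p_value := ct$p_value]
  tested[, q_value := stats::p.adjust(p_value, method = "BH")]
  tested[, delta := mc_b / total_b - mc_a / total_a]
  hits <- tested[pmin(n_sites_a, n_sites_b) >= min_sites &
                   abs(delta) >= min_delta & q_value <= q_threshold]
  if (!nrow(hits)) return(empty_dmr_table())
  hits[, direction := data.table::fifelse(delta > 0, "hyper", "hypo")]
  hits[, n_sites := pmin(n_sites_a, n_sites_b)]

  ctx_val <- context
  if (!merge) {
    out <- hits[, .(chrom, start, end, context = ctx_val, direction, delta,
                    chi2_stat, q_value, n_windows = 1L, n_sites)]
    data.table::setorder(out, chrom, start)
    return(out[])
  }

  # union of overlapping/adjacent-on-overlap same-direction windows;
  # summary stats pool the constituent windows' counts
  out <- hits[, {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      "w", IRanges::IRanges(start + 1L, end)))
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start + 1L, end), IRanges::ranges(gr))
    grp <- S4Vectors::subjectHits(ov)
    data.table::data.table(
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      delta = as.numeric(tapply(mc_b, grp, sum) / tapply(total_b, grp, sum) -
                           tapply(mc_a, grp, sum) / tapply(total_a, grp, sum)),
      chi2_stat = as.numeric(tapply(chi2_stat, grp, max)),
      q_value = as.numeric(tapply(q_value, grp, min)),
      n_windows = as.integer(tabulate(grp, nbins = length(gr))),
      n_sites = as.integer(tapply(n_sites, grp, max)))
  }, by = .(chrom, direction)]
  out[, context := ctx_val]
  data.table::setcolorder(out, c("chrom", "start", "end", "context",
                                 "direction", "delta", "chi2_stat", "q_value",
                                 "n_windows", "n_sites"))
  data.table::setorder(out, chrom, start)
  out[]
}

empty_dmr_table <- function() {
  data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    context = character(), direction = character(), delta = numeric(),
    chi2_stat = numeric(), q_value = numeric(), n_windows = integer(),
    n_sites = integer())
}

#' Annotate differentially methylated genes
#'
#' A gene is a DMG when a DMR overlaps its body extended by 2 kb flanks on
#' both sides by more than 1 nt. Genes hit by both hyper- and hypomethylated
#' DMRs are labelled `mixed`.
#'
#' @param dmrs DMR table from [call_dmrs()] (0-based half-open `start`/`end`).
#' @param genes A `GRanges` of gene records with a `gene_id` or `ID` metadata
#'   column, or a data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param flank Flank width in bp (default 2000).
#' @param min_overlap Minimum overlap in nt, exclusive bound is
#'   `min_overlap - 1` (default 2, i.e. overlap > 1 nt).
#' @return A `data.table`: `gene_id`, `n_dmrs`, `direction`
#'   (`hyper`/`hypo`/`mixed`), `dmr_ids` (comma-separated `chrom:start-end`).
#' @export
annotate_dmgs <- function(dmrs, genes, flank = 2000L, min_overlap = 2L) {
  dmrs <- as.data.table(dmrs)
  gdt <- genes_to_dt(genes)
  if (!nrow(dmrs) || !nrow(gdt)) {
    return(data.table::data.table(gene_id = character(), n_dmrs = integer(),
                                  direction = character(), dmr_ids = character()))
  }
  dmr_gr <- GenomicRanges::GRanges(dmrs$chrom,
                                   IRanges::IRanges(dmrs$start + 1L, dmrs$end))
  gene_gr <- GenomicRanges::GRanges(
    gdt$chrom, IRanges::IRanges(pmax(gdt$start - flank, 1L), gdt$end + flank))
  ov <- GenomicRanges::findOverlaps(dmr_gr, gene_gr,
                                    minoverlap = as.integer(min_overlap))
  if (!length(ov)) {
    return(data.table::data.table(gene_id = character(), n_dmrs = integer(),
                                  direction = character(), dmr_ids = character()))
  }
  pairs <- data.table::data.table(
    gene_id = gdt$gene_id[S4Vectors::subjectHits(ov)],
    direction = dmrs$direction[S4Vectors::queryHits(ov)],
    dmr_id = sprintf("%s:%d-%d", dmrs$chrom[S4Vectors::queryHits(ov)],
                     dmrs$start[S4Vectors::queryHits(ov)],
                     dmrs$end[S4Vectors::queryHits(ov)]))
  out <- pairs[, .(
    n_dmrs = .N,
    direction = if (length(unique(direction)) > 1L) "mixed" else direction[1],
    dmr_ids = paste(dmr_id, collapse = ",")), by = gene_id]
  data.table::setorder(out, gene_id)
  out[]
}

# accepts GRanges (gene_id/ID mcol) or data.frame-like gene coordinates
genes_to_dt <- function(genes) {
  if (methods::is(genes, "GRanges")) {
    ids <- if ("gene_id" %in% names(mcols(genes))) genes$gene_id
           else if ("ID" %in% names(mcols(genes))) as.character(genes$ID)
           else if ("feature_id" %in% names(mcols(genes))) genes$feature_id
           else sprintf("feature%06d", seq_along(genes))
    if ("type" %in% names(mcols(genes))) {
      keep <- as.character(genes$type) == "gene"
      genes <- genes[keep]; ids <- ids[keep]
    }
    data.table::data.table(gene_id = ids,
                           chrom = as.character(GenomicRanges::seqnames(genes)),
                           start = GenomicRanges::start(genes),
                           end = GenomicRanges::end(genes),
                           strand = as.character(GenomicRanges::strand(genes)))
  } else {
    dt <- as.data.table(genes)
    stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(dt)))
    dt
  }
}

#' Methylated-cytosine density along chromosomes
#'
#' Counts called methylated sites per fixed-width bin, per chromosome,
#' strand and context — the track behind chromosome-level 5mC density plots.
#'
#' @param calls Output of [call_sites()] (only `is_methylated` rows counted).
#' @param bin Bin width in bp (default 100 kb).
#' @param seqlengths Optional named chromosome lengths; when given, the full
#'   bin grid is emitted including zero-count bins.
#' @return A `data.table`: `chrom`, `strand`, `context`, `start` (0-based),
#'   `end`, `count`.
#' @export
chromosome_density <- function(calls, bin = 100000L, seqlengths = NULL) {
  calls <- as.data.table(calls)
  mcalls <- if ("is_methylated" %in% names(calls)) calls[is_methylated == TRUE]
            else calls
  counts <- if (nrow(mcalls)) {
    mcalls[, .(count = .N),
           by = .(chrom, strand, context, start = ((pos - 1L) %/% bin) * bin)]
  } else {
    data.table::data.table(chrom = character(), strand = character(),
                           context = character(), start = integer(),
                           count = integer())
  }
  if (!is.null(seqlengths)) {
    grid <- data.table::rbindlist(lapply(names(seqlengths), function(ch) {
      data.table::CJ(chrom = ch, strand = c("+", "-"), context = CONTEXTS,
                     start = seq.int(0L, max(0L, seqlengths[[ch]] - 1L), by = bin))
    }))
    counts <- merge(grid, counts, by = c("chrom", "strand", "context", "start"),
                    all.x = TRUE)
    counts[is.na(count), count := 0L]
    counts[, end := pmin(start + bin, seqlengths[chrom]), by = chrom]
  } else {
    counts[, end := start + bin]
  }
  data.table::setorder(counts, chrom, start, strand, context)
  counts[]
}
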