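#' Enumerate sliding windows along chromosomes
#'
#' Windows of `window` bp advance by `step` bp from position 0 of each
#' chromosome (coordinates are BED-style 0-based half-open). A window is
#' truncated at the chromosome end; a truncated tail window is emitted only
#' when it extends coverage beyond the previous window's end, so a 1000 bp
#' chromosome yields the nine windows `[0,200), [100,300), ..., [800,1000)`.
#'
#' @param seqlengths Named integer vector of chromosome lengths.
#' @param window Window width in bp (default 200).
#' @param step Step in bp (default 100).
#' @return A `data.table` with `chrom`, `start` (0-based), `end` (exclusive).
#' @export
enumerate_windows <- function(seqlengths, window = 200L, step = 100L) {
  if (step <= 0L || window < step) {
    stop("require step > 0 and window >= step")
  }
  out <- lapply(names(seqlengths), function(ch) {
    len <- as.integer(seqlengths[[ch]])
    if (len <= 0L) return(NULL)
    starts <- seq.int(0L, len - 1L, by = step)
    ends <- pmin(starts + window, len)
    keep <- c(TRUE, ends[-1L] > ends[-length(ends)])
    data.table::data.table(chrom = ch, start = starts[keep], end = ends[keep])
  })
  data.table::rbindlist(out)
}

#' Build sliding-window methylation levels for one sample
#'
#' Merges biological replicates of a sample into fixed sliding windows:
#' per-site counts are pooled across replicates, sites below the per-site
#' coverage floor are dropped, sites are filtered to the requested context
#' (`"ALL_C"` keeps every context; for CG and CHG the two strands of a
#' symmetric site simply both contribute to the window), and counts are
#' summed across the sites of each window. The window methylation level is
#' the pooled ratio `mc/total`.
#'
#' @param replicates A list of call tables (one per biological replicate),
#'   or a single call table.
#' @param seqlengths Named integer vector of chromosome lengths.
#' @param context `"CG"`, `"CHG"`, `"CHH"` or `"ALL_C"`.
#' @param window,step Window geometry in bp (defaults 200/100).
#' @param min_coverage Per-site pooled coverage floor (default 4).
#' @return A `data.table` with `chrom`, `start` (0-based), `end`, `context`,
#'   `n_sites` (covered context cytosine positions in the window), `mc`,
#'   `total` and `level` (`NA` when the window holds no covered site).
#' @export
build_windows <- function(replicates, seqlengths, context = "ALL_C",
                          window = 200L, step = 100L, min_coverage = 4L) {
  if (!context %in% c(CONTEXTS, "ALL_C")) {
    stop(sprintf("unknown context label '%s'", context))
  }
  if (data.table::is.data.table(replicates) || is.data.frame(replicates)) {
    replicates <- list(replicates)
  }
  ctx_label <- context
  pooled <- pool_replicates(replicates)
  pooled <- pooled[total_count >= min_coverage]
  if (ctx_label != "ALL_C") pooled <- pooled[which(pooled$context == ctx_label)]

  win <- enumerate_windows(seqlengths, window, step)
  win[, window_id := .I]
  agg <- if (nrow(pooled)) {
    hits <- data.table::rbindlist(lapply(split(seq_len(nrow(win)), win$chrom),
      function(ix) {
        ch <- win$chrom[ix[1]]
        sites <- pooled[chrom == ch]
        if (!nrow(sites)) return(NULL)
        ov <- IRanges::findOverlaps(
          IRanges::IRanges(win$start[ix] + 1L, win$end[ix]),
          IRanges::IRanges(sites$pos, sites$pos))
        data.table::data.table(
          window_id = win$window_id[ix][S4Vectors::queryHits(ov)],
          mc = sites$mc_count[S4Vectors::subjectHits(ov)],
          total = sites$total_count[S4Vectors::subjectHits(ov)])
      }))
    if (nrow(hits)) hits[, .(n_sites = .N, mc = sum(mc), total = sum(total)),
                         by = window_id]
    else NULL
  } else NULL

  win[, `:=`(n_sites = 0L, mc = 0L, total = 0L)]
  if (!is.null(agg)) {
    win[agg, on = "window_id",
        `:=`(n_sites = i.n_sites, mc = i.mc, total = i.total)]
  }
  win[, level := data.table::fifelse(total > 0L, mc / total, NA_real_)]
  win[, context := ctx_label]
  data.table::setcolorder(win, c("chrom", "start", "end", "context",
                                 "n_sites", "mc", "total", "level"))
  win[, window_id := NULL]
  win[]
}
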