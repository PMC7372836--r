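#' Estimate the bisulfite conversion rate from a lambda spike-in
#'
#' The lambda phage genome carries no 5mC, so every methylated call on it is
#' a conversion failure (or base-calling error). The conversion rate is the
#' pooled fraction of converted read-bases over all lambda cytosines:
#' `sum(total - mc) / sum(total)`; its complement is the non-conversion rate
#' used as the null rate of the binomial methylation caller.
#'
#' @param lambda_calls Call table for the lambda spike-in (see [read_calls()]);
#'   replicates may simply be concatenated.
#' @param sample_id Optional sample label carried into the result.
#' @return A one-row `data.table`: `sample_id`, `converted_reads`,
#'   `total_reads`, `conversion_rate`, `non_conversion_rate`.
#' @examples
#' lam <- data.frame(chrom = "lambda", pos = 1:2, strand = "+",
#'                   context = "CHH", mc_count = c(1L, 0L),
#'                   total_count = c(30L, 20L))
#' estimate_conversion(lam)
#' @export
estimate_conversion <- function(lambda_calls, sample_id = NA_character_) {
  lambda_calls <- as.data.table(lambda_calls)
  if (!nrow(lambda_calls)) stop("lambda call table is empty")
  tot <- sum(as.numeric(lambda_calls$total_count))
  if (tot == 0) stop("lambda call table has zero total reads")
  mc <- sum(as.numeric(lambda_calls$mc_count))
  data.table::data.table(
    sample_id = sample_id,
    converted_reads = tot - mc,
    total_reads = tot,
    conversion_rate = (tot - mc) / tot,
    non_conversion_rate = mc / tot)
}

#' Call methylated cytosines by binomial test against the non-conversion null
#'
#' For each covered cytosine the observed methylated-read count is tested
#' against the null that all apparent methylation is bisulfite non-conversion:
#' `p = P(X >= mc_count)` with `X ~ Binomial(total_count, non_conversion_rate)`
#' (one-sided upper tail). p-values are corrected across all tested sites of
#' the sample by Benjamini-Hochberg; a site is called methylated when
#' `q <= q_threshold`. Sites below the coverage floor are excluded from
#' testing entirely. Replicates of a sample should be pooled (counts summed
#' per site) before calling; see [pool_replicates()].
#'
#' @param sites Call table for one sample (replicates already pooled).
#' @param non_conversion_rate Null methylation probability in (0,1), from
#'   [estimate_conversion()].
#' @param q_threshold FDR threshold (default 0.05).
#' @param min_coverage Minimum reads for a site to be testable (default 4).
#' @return The input table restricted to tested sites, with `p_value`,
#'   `q_value` and `is_methylated` columns appended.
#' @export
call_sites <- function(sites, non_conversion_rate, q_threshold = 0.05,
                       min_coverage = 4L) {
  if (!is.numeric(non_conversion_rate) || non_conversion_rate <= 0 ||
      non_conversion_rate >= 1) {
    stop("non_conversion_rate must lie strictly between 0 and 1")
  }
  sites <- as.data.table(sites)
  tested <- sites[total_count >= min_coverage]
  tested[, p_value := stats::pbinom(mc_count - 1L, total_count,
                                    non_conversion_rate, lower.tail = FALSE)]
  tested[, q_value := stats::p.adjust(p_value, method = "BH")]
  tested[, is_methylated := q_value <= q_threshold]
  tested[]
}

#' Pool replicate call tables of one sample
#'
#' Sums methylated and total counts per site (chrom, pos, strand, context)
#' across biological replicates, the arithmetic used before site calling.
#'
#' @param replicates A list of call tables.
#' @return A single pooled call table.
#' @export
pool_replicates <- function(replicates) {
  stopifnot(is.list(replicates), length(replicates) >= 1L)
  all <- data.table::rbindlist(lapply(replicates, as.data.table))
  pooled <- all[, .(mc_count = sum(mc_count), total_count = sum(total_count)),
                by = .(chrom, pos, strand, context)]
  data.table::setorder(pooled, chrom, pos, strand)
  pooled[]
}
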