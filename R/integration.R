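EXPR_BINS <- c("None", "Low", "Moderate", "High")
GENE_REGIONS <- c("promoter", "gene_body", "downstream_2kb")

#' Bin genes by expression level
#'
#' FPKM bins: `None` (FPKM <= 1, non-expressed), `Low` (1 < FPKM <= 10),
#' `Moderate` (10 < FPKM <= 100), `High` (FPKM > 100). The boundaries are
#' half-open and disjoint, so every gene falls in exactly one bin; a gene at
#' exactly FPKM = 100 is `Moderate`.
#'
#' @param expression A data.frame/data.table with `gene_id`, `fpkm` and
#'   optionally `sample_id`.
#' @return The input with an `expr_bin` factor column appended.
#' @export
bin_expression <- function(expression) {
  expression <- as.data.table(expression)
  if (anyNA(expression$fpkm) || any(expression$fpkm < 0)) {
    stop("FPKM values must be non-negative")
  }
  expression[, expr_bin := cut(fpkm, breaks = c(-Inf, 1, 10, 100, Inf),
                               labels = EXPR_BINS, right = TRUE)]
  expression[]
}

#' Per-gene methylation levels and tertile bins by genic region and context
#'
#' Pools methylation counts per gene over each genic region (`promoter`,
#' `gene_body`, `downstream_2kb`) and sequence context, then bins the genes
#' of every region x context stratum into methylation tertiles over genes
#' with at least one covered site: the bottom third is `Low`, the middle
#' `Moderate`, the top `High`; genes with zero covered context sites in the
#' region are `None`. Ties are broken by gene id after sorting on level, so
#' the binning is reproducible.
#'
#' @param calls Pooled call table for one sample.
#' @param features Feature `GRanges` from [derive_features()].
#' @param min_coverage Per-site coverage floor (default 4).
#' @return A `data.table`: `gene_id`, `region`, `context`, `mc`, `total`,
#'   `n_sites`, `level`, `meth_bin`.
#' @export
gene_methylation <- function(calls, features, min_coverage = 4L) {
  calls <- as.data.table(calls)[total_count >= min_coverage]
  feats <- features[features$kind %in% GENE_REGIONS]
  genes <- unique(stats::na.omit(feats$gene_id))
  grid <- data.table::CJ(gene_id = genes, region = GENE_REGIONS,
                         context = CONTEXTS)
  if (!nrow(calls) || !length(feats)) {
    grid[, `:=`(mc = 0L, total = 0L, n_sites = 0L, level = NA_real_,
                meth_bin = "None")]
    return(grid[])
  }
  site_gr <- GenomicRanges::GRanges(calls$chrom,
                                    IRanges::IRanges(calls$pos, calls$pos))
  ov <- GenomicRanges::findOverlaps(site_gr, feats, ignore.strand = TRUE)
  hits <- data.table::data.table(
    gene_id = feats$gene_id[S4Vectors::subjectHits(ov)],
    region = feats$kind[S4Vectors::subjectHits(ov)],
    context = calls$context[S4Vectors::queryHits(ov)],
    mc = calls$mc_count[S4Vectors::queryHits(ov)],
    total = calls$total_count[S4Vectors::queryHits(ov)])
  agg <- hits[, .(mc = sum(mc), total = sum(total), n_sites = .N),
              by = .(gene_id, region, context)]
  out <- merge(grid, agg, by = c("gene_id", "region", "context"), all.x = TRUE)
  out[is.na(n_sites), `:=`(mc = 0L, total = 0L, n_sites = 0L)]
  out[, level := data.table::fifelse(total > 0L, mc / total, NA_real_)]
  out[, meth_bin := "None"]
  out[n_sites > 0L, meth_bin := {
    o <- order(level, gene_id)
    r <- integer(.N); r[o] <- seq_len(.N)
    c("Low", "Moderate", "High")[ceiling(3 * r / .N)]
  }, by = .(region, context)]
  data.table::setorder(out, gene_id, region, context)
  out[]
}

#' Mean methylation stratified by expression bin
#'
#' Joins per-gene region x context methylation with binned expression and
#' reports, per expression bin x region x context (x sample when present),
#' the count-pooled methylation level and the number of genes.
#'
#' @param gene_meth Output of [gene_methylation()].
#' @param expression Output of [bin_expression()].
#' @return A `data.table`: join keys, `expr_bin`, `region`, `context`,
#'   `mean_level`, `n_genes`.
#' @export
stratified_levels <- function(gene_meth, expression) {
  gene_meth <- as.data.table(gene_meth)
  expression <- as.data.table(expression)
  if (!"expr_bin" %in% names(expression)) expression <- bin_expression(expression)
  joined <- merge(gene_meth, expression, by = "gene_id",
                  allow.cartesian = TRUE)
  joined <- joined[total > 0L]
  if (!nrow(joined)) {
    warning("no gene has both covered methylation and expression")
    return(data.table::data.table(expr_bin = character(), region = character(),
                                  context = character(), mean_level = numeric(),
                                  n_genes = integer()))
  }
  keys <- intersect(c("sample_id", "expr_bin", "region", "context"),
                    names(joined))
  out <- joined[, .(mean_level = sum(mc) / sum(total), n_genes = .N),
                by = keys]
  data.table::setorderv(out, keys)
  out[]
}

#' Spearman correlation between methylation and expression
#'
#' Rank correlation (average ranks for ties) between per-gene methylation
#' levels in one genic region x context and FPKM, with the p-value from the
#' large-sample approximation. Genes without covered methylation in the
#' region are dropped before ranking.
#'
#' @param gene_meth Output of [gene_methylation()].
#' @param expression Expression table with `gene_id`, `fpkm`.
#' @param region One of `promoter`, `gene_body`, `downstream_2kb`.
#' @param context One of `CG`, `CHG`, `CHH`.
#' @return A one-row `data.table`: `region`, `context`, `n`, `rho`, `p_value`.
#' @export
methylation_expression_correlation <- function(gene_meth, expression,
                                               region = "gene_body",
                                               context = "CG") {
  stopifnot(region %in% GENE_REGIONS, context %in% CONTEXTS)
  reg_val <- region; ctx_val <- context
  gm <- as.data.table(gene_meth)
  gm <- gm[which(gm$region == reg_val & gm$context == ctx_val & gm$total > 0L)]
  joined <- merge(gm[, .(gene_id, level)],
                  as.data.table(expression)[, .(gene_id, fpkm)], by = "gene_id")
  if (nrow(joined) < 10L) {
    stop(sprintf("only %d genes with both methylation and expression; need >= 10",
                 nrow(joined)))
  }
  ct <- suppressWarnings(stats::cor.test(joined$level, joined$fpkm,
                                         method = "spearman", exact = FALSE))
  data.table::data.table(region = region, context = context,
                         n = nrow(joined),
                         rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Intersect differentially methylated and differentially expressed genes
#'
#' Set intersection on gene id between a DMG table and a DEG table, with
#' both directions reported per common gene, plus the three-way counts a
#' Venn diagram would show.
#'
#' @param dmgs DMG table from [annotate_dmgs()] (`gene_id`, `direction`).
#' @param degs DEG table with `gene_id` and `direction` (`up`/`down`).
#' @return A list: `common` (`data.table` of shared genes with
#'   `dmg_direction` and `deg_direction`) and `counts`
#'   (`dmg_only`, `deg_only`, `common`).
#' @export
intersect_dmg_deg <- function(dmgs, degs) {
  dmgs <- as.data.table(dmgs); degs <- as.data.table(degs)
  if (anyDuplicated(dmgs$gene_id)) {
    stop("duplicate gene_ids in the DMG table")
  }
  if (anyDuplicated(degs$gene_id)) {
    stop("duplicate gene_ids in the DEG table")
  }
  common_ids <- intersect(dmgs$gene_id, degs$gene_id)
  common <- data.table::data.table(gene_id = sort(common_ids))
  common[, dmg_direction := dmgs$direction[match(gene_id, dmgs$gene_id)]]
  common[, deg_direction := degs$direction[match(gene_id, degs$gene_id)]]
  list(common = common,
       counts = list(dmg_only = length(setdiff(dmgs$gene_id, degs$gene_id)),
                     deg_only = length(setdiff(degs$gene_id, dmgs$gene_id)),
                     common = length(common_ids)))
}

#' Call differentially expressed genes with a simple fold-change rule
#'
#' A documented input-generation rule for synthetic tests (the pipeline
#' otherwise takes DEG lists as an input): a gene is a DEG when the absolute
#' log2 fold-change between the two conditions' mean FPKM is at least
#' `min_log2fc` and both condition means exceed `min_fpkm`.
#'
#' @param expression Long expression table with `gene_id`, `condition`,
#'   `fpkm` (replicates averaged within condition).
#' @param conditions Character vector of the two condition labels (A, B);
#'   defaults to the first two in the table.
#' @param min_log2fc Minimum |log2 fold-change| (default 1).
#' @param min_fpkm Expression floor for both conditions (default 1).
#' @return A `data.table`: `gene_id`, `mean_a`, `mean_b`, `log2fc`,
#'   `direction` (`up` = higher in B).
#' @export
call_degs <- function(expression, conditions = NULL, min_log2fc = 1,
                      min_fpkm = 1) {
  expression <- as.data.table(expression)
  if (is.null(conditions)) conditions <- unique(expression$condition)[1:2]
  stopifnot(length(conditions) == 2L)
  means <- expression[condition %in% conditions,
                      .(fpkm = mean(fpkm)), by = .(gene_id, condition)]
  wide <- data.table::dcast(means, gene_id ~ condition, value.var = "fpkm")
  data.table::setnames(wide, conditions, c("mean_a", "mean_b"))
  wide[, log2fc := log2(mean_b / mean_a)]
  degs <- wide[mean_a > min_fpkm & mean_b > min_fpkm &
                 abs(log2fc) >= min_log2fc]
  degs[, direction := data.table::fifelse(log2fc > 0, "up", "down")]
  degs[]
}
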