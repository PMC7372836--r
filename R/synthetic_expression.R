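#' Generate expression tables correlated with gene-body methylation
#'
#' FPKM values are drawn through a Gaussian copula on the ranks of gene-body
#' CG methylation, so that the *population* Spearman correlation between
#' methylation and expression equals `expression_copula_rho`: the
#' methylation ranks are mapped to normal scores, mixed with independent
#' noise at latent correlation `2*sin(pi*rho/6)` (the inverse of the
#' Gaussian-copula Spearman relation), and mapped through a log-normal FPKM
#' scale spanning the None/Low/Moderate/High expression bins. At
#' `|rho| = 1` the copula degenerates to an exact monotone map. A
#' `deg_fraction` of genes receives a planted condition-B log2 fold-change
#' drawn from `deg_log2fc_range` with random sign; replicate FPKM values add
#' log-normal noise around the condition means.
#'
#' @param config A [synthetic_config()].
#' @param gene_meth_truth A data.frame with `gene_id` and `meth_level`
#'   (true gene-body CG methylation mean per gene); see
#'   [gene_body_truth()].
#' @return A list: `expression` (long `data.table`: `gene_id`, `condition`,
#'   `replicate`, `fpkm`), `condition_means` (`gene_id`, per-condition mean
#'   FPKM), `true_degs` (`gene_id`, `log2fc`, `direction`).
#' @export
generate_expression <- function(config, gene_meth_truth) {
  config <- validate_synthetic_config(config)
  gm <- as.data.table(gene_meth_truth)
  stopifnot(all(c("gene_id", "meth_level") %in% names(gm)))
  n <- nrow(gm)
  if (n == 0L) stop("no genes to generate expression for")
  rho <- config$expression_copula_rho
  set.seed(config$seed + SEED_EXPR)

  # normal scores of the methylation ranks (no ties for continuous levels)
  r <- rank(gm$meth_level, ties.method = "first")
  z_m <- stats::qnorm((r - 0.5) / n)
  if (abs(rho) == 1) {
    z <- sign(rho) * z_m
  } else {
    latent <- 2 * sin(pi * rho / 6)
    z <- latent * z_m + sqrt(1 - latent^2) * stats::rnorm(n)
  }
  base_fpkm <- 10^(0.8 + 1.2 * z)

  n_deg <- round(config$deg_fraction * n)
  deg_idx <- if (n_deg > 0) sample.int(n, n_deg) else integer()
  lfc <- numeric(n)
  lfc[deg_idx] <- stats::runif(n_deg, config$deg_log2fc_range[1],
                               config$deg_log2fc_range[2]) *
    sample(c(-1, 1), n_deg, replace = TRUE)

  cond <- config$condition_names
  means <- data.table::data.table(gene_id = gm$gene_id)
  means[[cond[1]]] <- base_fpkm
  means[[cond[2]]] <- base_fpkm * 2^lfc

  reps <- data.table::CJ(condition = cond,
                         replicate = seq_len(config$n_replicates))
  expr <- data.table::rbindlist(lapply(seq_len(nrow(reps)), function(i) {
    mu <- means[[reps$condition[i]]]
    data.table::data.table(gene_id = gm$gene_id,
                           condition = reps$condition[i],
                           replicate = reps$replicate[i],
                           fpkm = mu * 2^stats::rnorm(length(mu), 0, 0.15))
  }))
  true_degs <- data.table::data.table(
    gene_id = gm$gene_id[deg_idx], log2fc = lfc[deg_idx],
    direction = data.table::fifelse(lfc[deg_idx] > 0, "up", "down"))
  data.table::setorder(true_degs, gene_id)
  list(expression = expr, condition_means = means, true_degs = true_degs)
}

#' True gene-body methylation means from generator ground truth
#'
#' Averages the true per-site levels of one context over each gene body —
#' the quantity the expression copula conditions on.
#'
#' @param truth Truth table from [generate_methylome()].
#' @param genes Gene `GRanges` from [generate_genome()].
#' @param context Sequence context (default `"CG"`).
#' @return A `data.table`: `gene_id`, `meth_level`, `n_sites`.
#' @export
gene_body_truth <- function(truth, genes, context = "CG") {
  truth <- as.data.table(truth)
  gdt <- genes_to_dt(genes)
  ctx_val <- context
  sites <- truth[which(truth$context == ctx_val)]
  gr_sites <- GenomicRanges::GRanges(sites$chrom,
                                     IRanges::IRanges(sites$pos, sites$pos))
  gr_genes <- GenomicRanges::GRanges(gdt$chrom,
                                     IRanges::IRanges(gdt$start, gdt$end))
  ov <- GenomicRanges::findOverlaps(gr_sites, gr_genes, ignore.strand = TRUE)
  hits <- data.table::data.table(
    gene_id = gdt$gene_id[S4Vectors::subjectHits(ov)],
    true_level = sites$true_level[S4Vectors::queryHits(ov)])
  agg <- hits[, .(meth_level = mean(true_level), n_sites = .N), by = gene_id]
  out <- merge(data.table::data.table(gene_id = gdt$gene_id), agg,
               by = "gene_id", all.x = TRUE)
  out[is.na(n_sites), `:=`(meth_level = 0, n_sites = 0L)]
  data.table::setorder(out, gene_id)
  out[]
}
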