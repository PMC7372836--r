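#' Configuration for a synthetic WGBS study
#'
#' Bundles every knob of the synthetic-study generator with defaults that
#' reproduce the statistical structure of a poplar stem methylome: a
#' bimodal CG/CHG and low CHH methylation-level mixture, TE-dense
#' hypermethylated versus gene-rich hypomethylated regions, three
#' biological replicates at ~30x Poisson depth, an unmethylated lambda
#' spike-in with a small non-conversion probability (~0.49%), and
#' expression values with a tunable Spearman correlation to gene-body CG
#' methylation.
#'
#' @param seed Integer master seed; all generator stages derive their RNG
#'   state from it, so identical configs give byte-identical outputs.
#' @param genome_length Total genome length in bp.
#' @param n_chromosomes Number of chromosomes (lengths split evenly).
#' @param gc_fraction G+C fraction of the random genome.
#' @param n_genes,n_tes Number of genes / transposable elements to place.
#' @param gene_structure List: `n_exons` (range), `exon_length` (range, bp),
#'   `intron_length` (range, bp), `utr5_length`, `utr3_length` (bp).
#' @param te_class_weights Named proportions over `LTR`, `LINE`, `SINE`,
#'   `DNA`; must sum to 1.
#' @param context_methylation Per-context Beta-mixture spec: lists with
#'   `weights` (sum to 1), `means` and `conc` (Beta concentration) per
#'   component; a component mean of exactly 0 (or 1) is a point mass.
#'   Defaults put 0.45 (CG), 0.65 (CHG) and 0.83 (CHH) of sites in an
#'   unmethylated component, and 0.40 / 0.24 / 0.01 in a high component.
#' @param te_methylation_boost Additive true-level shift inside TE spans
#'   (clamped to \[0,1\]).
#' @param depth_mean Mean per-site read depth (Poisson).
#' @param n_replicates Biological replicates per condition.
#' @param planted_dmrs Optional data.frame of planted differential regions:
#'   `chrom`, `start`, `end` (1-based inclusive), `context`, `delta`
#'   (added to condition B's true level, clamped). Intervals must lie within
#'   the genome and not overlap each other.
#' @param lambda_length Length of the unmethylated lambda spike-in (bp).
#' @param non_conversion_rate Probability an unmethylated cytosine escapes
#'   bisulfite conversion.
#' @param expression_copula_rho Target population Spearman correlation in
#'   \[-1,1\] between gene-body CG methylation and expression.
#' @param deg_fraction Fraction of genes given a condition-B fold-change.
#' @param deg_log2fc_range Range the planted |log2 fold-changes| are drawn
#'   from.
#' @param condition_names Labels of the two conditions.
#' @return A validated config list of class `stemethyl_synth_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    genome_length = 200000L,
    n_chromosomes = 2L,
    gc_fraction = 0.34,
    n_genes = 40L,
    gene_structure = list(n_exons = c(1L, 4L), exon_length = c(200L, 400L),
                          intron_length = c(80L, 250L),
                          utr5_length = 100L, utr3_length = 120L),
    n_tes = 30L,
    te_class_weights = c(LTR = 0.4, LINE = 0.2, SINE = 0.1, DNA = 0.3),
    context_methylation = list(
      CG  = list(weights = c(0.45, 0.15, 0.40), means = c(0, 0.50, 0.97),
                 conc = c(1, 10, 25)),
      CHG = list(weights = c(0.65, 0.11, 0.24), means = c(0, 0.50, 0.95),
                 conc = c(1, 10, 25)),
      CHH = list(weights = c(0.83, 0.16, 0.01), means = c(0, 0.25, 0.90),
                 conc = c(1, 14, 25))),
    te_methylation_boost = 0.30,
    depth_mean = 30,
    n_replicates = 3L,
    planted_dmrs = NULL,
    lambda_length = 48502L,
    non_conversion_rate = 0.0049,
    expression_copula_rho = 0.25,
    deg_fraction = 0.10,
    deg_log2fc_range = c(1, 3),
    condition_names = c("S1", "S2")) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_chromosomes = as.integer(n_chromosomes),
              gc_fraction = gc_fraction, n_genes = as.integer(n_genes),
              gene_structure = gene_structure, n_tes = as.integer(n_tes),
              te_class_weights = te_class_weights,
              context_methylation = context_methylation,
              te_methylation_boost = te_methylation_boost,
              depth_mean = depth_mean, n_replicates = as.integer(n_replicates),
              planted_dmrs = if (!is.null(planted_dmrs))
                as.data.table(planted_dmrs) else NULL,
              lambda_length = as.integer(lambda_length),
              non_conversion_rate = non_conversion_rate,
              expression_copula_rho = expression_copula_rho,
              deg_fraction = deg_fraction,
              deg_log2fc_range = deg_log2fc_range,
              condition_names = condition_names)
  class(cfg) <- "stemethyl_synth_config"
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  in01 <- function(x) all(x >= 0 & x <= 1)
  if (!in01(c(cfg$gc_fraction, cfg$non_conversion_rate, cfg$deg_fraction))) {
    stop("gc_fraction, non_conversion_rate and deg_fraction must lie in [0,1]")
  }
  if (abs(sum(cfg$te_class_weights) - 1) > 1e-9 || !in01(cfg$te_class_weights)) {
    stop("te_class_weights must be proportions summing to 1")
  }
  for (ctx in CONTEXTS) {
    mix <- cfg$context_methylation[[ctx]]
    if (is.null(mix)) stop(sprintf("context_methylation lacks %s", ctx))
    if (abs(sum(mix$weights) - 1) > 1e-9 || !in01(mix$weights) ||
        !in01(mix$means)) {
      stop(sprintf("%s mixture weights must sum to 1 and means lie in [0,1]",
                   ctx))
    }
  }
  if (abs(cfg$expression_copula_rho) > 1) {
    stop("expression_copula_rho must lie in [-1, 1]")
  }
  if (cfg$genome_length < cfg$n_chromosomes) {
    stop("genome shorter than the number of chromosomes")
  }
  if (!is.null(cfg$planted_dmrs) && nrow(cfg$planted_dmrs)) {
    pd <- cfg$planted_dmrs
    stopifnot(all(c("chrom", "start", "end", "context", "delta") %in% names(pd)))
    sl <- synthetic_seqlengths(cfg)
    if (any(!pd$chrom %in% names(sl)) || any(pd$start < 1) ||
        any(pd$end > sl[pd$chrom]) || any(pd$start > pd$end)) {
      stop("planted DMR intervals must lie within the genome")
    }
    gr <- GenomicRanges::GRanges(pd$chrom, IRanges::IRanges(pd$start, pd$end))
    if (length(GenomicRanges::reduce(gr)) != length(gr)) {
      stop("planted DMR intervals must not overlap each other")
    }
  }
  cfg
}

#' Chromosome lengths implied by a synthetic config
#'
#' The genome length is split as evenly as possible across chromosomes
#' `chr1..chrN` (the last chromosome absorbs the remainder).
#'
#' @param config A [synthetic_config()].
#' @return Named integer vector of chromosome lengths.
#' @export
synthetic_seqlengths <- function(config) {
  n <- config$n_chromosomes
  base <- config$genome_length %/% n
  lens <- rep(base, n)
  lens[n] <- lens[n] + config$genome_length - base * n
  stats::setNames(as.integer(lens), paste0("chr", seq_len(n)))
}
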