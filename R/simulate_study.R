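#' Simulate a complete two-condition WGBS study
#'
#' Runs every synthetic generator in sequence — genome and annotations,
#' per-condition methylomes (with shared base levels and any planted DMRs
#' applied to condition B), per-condition lambda spike-ins, and expression
#' tables — and optionally writes the whole study to disk in the standard
#' on-disk formats (FASTA, GFF3, call-table TSVs, expression TSV, and a
#' JSON ground-truth manifest). Fully deterministic given the config.
#'
#' @param config A [synthetic_config()].
#' @param outdir Optional output directory; created if missing.
#' @return A list: `config`, `genome`, `genes`, `tes`, `seqlengths`,
#'   `lambda` (per-condition list of `sequence` + `calls`), `methylomes`
#'   (per-condition list of `calls` + `truth`), `expression`,
#'   `condition_means`, `true_degs`, `gene_body_meth`, and `files` (named
#'   paths when `outdir` is given).
#' @export
simulate_study <- function(config, outdir = NULL) {
  config <- validate_synthetic_config(config)
  gen <- generate_genome(config)
  cond <- config$condition_names
  methylomes <- list(
    generate_methylome(config, gen$genome, gen$genes, gen$tes, 0L),
    generate_methylome(config, gen$genome, gen$genes, gen$tes, 1L))
  names(methylomes) <- cond
  lambda <- list(generate_lambda_calls(config, 0L),
                 generate_lambda_calls(config, 1L))
  names(lambda) <- cond
  if (length(gen$genes)) {
    gb <- gene_body_truth(methylomes[[1]]$truth, gen$genes, "CG")
    expr <- generate_expression(config, gb)
  } else {
    gb <- data.table::data.table(gene_id = character(), meth_level = numeric(),
                                 n_sites = integer())
    expr <- list(
      expression = data.table::data.table(gene_id = character(),
                                          condition = character(),
                                          replicate = integer(),
                                          fpkm = numeric()),
      condition_means = data.table::data.table(gene_id = character()),
      true_degs = data.table::data.table(gene_id = character(),
                                         log2fc = numeric(),
                                         direction = character()))
  }

  res <- list(config = config, genome = gen$genome, genes = gen$genes,
              tes = gen$tes, seqlengths = gen$seqlengths, lambda = lambda,
              methylomes = methylomes, expression = expr$expression,
              condition_means = expr$condition_means,
              true_degs = expr$true_degs, gene_body_meth = gb,
              files = NULL)
  if (is.null(outdir)) return(res)

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outdir, ...)
  files <- list(genome = fp("genome.fa"), genes = fp("genes.gff3"),
                tes = fp("tes.gff3"), lambda_fasta = fp("lambda.fa"),
                expression = fp("expression.tsv"), truth = fp("truth.json"))
  Biostrings::writeXStringSet(gen$genome, files$genome)
  Biostrings::writeXStringSet(lambda[[1]]$sequence, files$lambda_fasta)
  write_gff3(gen$genes, files$genes)
  write_gff3(gen$tes, files$tes)
  data.table::fwrite(res$expression, files$expression, sep = "\t")
  for (s in cond) {
    files[[paste0("lambda_", s)]] <- fp(sprintf("%s_lambda.tsv", s))
    write_calls(lambda[[s]]$calls, files[[paste0("lambda_", s)]])
    for (r in seq_len(config$n_replicates)) {
      key <- sprintf("calls_%s_rep%d", s, r)
      files[[key]] <- fp(sprintf("%s_rep%d.tsv", s, r))
      write_calls(methylomes[[s]]$calls[[r]], files[[key]])
    }
  }
  truth <- list(
    seed = config$seed,
    condition_names = cond,
    planted_dmrs = if (!is.null(config$planted_dmrs)) config$planted_dmrs,
    true_degs = res$true_degs,
    non_conversion_rate = config$non_conversion_rate,
    true_level_means = lapply(stats::setNames(CONTEXTS, CONTEXTS), function(cc) {
      tr <- methylomes[[1]]$truth
      mean(tr$true_level[tr$context == cc])
    }))
  jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  res$files <- files
  res
}
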