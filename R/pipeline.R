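PIPELINE_DEFAULTS <- list(
  window = 200L, step = 100L, min_coverage = 4L, q_threshold = 0.05,
  flank = 2000L, body_bins = 20L, flank_bin = 100L, density_bin = 100000L,
  contexts = c("CG", "CHG", "CHH"), deg_min_log2fc = 1, deg_min_fpkm = 1)

#' Validate and normalise a pipeline configuration
#'
#' Accepts a YAML file path or a list. Required fields: `outdir`, plus
#' either a `simulate` block (any [synthetic_config()] arguments; the study
#' is generated into `outdir/simulated`) or `genome`, `genes` and a
#' `samples` map (`sample id -> list(lambda = path, replicates = [paths])`).
#' Optional: `tes` (TE GFF3), `expression` (TSV with `gene_id`, `condition`,
#' `replicate`, `fpkm`), `degs` (TSV with `gene_id`, `direction`),
#' `comparisons` (list of two-sample pairs; direction is B relative to A),
#' and a `parameters` block overriding the stage defaults (window 200,
#' step 100, min_coverage 4, q_threshold 0.05, flank 2000, contexts
#' CG/CHG/CHH, ...). Every problem is reported in a single error. The
#' function is idempotent on its own output.
#'
#' @param config Path to a YAML file or a named list.
#' @return A normalized config of class `stemethyl_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (inherits(config, "stemethyl_config")) return(config)
  stopifnot(is.list(config))
  errors <- character()
  note <- function(msg) errors <<- c(errors, msg)

  if (is.null(config$outdir)) note("missing required field: outdir")
  config$seed <- as.integer(config$seed %||% 1L)

  params <- utils::modifyList(PIPELINE_DEFAULTS, config$parameters %||% list())
  bad_par <- setdiff(names(params), names(PIPELINE_DEFAULTS))
  if (length(bad_par)) {
    note(sprintf("unknown parameter(s): %s", paste(bad_par, collapse = ", ")))
  }
  config$parameters <- params

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (isTRUE(sim_args)) sim_args <- list()
    sim_args$seed <- sim_args$seed %||% config$seed
    config$simulate <- tryCatch(do.call(synthetic_config, sim_args),
                                error = function(e) {
                                  note(sprintf("simulate block: %s",
                                               conditionMessage(e)))
                                  NULL
                                })
  } else {
    for (f in c("genome", "genes")) {
      if (is.null(config[[f]])) {
        note(sprintf("missing required field: %s (or a simulate block)", f))
      } else if (!file.exists(config[[f]])) {
        note(sprintf("%s file does not exist: %s", f, config[[f]]))
      }
    }
    if (is.null(config$samples) || !length(config$samples)) {
      note("missing required field: samples")
    } else {
      for (s in names(config$samples)) {
        smp <- config$samples[[s]]
        for (p in c(smp$lambda, unlist(smp$replicates))) {
          if (!file.exists(p)) note(sprintf("sample %s: file does not exist: %s",
                                            s, p))
        }
        if (is.null(smp$replicates)) {
          note(sprintf("sample %s: no replicate call tables", s))
        }
      }
    }
    for (f in c("tes", "expression", "degs")) {
      if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
        note(sprintf("%s file does not exist: %s", f, config[[f]]))
      }
    }
  }

  sample_ids <- if (!is.null(config$simulate)) config$simulate$condition_names
                else names(config$samples)
  if (is.null(config$comparisons) || !length(config$comparisons)) {
    warning("no comparisons configured; only descriptive stages will run")
    config$comparisons <- list()
  } else {
    config$comparisons <- lapply(config$comparisons, unlist)
    for (cmp in config$comparisons) {
      if (length(cmp) != 2L || !all(cmp %in% sample_ids)) {
        note(sprintf("comparison (%s) must name two declared samples",
                     paste(cmp, collapse = " vs ")))
      }
    }
  }

  if (length(errors)) {
    stop(paste0("invalid pipeline config:\n", paste("-", errors, collapse = "\n")))
  }
  class(config) <- "stemethyl_config"
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full methylome pipeline
#'
#' Executes the stages in dependency order — simulate (optional), conversion
#' estimation + site calling per sample, genome summaries and histograms,
#' sliding windows + DMR + DMG calling per comparison and context, feature
#' and metaprofiles, and expression integration — writing tidy TSV/BED/JSON
#' outputs under `outdir` plus a `manifest.json` recording parameters, input
#' hashes and every artifact. A stage whose inputs, parameters and outputs
#' are unchanged since the last run is skipped, so re-running an unchanged
#' config is a no-op.
#'
#' @param config A [validate_config()] result, a YAML path, or a list.
#' @return Invisibly, a list of the in-memory stage results plus the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  par <- config$parameters
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(config$outdir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else list(stages = list())
  results <- list()

  stage_key <- function(inputs, params) {
    in_hash <- if (length(inputs)) as.list(tools::md5sum(unlist(inputs)))
               else list()
    list(inputs = in_hash, params = params)
  }
  run_stage <- function(name, inputs, params, outputs, fun) {
    key <- stage_key(inputs, params)
    prev <- manifest$stages[[name]]
    if (!is.null(prev) &&
        identical(jsonlite::toJSON(prev$key, auto_unbox = TRUE),
                  jsonlite::toJSON(key, auto_unbox = TRUE)) &&
        all(file.exists(unlist(outputs)))) {
      message(sprintf("[%s] up to date, skipped", name))
      return(invisible(NULL))
    }
    message(sprintf("[%s] running", name))
    fun()
    manifest$stages[[name]] <<- list(key = key, outputs = outputs,
                                     completed = TRUE)
    save_manifest()
  }
  save_manifest <- function() {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  out_path <- function(...) file.path(config$outdir, ...)

  # -- stage: simulate -------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_dir <- out_path("simulated")
    sim_params <- unclass(config$simulate)
    sim_params$planted_dmrs <- if (!is.null(sim_params$planted_dmrs))
      as.list(sim_params$planted_dmrs)
    run_stage("simulate", list(), sim_params,
              list(file.path(sim_dir, "genome.fa")), function() {
      simulate_study(config$simulate, sim_dir)
    })
    sim <- simulate_study(config$simulate)  # in-memory copy (deterministic)
    config$genome <- file.path(sim_dir, "genome.fa")
    config$genes <- file.path(sim_dir, "genes.gff3")
    config$tes <- file.path(sim_dir, "tes.gff3")
    config$expression <- file.path(sim_dir, "expression.tsv")
    config$samples <- lapply(
      stats::setNames(nm = config$simulate$condition_names), function(s) {
        list(lambda = file.path(sim_dir, sprintf("%s_lambda.tsv", s)),
             replicates = file.path(sim_dir, sprintf(
               "%s_rep%d.tsv", s, seq_len(config$simulate$n_replicates))))
      })
  }

  genome <- Biostrings::readDNAStringSet(config$genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  seqlengths <- stats::setNames(Biostrings::width(genome), names(genome))
  features <- derive_features(config$genes, config$tes,
                              seqlengths = seqlengths, flank = par$flank)
  gene_gr <- rtracklayer::import(config$genes, format = "gff3")
  gene_gr <- gene_gr[gene_gr$type == "gene"]

  # -- per-sample calling and summaries --------------------------------------
  samples <- names(config$samples)
  pooled <- list(); called <- list(); conv <- list()
  for (s in samples) {
    smp <- config$samples[[s]]
    reps <- lapply(smp$replicates, read_calls)
    pooled[[s]] <- pool_replicates(reps)
    conv[[s]] <- estimate_conversion(read_calls(smp$lambda), sample_id = s)
    called[[s]] <- call_sites(pooled[[s]], conv[[s]]$non_conversion_rate,
                              q_threshold = par$q_threshold,
                              min_coverage = par$min_coverage)
    run_stage(paste0("call_", s),
              c(smp$replicates, smp$lambda),
              par[c("q_threshold", "min_coverage")],
              list(out_path(sprintf("%s_calls.tsv", s))), function() {
      data.table::fwrite(called[[s]], out_path(sprintf("%s_calls.tsv", s)),
                         sep = "\t")
    })
    run_stage(paste0("summarise_", s),
              c(smp$replicates, smp$lambda),
              par[c("q_threshold", "min_coverage", "density_bin")],
              list(out_path(sprintf("%s_summary.tsv", s))), function() {
      data.table::fwrite(genome_summary(called[[s]], s),
                         out_path(sprintf("%s_summary.tsv", s)), sep = "\t")
      hist <- data.table::rbindlist(lapply(par$contexts, function(cc)
        level_histogram(pooled[[s]], cc, par$min_coverage)))
      data.table::fwrite(hist, out_path(sprintf("%s_level_histogram.tsv", s)),
                         sep = "\t")
      data.table::fwrite(context_proportions(called[[s]]),
                         out_path(sprintf("%s_context_proportions.tsv", s)),
                         sep = "\t")
      data.table::fwrite(
        chromosome_density(called[[s]], par$density_bin, seqlengths),
        out_path(sprintf("%s_density.tsv", s)), sep = "\t")
    })
  }
  results$conversion <- data.table::rbindlist(conv)
  data.table::fwrite(results$conversion, out_path("conversion_rates.tsv"),
                     sep = "\t")

  # -- profiles --------------------------------------------------------------
  for (s in samples) {
    smp <- config$samples[[s]]
    run_stage(paste0("profile_", s), smp$replicates,
              par[c("min_coverage", "body_bins", "flank", "flank_bin")],
              list(out_path(sprintf("%s_feature_levels.tsv", s))), function() {
      fl <- data.table::rbindlist(lapply(par$contexts, function(cc)
        feature_levels(pooled[[s]], features, cc, par$min_coverage)))
      data.table::fwrite(fl, out_path(sprintf("%s_feature_levels.tsv", s)),
                         sep = "\t")
      mp <- data.table::rbindlist(lapply(par$contexts, function(cc)
        metaprofile(pooled[[s]], gene_gr, cc, par$body_bins, par$flank,
                    par$flank_bin, par$min_coverage)))
      data.table::fwrite(mp, out_path(sprintf("%s_gene_metaprofile.tsv", s)),
                         sep = "\t")
    })
  }

  # -- DMRs / DMGs per comparison --------------------------------------------
  dmgs_by_cmp <- list()
  for (cmp in config$comparisons) {
    a <- cmp[1]; b <- cmp[2]
    tag <- sprintf("%s_vs_%s", a, b)
    reps_a <- lapply(config$samples[[a]]$replicates, read_calls)
    reps_b <- lapply(config$samples[[b]]$replicates, read_calls)
    all_dmrs <- list()
    for (cc in c(par$contexts, "ALL_C")) {
      wa <- build_windows(reps_a, seqlengths, cc, par$window, par$step,
                          par$min_coverage)
      wb <- build_windows(reps_b, seqlengths, cc, par$window, par$step,
                          par$min_coverage)
      all_dmrs[[cc]] <- call_dmrs(wa, wb, cc, q_threshold = par$q_threshold)
    }
    dmrs <- data.table::rbindlist(all_dmrs)
    dmgs <- annotate_dmgs(dmrs[context != "ALL_C"], gene_gr, flank = par$flank)
    dmgs_by_cmp[[tag]] <- dmgs
    run_stage(paste0("dmr_", tag),
              c(config$samples[[a]]$replicates, config$samples[[b]]$replicates),
              par[c("window", "step", "min_coverage", "q_threshold")],
              list(out_path(sprintf("%s_dmrs.bed", tag))), function() {
      if (nrow(dmrs)) {
        bed <- dmrs[, .(chrom, start = start + 1L, end,
                        name = sprintf("%s_%s_DMR", context, direction),
                        score = round(-log10(pmax(q_value, 1e-300)), 3),
                        strand = ".", delta = round(delta, 4), context)]
        write_bed(bed, out_path(sprintf("%s_dmrs.bed", tag)))
      } else {
        file.create(out_path(sprintf("%s_dmrs.bed", tag)))
      }
      data.table::fwrite(dmgs, out_path(sprintf("%s_dmgs.tsv", tag)), sep = "\t")
    })
    results$dmrs[[tag]] <- dmrs
    results$dmgs[[tag]] <- dmgs
  }

  # -- expression integration ------------------------------------------------
  if (!is.null(config$expression)) {
    expr <- data.table::fread(config$expression)
    mean_expr <- expr[, .(fpkm = mean(fpkm)), by = .(gene_id, condition)]
    for (s in intersect(samples, unique(mean_expr$condition))) {
      binned <- bin_expression(mean_expr[condition == s])
      gm <- gene_methylation(pooled[[s]], features, par$min_coverage)
      run_stage(paste0("integrate_", s),
                c(config$samples[[s]]$replicates, config$expression),
                par["min_coverage"],
                list(out_path(sprintf("%s_stratified_levels.tsv", s))),
                function() {
        data.table::fwrite(stratified_levels(gm, binned),
                           out_path(sprintf("%s_stratified_levels.tsv", s)),
                           sep = "\t")
        cors <- data.table::rbindlist(lapply(GENE_REGIONS, function(rg)
          data.table::rbindlist(lapply(par$contexts, function(cc)
            tryCatch(methylation_expression_correlation(gm, binned, rg, cc),
                     error = function(e) NULL)))))
        data.table::fwrite(cors, out_path(sprintf("%s_meth_expr_cor.tsv", s)),
                           sep = "\t")
      })
    }
    degs <- if (!is.null(config$degs)) {
      data.table::fread(config$degs)
    } else {
      tryCatch(call_degs(expr, min_log2fc = par$deg_min_log2fc,
                         min_fpkm = par$deg_min_fpkm),
               error = function(e) NULL)
    }
    if (!is.null(degs) && length(dmgs_by_cmp)) {
      for (tag in names(dmgs_by_cmp)) {
        venn <- intersect_dmg_deg(dmgs_by_cmp[[tag]], degs)
        data.table::fwrite(venn$common,
                           out_path(sprintf("%s_dmg_deg_common.tsv", tag)),
                           sep = "\t")
        jsonlite::write_json(venn$counts,
                             out_path(sprintf("%s_dmg_deg_venn.json", tag)),
                             auto_unbox = TRUE, digits = NA)
        results$venn[[tag]] <- venn
      }
    }
    results$degs <- degs
  }

  save_manifest()
  results$manifest <- manifest
  invisible(results)
}
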