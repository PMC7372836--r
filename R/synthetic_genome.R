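# RNG seed offsets per generator stage; keeping them fixed makes every stage
# individually reproducible and the base methylome shared across conditions
SEED_GENOME <- 1L
SEED_LAMBDA <- 7L
SEED_LEVELS <- 11L
SEED_COUNTS <- 100L
SEED_EXPR <- 900L

#' Generate a synthetic genome with gene and TE annotations
#'
#' Draws random chromosome sequences at the configured GC fraction and
#' places non-overlapping genes and transposable elements. Genes are placed
#' preferentially in the first ~55% of each chromosome and TEs in the last
#' ~55%, producing the gene-rich versus TE-dense regional contrast plant
#' methylomes show once TE spans receive their methylation boost. Each gene
#' gets a strand, exons separated by introns, and 5'/3' UTRs at the
#' transcript ends; each TE gets a class (`LTR`, `LINE`, `SINE`, `DNA`) and
#' a superfamily label.
#'
#' @param config A [synthetic_config()].
#' @return A list: `genome` (`DNAStringSet`), `genes` (`GRanges` with
#'   gene/mRNA/exon/five_prime_UTR/CDS/three_prime_UTR records and
#'   `ID`/`Parent` attributes), `tes` (`GRanges` of `repeat_region` records
#'   with `te_class`/`te_superfamily`), `seqlengths`.
#' @export
generate_genome <- function(config) {
  config <- validate_synthetic_config(config)
  set.seed(config$seed + SEED_GENOME)
  sl <- synthetic_seqlengths(config)
  gc <- config$gc_fraction
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  genome <- Biostrings::DNAStringSet(vapply(sl, function(len) {
    paste(sample(names(probs), len, replace = TRUE, prob = probs),
          collapse = "")
  }, ""))
  names(genome) <- names(sl)

  occupied <- lapply(names(sl), function(ch) IRanges::IRanges())
  names(occupied) <- names(sl)
  place <- function(len, lo_frac, hi_frac, min_gap = 1L) {
    # random placement with rejection against already-placed intervals
    for (try in seq_len(500L)) {
      ch <- sample(names(sl), 1L)
      lo <- max(1L, as.integer(sl[[ch]] * lo_frac))
      hi <- as.integer(sl[[ch]] * hi_frac) - len
      if (hi <= lo) next
      s <- sample(lo:hi, 1L)
      cand <- IRanges::IRanges(s - min_gap, s + len - 1L + min_gap)
      if (!any(IRanges::overlapsAny(cand, occupied[[ch]]))) {
        occupied[[ch]] <<- c(occupied[[ch]], IRanges::IRanges(s, s + len - 1L))
        return(list(chrom = ch, start = s))
      }
    }
    stop(sprintf(
      "placement failure: could not place a %d bp feature; genome too short for the requested genes/TEs",
      len))
  }

  gs <- config$gene_structure
  rows <- list()
  emit <- function(chrom, start, end, strand, type, id, parent = NA_character_,
                   te_class = NA_character_, te_superfamily = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.table::data.table(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      strand = strand, type = type, id = id, parent = parent,
      te_class = te_class, te_superfamily = te_superfamily)
  }

  if (config$n_genes > 0L) {
    for (i in seq_len(config$n_genes)) {
      gid <- sprintf("gene%04d", i)
      n_ex <- sample(gs$n_exons[1]:gs$n_exons[2], 1L)
      min_terminal <- gs$utr5_length + gs$utr3_length + 30L
      ex_len <- sample(gs$exon_length[1]:gs$exon_length[2], n_ex, replace = TRUE)
      # terminal exons must hold their UTR plus some CDS
      if (n_ex == 1L) {
        ex_len[1] <- max(ex_len[1], min_terminal)
      } else {
        ex_len[1] <- max(ex_len[1], gs$utr5_length + 30L)
        ex_len[n_ex] <- max(ex_len[n_ex], gs$utr3_length + 30L)
      }
      in_len <- if (n_ex > 1L) {
        sample(gs$intron_length[1]:gs$intron_length[2], n_ex - 1L,
               replace = TRUE)
      } else integer()
      glen <- sum(ex_len) + sum(in_len)
      strand <- sample(c("+", "-"), 1L)
      at <- place(glen, 0, 0.55)
      gstart <- at$start; ch <- at$chrom
      emit(ch, gstart, gstart + glen - 1L, strand, "gene", gid)
      mid <- paste0(gid, ".1")
      emit(ch, gstart, gstart + glen - 1L, strand, "mRNA", mid, gid)
      ex_start <- gstart + cumsum(c(0L, utils::head(ex_len, -1L) + in_len))
      ex_end <- ex_start + ex_len - 1L
      for (j in seq_len(n_ex)) {
        emit(ch, ex_start[j], ex_end[j], strand, "exon",
             sprintf("%s.exon%d", mid, j), mid)
      }
      # UTRs sit at the transcript's 5'/3' ends in gene orientation
      if (strand == "+") {
        u5 <- c(ex_start[1], ex_start[1] + gs$utr5_length - 1L)
        u3 <- c(ex_end[n_ex] - gs$utr3_length + 1L, ex_end[n_ex])
      } else {
        u5 <- c(ex_end[n_ex] - gs$utr5_length + 1L, ex_end[n_ex])
        u3 <- c(ex_start[1], ex_start[1] + gs$utr3_length - 1L)
      }
      emit(ch, u5[1], u5[2], strand, "five_prime_UTR", paste0(mid, ".utr5"), mid)
      emit(ch, u3[1], u3[2], strand, "three_prime_UTR", paste0(mid, ".utr3"), mid)
      utr <- IRanges::IRanges(c(u5[1], u3[1]), c(u5[2], u3[2]))
      cds <- IRanges::setdiff(IRanges::IRanges(ex_start, ex_end), utr)
      for (j in seq_along(cds)) {
        emit(ch, IRanges::start(cds)[j], IRanges::end(cds)[j], strand, "CDS",
             sprintf("%s.cds%d", mid, j), mid)
      }
    }
  }

  te_sf <- list(LTR = c("Gypsy", "Copia", "Caulimovirus"), LINE = "L1",
                SINE = "unknown", DNA = c("CMC-EnSpm", "hAT-Tag1", "hAT-Tip100"))
  te_len <- list(LTR = c(800L, 3000L), LINE = c(500L, 2000L),
                 SINE = c(150L, 400L), DNA = c(300L, 1500L))
  if (config$n_tes > 0L) {
    classes <- sample(names(config$te_class_weights), config$n_tes,
                      replace = TRUE, prob = config$te_class_weights)
    for (i in seq_len(config$n_tes)) {
      cl <- classes[i]
      len <- sample(te_len[[cl]][1]:te_len[[cl]][2], 1L)
      at <- place(len, 0.45, 1.0)
      emit(at$chrom, at$start, at$start + len - 1L,
           sample(c("+", "-"), 1L), "repeat_region", sprintf("TE%04d", i),
           te_class = cl, te_superfamily = sample(te_sf[[cl]], 1L))
    }
  }

  dt <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(chrom = character(), start = integer(),
                           end = integer(), strand = character(),
                           type = character(), id = character(),
                           parent = character(), te_class = character(),
                           te_superfamily = character())
  to_gr <- function(d) {
    gr <- GenomicRanges::GRanges(
      factor(d$chrom, levels = names(sl)),
      IRanges::IRanges(d$start, d$end), strand = d$strand,
      seqlengths = sl)
    mcols(gr) <- S4Vectors::DataFrame(
      type = d$type, ID = d$id,
      Parent = ifelse(is.na(d$parent), NA_character_, d$parent),
      te_class = d$te_class, te_superfamily = d$te_superfamily)
    gr  # definition order: gene, mRNA, exons, UTRs, CDS per gene
  }
  gene_types <- c("gene", "mRNA", "exon", "five_prime_UTR", "CDS",
                  "three_prime_UTR")
  list(genome = genome,
       genes = to_gr(dt[type %in% gene_types]),
       tes = to_gr(dt[type == "repeat_region"]),
       seqlengths = sl)
}

#' Write a synthetic annotation GRanges as GFF3
#'
#' @param gr A `GRanges` from [generate_genome()] (`type`, `ID`, `Parent`
#'   metadata columns).
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(gr, path) {
  out <- gr
  if ("type" %in% names(mcols(out)) && !"phase" %in% names(mcols(out))) {
    out$phase <- ifelse(as.character(out$type) == "CDS", 0L, NA_integer_)
  }
  # rtracklayer writes Parent as a proper multi-valued GFF3 attribute list
  if ("Parent" %in% names(mcols(out))) {
    p <- out$Parent
    out$Parent <- IRanges::CharacterList(ifelse(is.na(p), list(character()),
                                                as.list(p)))
  }
  keep <- vapply(seq_along(mcols(out)), function(i) {
    col <- mcols(out)[[i]]
    if (methods::is(col, "List")) any(lengths(col) > 0) else !all(is.na(col))
  }, TRUE)
  mcols(out) <- mcols(out)[, keep, drop = FALSE]
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}
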