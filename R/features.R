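#' Derive analysis features from gene and TE annotations
#'
#' Expands a gene GFF3 (gene/mRNA/exon/UTR records) and a TE GFF3
#' (repeat_region records) into the flat feature set the methylation
#' profiling operations consume: per gene a `gene_body`, a strand-aware
#' 2 kb `promoter` upstream of the TSS and a `downstream_2kb` region past
#' the TES; `exon`, `intron` (gaps between consecutive exons of the same
#' transcript), `five_prime_UTR` and `three_prime_UTR`; each TE as `TE`
#' plus its `TE_flank_upstream` / `TE_flank_downstream` 2 kb flanks.
#' Promoters, downstream regions and TE flanks are clipped to chromosome
#' bounds.
#'
#' @param genes Path to a gene GFF3 file or a [GenomicRanges::GRanges]
#'   imported from one (metadata columns `type`, `ID`, `Parent`).
#' @param tes Optional TE GFF3 path or `GRanges` (`repeat_region` records
#'   with `te_class` / `te_superfamily` attributes).
#' @param seqlengths Named integer vector of chromosome lengths used for
#'   clipping; taken from the annotation's seqinfo when omitted.
#' @param flank Flank width in bp (default 2000).
#' @return A `GRanges` with metadata columns `feature_id`, `kind`,
#'   `gene_id`, `te_class`, `te_superfamily`.
#' @export
derive_features <- function(genes, tes = NULL, seqlengths = NULL, flank = 2000L) {
  gr <- if (is.character(genes)) rtracklayer::import(genes, format = "gff3") else genes
  if (is.null(seqlengths)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    if (!all(is.na(sl))) seqlengths <- sl
  }
  clip <- function(chrom, s, e) {
    s <- pmax(s, 1L)
    if (!is.null(seqlengths)) e <- pmin(e, unname(seqlengths[as.character(chrom)]))
    list(s, e)
  }
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if ("ID" %in% names(mcols(gr))) as.character(gr$ID) else NA_character_,
    parent = if ("Parent" %in% names(mcols(gr)))
      vapply(gr$Parent, function(p) if (length(p)) p[1] else NA_character_, "")
    else NA_character_)

  g <- dt[type == "gene"]
  if (anyNA(g$id)) stop("gene records must carry an ID attribute")
  tx <- dt[type == "mRNA"]
  tx_gene <- stats::setNames(tx$parent, tx$id)

  rows <- list()
  add <- function(chrom, start, end, strand, kind, gene_id = NA_character_,
                  feature_id = NULL, te_class = NA_character_,
                  te_superfamily = NA_character_) {
    if (is.null(feature_id)) feature_id <- paste(kind, gene_id, sep = ":")
    keep <- !is.na(start) & !is.na(end) & start <= end
    rows[[length(rows) + 1L]] <<- data.table::data.table(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      strand = strand, kind = kind, gene_id = gene_id,
      feature_id = feature_id, te_class = te_class,
      te_superfamily = te_superfamily)[keep]
  }

  if (nrow(g)) {
    add(g$chrom, g$start, g$end, g$strand, "gene_body", g$id)
    plus <- g$strand != "-"
    prom_s <- ifelse(plus, g$start - flank, g$end + 1L)
    prom_e <- ifelse(plus, g$start - 1L, g$end + flank)
    ce <- clip(g$chrom, prom_s, prom_e)
    add(g$chrom, ce[[1]], ce[[2]], g$strand, "promoter", g$id)
    down_s <- ifelse(plus, g$end + 1L, g$start - flank)
    down_e <- ifelse(plus, g$end + flank, g$start - 1L)
    ce <- clip(g$chrom, down_s, down_e)
    add(g$chrom, ce[[1]], ce[[2]], g$strand, "downstream_2kb", g$id)

    ex <- dt[type == "exon"]
    if (nrow(ex)) {
      ex[, gene_id := tx_gene[parent]]
      ex[is.na(gene_id), gene_id := parent]  # exons parented directly on genes
      span <- merge(ex, g[, .(gene_id = id, gs = start, ge = end)], by = "gene_id")
      if (any(span$start < span$gs | span$end > span$ge)) {
        bad <- span[start < gs | end > ge][1]
        stop(sprintf("exon [%d,%d] outside the span of gene %s",
                     bad$start, bad$end, bad$gene_id))
      }
      add(ex$chrom, ex$start, ex$end, ex$strand, "exon", ex$gene_id)
      data.table::setorder(ex, parent, start)
      intr <- ex[, {
        if (.N > 1L) list(chrom = chrom[-.N], start = end[-.N] + 1L,
                          end = start[-1L] - 1L, strand = strand[-.N],
                          gene_id = gene_id[-.N])
      }, by = parent]
      if (nrow(intr)) {
        intr <- intr[start <= end]
        add(intr$chrom, intr$start, intr$end, intr$strand, "intron", intr$gene_id)
      }
    }
    for (k in c("five_prime_UTR", "three_prime_UTR")) {
      u <- dt[type == k]
      if (nrow(u)) {
        u[, gene_id := tx_gene[parent]]
        add(u$chrom, u$start, u$end, u$strand, k, u$gene_id)
      }
    }
  }

  if (!is.null(tes)) {
    tgr <- if (is.character(tes)) rtracklayer::import(tes, format = "gff3") else tes
    if (length(tgr)) {
      tdt <- data.table::data.table(
        chrom = as.character(GenomicRanges::seqnames(tgr)),
        start = GenomicRanges::start(tgr), end = GenomicRanges::end(tgr),
        strand = as.character(GenomicRanges::strand(tgr)),
        id = if ("ID" %in% names(mcols(tgr))) as.character(tgr$ID)
             else sprintf("TE%06d", seq_along(tgr)),
        te_class = if ("te_class" %in% names(mcols(tgr)))
          as.character(tgr$te_class) else NA_character_,
        te_superfamily = if ("te_superfamily" %in% names(mcols(tgr)))
          as.character(tgr$te_superfamily) else NA_character_)
      add(tdt$chrom, tdt$start, tdt$end, tdt$strand, "TE",
          feature_id = tdt$id, te_class = tdt$te_class,
          te_superfamily = tdt$te_superfamily)
      ce <- clip(tdt$chrom, tdt$start - flank, tdt$start - 1L)
      add(tdt$chrom, ce[[1]], ce[[2]], tdt$strand, "TE_flank_upstream",
          feature_id = paste0(tdt$id, ":up"), te_class = tdt$te_class,
          te_superfamily = tdt$te_superfamily)
      ce <- clip(tdt$chrom, tdt$end + 1L, tdt$end + flank)
      add(tdt$chrom, ce[[1]], ce[[2]], tdt$strand, "TE_flank_downstream",
          feature_id = paste0(tdt$id, ":down"), te_class = tdt$te_class,
          te_superfamily = tdt$te_superfamily)
    }
  }

  all <- data.table::rbindlist(rows)
  if (!nrow(all)) {
    return(GenomicRanges::GRanges())
  }
  res <- GenomicRanges::GRanges(
    seqnames = all$chrom,
    ranges = IRanges::IRanges(all$start, all$end),
    strand = ifelse(all$strand %in% c("+", "-"), all$strand, "*"))
  mcols(res) <- S4Vectors::DataFrame(
    feature_id = all$feature_id, kind = all$kind, gene_id = all$gene_id,
    te_class = all$te_class, te_superfamily = all$te_superfamily)
  res
}
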