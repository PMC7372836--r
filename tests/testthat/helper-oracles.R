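# Independent brute-force oracles, deliberately implemented with different
# primitives (substring scans, quadratic loops) than the package code paths
# they check.

# context of every cytosine by substring/regex matching on the sequence and
# its literal reverse complement (a different route than the package's
# per-base vector scan)
brute_contexts <- function(seq_chr) {
  s <- toupper(seq_chr)
  n <- nchar(s)
  contexts_on <- function(str) {
    # per-position context of the C's of one strand, read 5'->3'
    pos <- seq_len(nchar(str))
    tri <- substring(str, pos, pmin(pos + 2L, nchar(str)))
    ctx <- rep(NA_character_, length(pos))
    ctx[grepl("^CG", tri)] <- "CG"
    ctx[grepl("^C[ATC]G", tri)] <- "CHG"
    ctx[grepl("^C[ATC][ATC]$", tri) & nchar(tri) == 3L] <- "CHH"
    ctx
  }
  revcomp <- function(x) chartr("ACGTN", "TGCAN",
                                paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  fwd <- contexts_on(s)
  rev_ctx <- contexts_on(revcomp(s))
  plus <- which(substring(s, seq_len(n), seq_len(n)) == "C")
  minus <- which(substring(s, seq_len(n), seq_len(n)) == "G")
  rbind(
    data.frame(pos = plus, strand = "+", context = fwd[plus]),
    data.frame(pos = minus, strand = "-", context = rev_ctx[n - minus + 1L]))
}

# sliding-window list by explicit enumeration with coverage bookkeeping
brute_windows <- function(len, window = 200L, step = 100L) {
  out <- NULL
  covered_to <- 0L
  s <- 0L
  while (s < len) {
    e <- min(s + window, len)
    if (e > covered_to) {
      out <- rbind(out, data.frame(start = s, end = e))
      covered_to <- e
    }
    s <- s + step
  }
  out
}

# quadratic all-pairs DMR-gene intersection with the > 1 nt rule
brute_dmg <- function(dmrs, genes, flank = 2000L) {
  hits <- list()
  for (i in seq_len(nrow(dmrs))) {
    for (j in seq_len(nrow(genes))) {
      if (dmrs$chrom[i] != genes$chrom[j]) next
      lo <- max(dmrs$start[i] + 1L, max(genes$start[j] - flank, 1L))
      hi <- min(dmrs$end[i], genes$end[j] + flank)
      if (hi - lo + 1L > 1L) {
        hits[[length(hits) + 1L]] <- data.frame(
          gene_id = genes$gene_id[j], direction = dmrs$direction[i])
      }
    }
  }
  if (!length(hits)) return(data.frame(gene_id = character(),
                                       direction = character()))
  do.call(rbind, hits)
}

# random valid call table
random_calls <- function(n, seed = 1, chroms = c("chr1", "chr2"),
                         max_pos = 100000L) {
  set.seed(seed)
  total <- sample(0:60, n, replace = TRUE)
  data.table::data.table(
    chrom = sample(chroms, n, replace = TRUE),
    pos = sample.int(max_pos, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    context = sample(c("CG", "CHG", "CHH"), n, replace = TRUE),
    mc_count = vapply(total, function(t) if (t) sample(0:t, 1L) else 0L,
                      integer(1)),
    total_count = total)
}
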