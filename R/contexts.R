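#' Classify cytosine sequence contexts from a reference genome
#'
#' Scans every cytosine on both strands of a genome and assigns the plant
#' methylation sequence context: `CG`, `CHG` or `CHH`, where H is A, T or C.
#' The context is read 5'->3' on the cytosine's own strand, so a `G` on the
#' plus strand is a cytosine on the minus strand whose context is taken from
#' the reverse complement. Cytosines whose two downstream bases run off the
#' chromosome end, or whose context window touches an `N`, get an `NA`
#' context; they are kept in the table (so site counts are auditable) but are
#' excluded by every downstream analysis.
#'
#' @param genome A [Biostrings::DNAStringSet] (or named character vector) of
#'   chromosome sequences over the alphabet A, C, G, T, N.
#' @param drop_undefined Drop rows with `NA` context (default `FALSE`).
#' @return A [data.table::data.table] with columns `chrom`, `pos` (1-based),
#'   `strand` (`+`/`-`) and `context` (`CG`, `CHG`, `CHH` or `NA`).
#' @examples
#' ctx <- classify_contexts(c(chr1 = "ACGTTACAGT"))
#' ctx[context == "CG"]
#' @export
classify_contexts <- function(genome, drop_undefined = FALSE) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (is.null(names(genome)) || anyNA(names(genome))) {
    stop("genome sequences must be named (chromosome ids)")
  }
  out <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    out[[i]] <- classify_contexts_one(names(genome)[i],
                                      as.character(genome[[i]]))
  }
  res <- data.table::rbindlist(out)
  if (drop_undefined) res <- res[!is.na(context)]
  res[]
}

# context of one chromosome; vectorised over a character vector of bases
classify_contexts_one <- function(chrom_name, seq_chr) {
  s <- strsplit(toupper(seq_chr), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(s), c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop(sprintf("non-IUPAC character '%s' in %s at position %d",
                 bad[1], chrom_name, which(s == bad[1])[1]))
  }
  n <- length(s)
  h <- c("A", "T", "C")

  ctx_from <- function(b1, b2) {
    # b1, b2: the two bases downstream of the cytosine on its own strand
    ctx <- rep(NA_character_, length(b1))
    ok1 <- !is.na(b1) & b1 != "N"
    ctx[ok1 & b1 == "G"] <- "CG"
    ok2 <- ok1 & b1 %in% h & !is.na(b2) & b2 != "N"
    ctx[ok2 & b2 == "G"] <- "CHG"
    ctx[ok2 & b2 %in% h] <- "CHH"
    ctx
  }

  idx_p <- which(s == "C")
  b1p <- s[idx_p + 1L]; b1p[idx_p + 1L > n] <- NA
  b2p <- s[idx_p + 2L]; b2p[idx_p + 2L > n] <- NA
  plus <- data.table::data.table(
    chrom = chrom_name, pos = idx_p, strand = "+",
    context = ctx_from(b1p, b2p))

  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  idx_m <- which(s == "G")
  # downstream on the minus strand = upstream on the plus strand, complemented
  u1 <- ifelse(idx_m - 1L >= 1L, s[pmax(idx_m - 1L, 1L)], NA)
  u2 <- ifelse(idx_m - 2L >= 1L, s[pmax(idx_m - 2L, 1L)], NA)
  minus <- data.table::data.table(
    chrom = chrom_name, pos = idx_m, strand = "-",
    context = ctx_from(unname(comp[u1]), unname(comp[u2])))

  res <- rbind(plus, minus)
  data.table::setorder(res, pos, strand)
  res
}

#' Audit stored contexts against the reference
#'
#' Re-derives the context of every call-table row from the genome and reports
#' mismatches. Intended as a full-file sanity audit before analysis.
#'
#' @param calls A call table (see [read_calls()]).
#' @param genome A `DNAStringSet` / named character vector of chromosomes.
#' @return Invisibly, the rows of `calls` whose stored context disagrees with
#'   the reference (zero rows when the table is clean); a warning is raised
#'   when mismatches exist.
#' @export
audit_contexts <- function(calls, genome) {
  calls <- as.data.table(calls)
  ref <- classify_contexts(genome)
  merged <- merge(calls, ref, by = c("chrom", "pos", "strand"),
                  suffixes = c("", ".ref"), all.x = TRUE)
  bad <- merged[is.na(get("context.ref")) | get("context.ref") != context]
  if (nrow(bad)) {
    warning(sprintf("%d call rows have a context inconsistent with the reference",
                    nrow(bad)))
  }
  invisible(bad)
}
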