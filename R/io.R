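CALL_COLUMNS <- c("chrom", "pos", "strand", "context", "mc_count", "total_count")
CONTEXTS <- c("CG", "CHG", "CHH")

#' Read a per-cytosine methylation call table
#'
#' The call-table dialect is a 6-column TSV with header:
#' `chrom`, `pos` (1-based), `strand` (`+`/`-`), `context` (`CG`/`CHG`/`CHH`),
#' `mc_count` (methylated reads), `total_count` (total reads). This is the
#' post-alignment product of a bisulfite mapper; see
#' [read_methratio()] for an adapter from BSMAP/methratio output.
#'
#' Every row is validated: counts must be non-negative integers with
#' `mc_count <= total_count`, strand and context must be legal labels.
#' Malformed rows are reported with their line number.
#'
#' @param path Path to a TSV file.
#' @return A `data.table` with the six call columns.
#' @export
read_calls <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c(1, 3, 4)))
  if (!nrow(dt)) {
    dt <- data.table::data.table(chrom = character(), pos = integer(),
                                 strand = character(), context = character(),
                                 mc_count = integer(), total_count = integer())
  }
  if (!identical(names(dt), CALL_COLUMNS)) {
    stop(sprintf("call table %s: expected columns %s, found %s", path,
                 paste(CALL_COLUMNS, collapse = ","),
                 paste(names(dt), collapse = ",")))
  }
  validate_calls(dt, path)
  dt[]
}

# shared row validation; `where` names the source in error messages.
# line numbers are 1-based data rows + 1 for the header.
validate_calls <- function(dt, where = "calls") {
  bad_line <- function(mask) which(mask)[1] + 1L
  if (anyNA(dt$pos) || any(dt$pos < 1)) {
    stop(sprintf("%s line %d: position must be a positive integer",
                 where, bad_line(is.na(dt$pos) | dt$pos < 1)))
  }
  if (any(!dt$strand %in% c("+", "-"))) {
    stop(sprintf("%s line %d: strand must be '+' or '-'",
                 where, bad_line(!dt$strand %in% c("+", "-"))))
  }
  if (any(!dt$context %in% CONTEXTS)) {
    stop(sprintf("%s line %d: context must be one of CG, CHG, CHH",
                 where, bad_line(!dt$context %in% CONTEXTS)))
  }
  if (anyNA(dt$mc_count) || anyNA(dt$total_count) ||
      any(dt$mc_count < 0) || any(dt$total_count < 0)) {
    stop(sprintf("%s line %d: counts must be non-negative integers", where,
                 bad_line(is.na(dt$mc_count) | is.na(dt$total_count) |
                            dt$mc_count < 0 | dt$total_count < 0)))
  }
  if (any(dt$mc_count > dt$total_count)) {
    stop(sprintf("%s line %d: mc_count exceeds total_count",
                 where, bad_line(dt$mc_count > dt$total_count)))
  }
  invisible(dt)
}

#' Write a per-cytosine methylation call table
#'
#' @param calls A data.frame/data.table with the six call columns.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  calls <- as.data.table(calls)[, CALL_COLUMNS, with = FALSE]
  validate_calls(calls)
  data.table::fwrite(calls, path, sep = "\t")
  invisible(path)
}

#' Adapt BSMAP methratio output to the call-table dialect
#'
#' methratio.py emits (among others) columns `chr`, `pos`, `strand`,
#' `context`, `C_count` and `CT_count`, with the context given as the
#' surrounding 5-mer or as CG/CHG/CHH depending on version. This adapter
#' keeps only the six analysis columns and normalises 5-mer contexts.
#'
#' @param path Path to a methratio TSV file.
#' @return A call `data.table` (see [read_calls()]).
#' @export
read_methratio <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("chr", "pos", "strand", "context", "C_count", "CT_count")
  if (!all(need %in% names(dt))) {
    stop(sprintf("methratio file %s lacks columns: %s", path,
                 paste(setdiff(need, names(dt)), collapse = ",")))
  }
  ctx <- dt$context
  five_mer <- !ctx %in% CONTEXTS & nchar(ctx) == 5L
  if (any(five_mer)) {
    core <- substr(ctx[five_mer], 3L, 5L)  # cytosine + 2 downstream bases
    ctx[five_mer] <- data.table::fifelse(
      substr(core, 2, 2) == "G", "CG",
      data.table::fifelse(substr(core, 3, 3) == "G", "CHG", "CHH"))
  }
  out <- data.table::data.table(
    chrom = as.character(dt$chr), pos = as.integer(dt$pos),
    strand = as.character(dt$strand), context = ctx,
    mc_count = as.integer(dt$C_count), total_count = as.integer(dt$CT_count))
  validate_calls(out, path)
  out[]
}

#' Export genomic intervals as BED6(+)
#'
#' Converts 1-based inclusive coordinates to BED's 0-based half-open
#' convention. Extra columns beyond the BED6 set are appended in order.
#'
#' @param dt A data.table with `chrom`, `start`, `end` (1-based inclusive)
#'   plus optional `name`, `score`, `strand` and extra columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(dt, path) {
  dt <- as.data.table(dt)
  bed <- data.table::data.table(
    chrom = dt$chrom,
    start = dt$start - 1L,
    end = dt$end,
    name = if ("name" %in% names(dt)) dt$name else ".",
    score = if ("score" %in% names(dt)) dt$score else 0,
    strand = if ("strand" %in% names(dt)) dt$strand else ".")
  extra <- setdiff(names(dt), c("chrom", "start", "end", "name", "score", "strand"))
  if (length(extra)) bed <- cbind(bed, dt[, extra, with = FALSE])
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
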