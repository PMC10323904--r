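# Internal coordinate contract: all interval sets carried around by this
# package are 0-based half-open [start, end). GTF input (1-based closed) is
# converted on read; BED input is taken as-is. GRanges used for the actual
# interval algebra are 1-based closed, so conversion happens at this boundary
# only.

#' Convert a 0-based half-open interval table to GRanges
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `strand`.
#' @return a `GRanges` (1-based closed).
#' @keywords internal
bed0_to_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

#' Convert GRanges back to a 0-based half-open interval table
#' @keywords internal
granges_to_bed0 <- function(gr, keep_strand = FALSE) {
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (keep_strand) out$strand <- as.character(GenomicRanges::strand(gr))
  out
}

#' Read a BED3(+1) file of genomic intervals
#'
#' Reads plain BED with three columns (chrom, start, end; 0-based half-open)
#' and, when present, a numeric fourth column interpreted as a dataset-support
#' count.
#'
#' @param path path to a tab-separated BED file without header.
#' @param chrom_style one of `"none"` (leave names as-is), `"chr"` (ensure a
#'   "chr" prefix) or `"plain"` (strip a "chr" prefix). Mixed-source BED/GTF
#'   inputs often disagree on the dialect.
#' @return data.frame with columns `chrom`, `start`, `end` and optionally
#'   `support`.
#' @export
read_bed <- function(path, chrom_style = c("none", "chr", "plain")) {
  chrom_style <- match.arg(chrom_style)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (ncol(df) >= 4 && is.numeric(df[[4]])) names(df)[4] <- "support"
  df$chrom <- normalize_chrom(df$chrom, chrom_style)
  df[, names(df) %in% c("chrom", "start", "end", "support"), drop = FALSE]
}

#' Write an interval table as BED
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally `support`.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end")
  if ("support" %in% names(df)) cols <- c(cols, "support")
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Normalize chromosome-name dialects
#'
#' @param x character vector of sequence names.
#' @param style `"none"`, `"chr"` or `"plain"`.
#' @return character vector.
#' @export
normalize_chrom <- function(x, style = c("none", "chr", "plain")) {
  style <- match.arg(style)
  switch(style,
    none = x,
    chr = ifelse(grepl("^chr", x), x, paste0("chr", x)),
    plain = sub("^chr", "", x)
  )
}

# validate an interval table; `what` names the offending dataset in errors
validate_intervals <- function(df, what = "interval set") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: missing columns %s", what,
                 paste(setdiff(need, names(df)), collapse = ", ")))
  }
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    stop(sprintf("%s: interval with start >= end at row %d (%s:%d-%d)",
                 what, bad[1], df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  }
  invisible(df)
}
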