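# Multi-dataset ChIP-seq recurrence. Recurrence is defined per base: the
# union of all peak sets is partitioned into maximal segments with a constant
# set of supporting datasets, segments supported by >= k datasets are kept,
# and kept segments closer than a small gap (default: book-ended only) are
# merged. DREAM sites are the interval intersection of the recurrent E2F4 and
# p130/p107 site sets.

#' Partition the union of peak sets into constant-support segments
#'
#' Computes the multi-way intersection of per-dataset peak sets: the output
#' segments exactly partition the union of all inputs, within a segment the
#' set of covering datasets is constant, and adjacent (book-ended) segments
#' differ in their dataset set. Peaks overlapping within one dataset are
#' collapsed first so support counts datasets, not peaks.
#'
#' @param peak_sets named list of interval tables (\code{chrom}, \code{start},
#'   \code{end}; 0-based half-open).
#' @return a \code{support_partition}: data.frame with \code{chrom},
#'   \code{start}, \code{end}, \code{support} and a comma-joined
#'   \code{dataset_ids} column, plus attribute \code{n_datasets}.
#' @export
multi_intersect <- function(peak_sets) {
  if (is.null(names(peak_sets)) || any(names(peak_sets) == "")) {
    names(peak_sets) <- paste0("dataset", seq_along(peak_sets))
  }
  grl <- lapply(names(peak_sets), function(id) {
    validate_intervals(peak_sets[[id]], what = id)
    GenomicRanges::reduce(bed0_to_granges(peak_sets[[id]]))
  })
  names(grl) <- names(peak_sets)
  all_gr <- do.call(c, unname(grl))
  if (length(all_gr) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      support = integer(), dataset_ids = character(),
                      stringsAsFactors = FALSE)
    attr(out, "n_datasets") <- length(peak_sets)
    class(out) <- c("support_partition", "data.frame")
    return(out)
  }
  seg <- GenomicRanges::disjoin(all_gr)
  memb <- vapply(grl, function(g) IRanges::overlapsAny(seg, g),
                 logical(length(seg)))
  memb <- matrix(memb, nrow = length(seg),
                 dimnames = list(NULL, names(peak_sets)))

  out <- granges_to_bed0(seg)
  key <- apply(memb, 1L, function(r) paste(which(r), collapse = ","))
  # merge book-ended neighbours on one chromosome with an identical dataset set
  ord <- order(out$chrom, out$start)
  out <- out[ord, , drop = FALSE]; key <- key[ord]; memb <- memb[ord, , drop = FALSE]
  n <- nrow(out)
  if (n > 1L) {
    same <- out$chrom[-1] == out$chrom[-n] &
      out$start[-1] == out$end[-n] & key[-1] == key[-n]
    grp <- cumsum(c(TRUE, !same))
  } else grp <- rep(1L, n)
  first <- !duplicated(grp)
  last <- cumsum(rle(grp)$lengths)   # groups are runs of contiguous rows
  merged <- data.frame(
    chrom = out$chrom[first],
    start = out$start[first],
    end = out$end[last],
    stringsAsFactors = FALSE
  )
  memb <- memb[first, , drop = FALSE]
  merged$support <- as.integer(rowSums(memb))
  merged$dataset_ids <- apply(memb, 1L, function(r)
    paste(colnames(memb)[r], collapse = ","))
  rownames(merged) <- NULL
  attr(merged, "n_datasets") <- length(peak_sets)
  class(merged) <- c("support_partition", "data.frame")
  merged
}

#' Recurrent binding sites from a support partition
#'
#' Keeps the segments supported by at least \code{k} datasets and merges kept
#' segments separated by at most \code{merge_gap} intervening bases
#' (default 0: book-ended segments only).
#'
#' @param partition a \code{support_partition} from
#'   \code{\link{multi_intersect}}.
#' @param k recurrence threshold, \code{1 <= k <= n} datasets. Published
#'   compendium thresholds: p53 5/28, E2F4 4/9, p130/p107 2/4, RB 3/6.
#' @param factor label for the resulting site set.
#' @param merge_gap maximum gap (bases) bridged when merging kept segments.
#' @return a \code{recurrent_sites} data.frame (\code{chrom}, \code{start},
#'   \code{end}) with attributes \code{factor}, \code{k}, \code{n}.
#' @export
recurrent_sites <- function(partition, k, factor = "factor", merge_gap = 0) {
  n <- attr(partition, "n_datasets")
  if (is.null(n)) n <- max(partition$support, 0L)
  stopifnot(k >= 1, k <= n)
  kept <- partition[partition$support >= k, c("chrom", "start", "end"),
                    drop = FALSE]
  if (nrow(kept)) {
    gr <- GenomicRanges::reduce(bed0_to_granges(kept),
                                min.gapwidth = merge_gap + 1L)
    kept <- granges_to_bed0(GenomicRanges::sort(gr))
  }
  new_recurrent_sites(kept, factor = factor, k = k, n = n)
}

new_recurrent_sites <- function(df, factor, k = NA_integer_, n = NA_integer_) {
  rownames(df) <- NULL
  attr(df, "factor") <- factor
  attr(df, "k") <- k
  attr(df, "n") <- n
  class(df) <- c("recurrent_sites", "data.frame")
  df
}

#' @export
print.recurrent_sites <- function(x, ...) {
  cat(sprintf("recurrent_sites[%s]: %d sites (k=%s of n=%s datasets)\n",
              attr(x, "factor"), nrow(x), attr(x, "k"), attr(x, "n")))
  invisible(x)
}

#' DREAM-binding sites as the intersection of E2F4 and p130/p107 sites
#'
#' The DREAM complex is located where both its key repressive components bind
#' recurrently; its site set is the base-wise intersection (overlapping
#' portions only) of the two recurrent site sets.
#'
#' @param e2f4,p130p107 \code{recurrent_sites} for the two factors.
#' @return \code{recurrent_sites} labelled \code{"DREAM"}.
#' @export
dream_sites <- function(e2f4, p130p107) {
  a <- bed0_to_granges(e2f4)
  b <- bed0_to_granges(p130p107)
  ov <- GenomicRanges::intersect(a, b)
  new_recurrent_sites(granges_to_bed0(GenomicRanges::sort(ov)), factor = "DREAM")
}

#' Load a precompiled recurrent-site BED (e.g. a published p53 site set)
#'
#' @param path BED3 path.
#' @param factor factor label.
#' @param k,n recurrence provenance, if known.
#' @param chrom_style see \code{\link{normalize_chrom}}.
#' @return \code{recurrent_sites}.
#' @export
load_recurrent_sites <- function(path, factor, k = NA_integer_,
                                 n = NA_integer_,
                                 chrom_style = c("none", "chr", "plain")) {
  df <- read_bed(path, chrom_style = match.arg(chrom_style))
  validate_intervals(df, what = path)
  gr <- GenomicRanges::sort(GenomicRanges::reduce(bed0_to_granges(df)))
  new_recurrent_sites(granges_to_bed0(gr), factor = factor, k = k, n = n)
}
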