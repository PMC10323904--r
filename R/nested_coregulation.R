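# Nested lncRNA / host-gene co-regulation. A lncRNA is nested when its full
# gene span lies within a protein-coding gene's span on the same strand and
# chromosome (overlap fraction of the lncRNA = 1). Co-regulation is the
# Spearman correlation of the two genes' log2 fold-change vectors across the
# DE datasets where both were testable.

#' Find lncRNAs fully nested in protein-coding host genes
#'
#' Strand-aware containment on gene spans: a pair (lncRNA, host) is reported
#' iff both genes share chromosome and strand and the host span fully
#' contains the lncRNA span. A lncRNA contained in several hosts yields one
#' pair per host.
#'
#' @param lnc_genes \code{gene_catalog} rows of lncRNA biotype.
#' @param coding_genes \code{gene_catalog} rows of protein-coding biotype.
#' @return data.frame of pairs: \code{lnc_id}, \code{host_id},
#'   \code{relation} (descriptive placement; \code{"unclassified"} when no
#'   exon models are supplied).
#' @export
find_nested <- function(lnc_genes, coding_genes) {
  empty <- data.frame(lnc_id = character(), host_id = character(),
                      relation = character(), stringsAsFactors = FALSE)
  if (nrow(lnc_genes) == 0L || nrow(coding_genes) == 0L) return(empty)
  lgr <- bed0_to_granges(lnc_genes[, c("chrom", "start", "end", "strand")])
  hgr <- bed0_to_granges(coding_genes[, c("chrom", "start", "end", "strand")])
  hits <- GenomicRanges::findOverlaps(lgr, hgr, type = "within",
                                      ignore.strand = FALSE)
  if (length(hits) == 0L) return(empty)
  data.frame(
    lnc_id = lnc_genes$gene_id[S4Vectors::queryHits(hits)],
    host_id = coding_genes$gene_id[S4Vectors::subjectHits(hits)],
    relation = "unclassified",
    stringsAsFactors = FALSE
  )
}

#' Spearman rank correlation with small-sample exact p-values
#'
#' Average ranks on ties; exact permutation null below n = 10 when there are
#' no ties, large-sample t approximation otherwise (the behaviour of
#' \code{stats::cor.test}).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with \code{rho} and two-sided \code{p}.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  exact <- length(x) < 10 && !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact)
  )
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Test lncRNA/host co-regulation across the DE compendium
#'
#' For each nested pair, restricts to the datasets where both genes have a
#' log2 fold-change, computes the Spearman correlation of the paired vectors,
#' and flags pairs with \code{rho > 0} and \code{p < alpha} as significantly
#' positively co-regulated. Pairs sharing fewer than \code{min_shared}
#' datasets are flagged untestable and carry no statistic.
#'
#' @param pairs pair table from \code{\link{find_nested}}.
#' @param de long-format DE table (\code{dataset_id}, \code{gene_id},
#'   \code{log2fc}).
#' @param alpha significance level for the positive-co-regulation flag
#'   (default 0.05).
#' @param min_shared minimum shared datasets for a correlation (default 3).
#' @return the pair table with added \code{n_shared}, \code{rho}, \code{p},
#'   \code{positive_coregulated}, \code{testable} columns.
#' @export
host_coregulation <- function(pairs, de, alpha = 0.05, min_shared = 3) {
  n <- nrow(pairs)
  pairs$n_shared <- integer(n)
  pairs$rho <- rep(NA_real_, n)
  pairs$p <- rep(NA_real_, n)
  pairs$testable <- logical(n)
  by_gene <- split(seq_len(nrow(de)), de$gene_id)
  for (i in seq_len(n)) {
    li <- by_gene[[pairs$lnc_id[i]]]
    hi <- by_gene[[pairs$host_id[i]]]
    if (is.null(li) || is.null(hi)) next
    lv <- stats::setNames(de$log2fc[li], de$dataset_id[li])
    hv <- stats::setNames(de$log2fc[hi], de$dataset_id[hi])
    shared <- intersect(names(lv), names(hv))
    pairs$n_shared[i] <- length(shared)
    if (length(shared) < min_shared) next
    st <- spearman_cor(lv[shared], hv[shared])
    pairs$rho[i] <- st$rho
    pairs$p[i] <- st$p
    pairs$testable[i] <- TRUE
  }
  pairs$positive_coregulated <- pairs$testable & !is.na(pairs$rho) &
    pairs$rho > 0 & pairs$p < alpha
  pairs
}

#' Write the nested-pair export
#' @param pairs annotated pair table.
#' @param path output TSV.
#' @export
write_nested_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
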