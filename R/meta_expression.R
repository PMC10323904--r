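# Recurrence scoring across a compendium of differential-expression (DE)
# datasets. The expression score of a gene is the number of datasets calling
# it significantly up-regulated minus the number calling it significantly
# down-regulated; the median log2 fold-change is taken over all datasets where
# the gene was testable, regardless of significance. A gene enters the score
# table only if it was testable in at least `min_expressed` datasets.

#' Read a differential-expression compendium
#'
#' Accepts either a single long-format TSV with columns \code{dataset_id},
#' \code{gene_id}, \code{log2fc}, \code{fdr} (and optionally a precomputed
#' ternary \code{call} column with values \code{up}/\code{down}/\code{ns}), or
#' a vector of per-dataset TSVs each with \code{gene_id}, \code{log2fc},
#' \code{fdr}; dataset ids then default to the file names. A gene absent from
#' a dataset's rows was not testable there.
#'
#' @param paths one or more TSV paths.
#' @param dataset_ids optional ids for the per-dataset form.
#' @return long-format data.frame of DE entries.
#' @export
read_de_tables <- function(paths, dataset_ids = NULL) {
  tabs <- lapply(paths, utils::read.table, sep = "\t", header = TRUE,
                 stringsAsFactors = FALSE)
  if (length(paths) == 1L && "dataset_id" %in% names(tabs[[1]])) {
    return(tabs[[1]])
  }
  if (is.null(dataset_ids)) dataset_ids <- basename(paths)
  for (i in seq_along(tabs)) tabs[[i]]$dataset_id <- dataset_ids[i]
  do.call(rbind, tabs)
}

#' Compute recurrence expression scores across DE datasets
#'
#' For every gene testable in at least \code{min_expressed} datasets, counts
#' the datasets calling it significantly up (\code{fdr < sig_fdr} and
#' \code{log2fc > 0}) and significantly down, and reports
#' \code{score = n_up - n_down} together with the median log2 fold-change over
#' all testable entries regardless of significance. An entry with
#' \code{log2fc == 0} counts neither up nor down even when significant, since
#' its direction is undefined. When the compendium carries a precomputed
#' ternary \code{call} column (\code{up}/\code{down}/\code{ns}), those calls
#' are used verbatim instead of the fdr threshold.
#'
#' @param de long-format DE table: \code{dataset_id}, \code{gene_id},
#'   \code{log2fc}, \code{fdr}, optional \code{call}.
#' @param sig_fdr significance threshold on the adjusted p-value (default
#'   0.05).
#' @param min_expressed minimum number of datasets in which a gene must be
#'   testable to be scored (default 3); genes below it are dropped, not
#'   scored 0.
#' @return data.frame of score records: \code{gene_id}, \code{n_expressed},
#'   \code{n_up}, \code{n_down}, \code{score}, \code{median_log2fc}.
#' @export
compute_scores <- function(de, sig_fdr = 0.05, min_expressed = 3) {
  stopifnot(sig_fdr > 0, sig_fdr < 1, min_expressed >= 1)
  if (anyDuplicated(de[, c("gene_id", "dataset_id")])) {
    dup <- de[duplicated(de[, c("gene_id", "dataset_id")]), ][1, ]
    stop(sprintf("duplicate DE entry for gene %s in dataset %s",
                 dup$gene_id, dup$dataset_id))
  }
  if (any(!is.finite(de$log2fc))) {
    stop("non-finite log2fc for testable entry (gene ",
         de$gene_id[which(!is.finite(de$log2fc))[1]], ")")
  }
  if ("call" %in% names(de)) {
    up <- de$call == "up"
    down <- de$call == "down"
  } else {
    sig <- de$fdr < sig_fdr
    up <- sig & de$log2fc > 0
    down <- sig & de$log2fc < 0
  }
  gid <- factor(de$gene_id)
  out <- data.frame(
    gene_id = levels(gid),
    n_expressed = as.integer(tabulate(gid, nlevels(gid))),
    n_up = as.integer(rowsum(as.integer(up), gid)[, 1]),
    n_down = as.integer(rowsum(as.integer(down), gid)[, 1]),
    stringsAsFactors = FALSE
  )
  out$score <- out$n_up - out$n_down
  med <- vapply(split(de$log2fc, gid), stats::median, 0)
  out$median_log2fc <- as.numeric(med)
  out <- out[out$n_expressed >= min_expressed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify recurrently regulated genes from their scores
#'
#' @param scores score table from \code{\link{compute_scores}}.
#' @param up_threshold inclusive lower bound on the score for the up set
#'   (default 10).
#' @param down_threshold inclusive upper bound for the down set (default -10).
#' @return list with character vectors \code{up_set} and \code{down_set}
#'   (disjoint by construction).
#' @export
classify_recurrent <- function(scores, up_threshold = 10, down_threshold = -10) {
  stopifnot(up_threshold > 0, down_threshold < 0)
  list(up_set = scores$gene_id[scores$score >= up_threshold],
       down_set = scores$gene_id[scores$score <= down_threshold])
}

#' Median fold-change profile for one gene
#'
#' @param gene_id gene to profile.
#' @param de long-format DE table.
#' @return list with \code{median} and the named per-dataset \code{log2fc}
#'   vector (datasets where the gene was testable).
#' @export
median_log2fc_profile <- function(gene_id, de) {
  rows <- de[de$gene_id == gene_id, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no expression data for gene ", gene_id)
  v <- stats::setNames(rows$log2fc, rows$dataset_id)
  list(median = stats::median(v), log2fc = v)
}

#' Write the score table export
#' @param scores score table; an optional \code{name} column is carried along.
#' @param path output TSV.
#' @export
write_score_table <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
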