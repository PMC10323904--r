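# Gene annotation: parse GTF into a flat gene catalog that defines the
# coordinate contract used by every downstream module. Internally all
# coordinates are 0-based half-open; GTF is 1-based closed and converted on
# read. Gene span = min/max over the gene's transcripts; the TSS set holds one
# position per distinct transcript start (leftmost base on '+', rightmost on
# '-').

#' Read a gene annotation (GTF) into a gene catalog
#'
#' Parses gene and transcript records from a GTF file and assembles one row
#' per gene with its biotype, strand, span and the deduplicated set of
#' transcription start sites (TSSs) of all its transcripts. Biotypes are
#' canonicalized into \code{lncRNA}, \code{protein_coding} and \code{other};
#' the \code{gene_biotype} and \code{gene_type} attribute keys are both
#' accepted. Records without a biotype attribute are dropped with a warning.
#'
#' @param path path to a GTF file (1-based closed coordinates; converted to
#'   the package-internal 0-based half-open convention).
#' @param keep_biotypes optional character vector of canonical biotypes to
#'   retain (e.g. \code{c("lncRNA", "protein_coding")}); \code{NULL} keeps
#'   everything.
#' @param chrom_style chromosome-name normalization, see
#'   \code{\link{normalize_chrom}}.
#' @param annotation_tag free-text provenance label stored on the catalog.
#' @return a \code{gene_catalog}: a data.frame with columns \code{gene_id},
#'   \code{name}, \code{biotype}, \code{chrom}, \code{start}, \code{end},
#'   \code{strand} and a list-column \code{tss} of sorted unique 0-based TSS
#'   positions, plus an \code{annotation_tag} attribute.
#' @export
read_gene_annotation <- function(path, keep_biotypes = NULL,
                                 chrom_style = c("none", "chr", "plain"),
                                 annotation_tag = basename(path)) {
  chrom_style <- match.arg(chrom_style)
  gtf <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gtf)
  feat <- as.character(meta$type)
  tx <- gtf[feat == "transcript"]
  if (length(tx) == 0L) stop("no transcript records found in ", path)
  txm <- S4Vectors::mcols(tx)
  biotype <- if ("gene_biotype" %in% names(txm)) txm$gene_biotype
             else if ("gene_type" %in% names(txm)) txm$gene_type
             else rep(NA_character_, length(tx))
  missing_bt <- is.na(biotype)
  if (any(missing_bt)) {
    warning(sum(missing_bt), " transcript record(s) without a biotype ",
            "attribute were excluded")
    tx <- tx[!missing_bt]
    txm <- S4Vectors::mcols(tx)
    biotype <- biotype[!missing_bt]
  }
  name <- if ("gene_name" %in% names(txm)) txm$gene_name else txm$gene_id

  df <- data.frame(
    gene_id = as.character(txm$gene_id),
    name = ifelse(is.na(name), as.character(txm$gene_id), as.character(name)),
    biotype = canonical_biotype(as.character(biotype)),
    chrom = normalize_chrom(as.character(GenomicRanges::seqnames(tx)), chrom_style),
    strand = as.character(GenomicRanges::strand(tx)),
    start0 = GenomicRanges::start(tx) - 1L,   # 1-based closed -> 0-based half-open
    end0 = GenomicRanges::end(tx),
    stringsAsFactors = FALSE
  )
  df$tss <- ifelse(df$strand == "-", df$end0 - 1L, df$start0)

  split_idx <- split(seq_len(nrow(df)), df$gene_id)
  genes <- lapply(split_idx, function(ix) {
    d <- df[ix, , drop = FALSE]
    list(gene_id = d$gene_id[1], name = d$name[1], biotype = d$biotype[1],
         chrom = d$chrom[1], start = min(d$start0), end = max(d$end0),
         strand = d$strand[1], tss = sort(unique(d$tss)))
  })
  cat <- data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    name = vapply(genes, `[[`, "", "name"),
    biotype = vapply(genes, `[[`, "", "biotype"),
    chrom = vapply(genes, `[[`, "", "chrom"),
    start = vapply(genes, `[[`, 0L, "start"),
    end = vapply(genes, `[[`, 0L, "end"),
    strand = vapply(genes, `[[`, "", "strand"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  cat$tss <- lapply(genes, `[[`, "tss")
  if (!is.null(keep_biotypes)) cat <- cat[cat$biotype %in% keep_biotypes, , drop = FALSE]
  rownames(cat) <- NULL
  new_gene_catalog(cat, annotation_tag)
}

canonical_biotype <- function(x) {
  out <- rep("other", length(x))
  out[x %in% c("lncRNA", "lincRNA", "antisense", "lnc_RNA")] <- "lncRNA"
  out[x == "protein_coding"] <- "protein_coding"
  out
}

new_gene_catalog <- function(df, annotation_tag = "") {
  stopifnot(all(c("gene_id", "name", "biotype", "chrom", "start", "end",
                  "strand", "tss") %in% names(df)))
  if (anyDuplicated(df$gene_id)) stop("gene_id values must be unique")
  if (any(df$start >= df$end)) stop("gene span must satisfy start < end")
  attr(df, "annotation_tag") <- annotation_tag
  class(df) <- c("gene_catalog", "data.frame")
  df
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat("gene_catalog:", nrow(x), "genes (",
      paste(sprintf("%s=%d", names(table(x$biotype)), table(x$biotype)),
            collapse = ", "),
      ") [", attr(x, "annotation_tag"), "]\n", sep = " ")
  invisible(x)
}

#' Extract TSS-centred windows for every gene
#'
#' For each gene, one window per TSS covering all positions within
#' \code{half_width} bases of the TSS inclusively, i.e. the 0-based half-open
#' interval \code{[tss - half_width, tss + half_width + 1)}, clamped at 0.
#' Windows of one gene may overlap and are deliberately not merged.
#'
#' @param catalog a \code{gene_catalog}.
#' @param half_width window half-width in bases (> 0); 2500 is the
#'   conventional promoter-proximity distance for p53, 1000 for DREAM/RB.
#' @return data.frame with columns \code{gene_id}, \code{chrom}, \code{tss},
#'   \code{start}, \code{end}.
#' @export
extract_tss_windows <- function(catalog, half_width) {
  stopifnot(half_width > 0)
  n_tss <- lengths(catalog$tss)
  tss <- unlist(catalog$tss, use.names = FALSE)
  if (is.null(tss)) tss <- integer(0)
  out <- data.frame(
    gene_id = rep(catalog$gene_id, n_tss),
    chrom = rep(catalog$chrom, n_tss),
    tss = as.integer(tss),
    stringsAsFactors = FALSE
  )
  out$start <- pmax(0L, out$tss - as.integer(half_width))
  out$end <- out$tss + as.integer(half_width) + 1L
  out
}

#' Write a gene catalog to its tabular export
#'
#' @param catalog a \code{gene_catalog}.
#' @param path output TSV path; the TSS set is serialized as a comma-joined
#'   \code{tss_csv} column.
#' @export
write_gene_catalog <- function(catalog, path) {
  out <- as.data.frame(catalog[, c("gene_id", "name", "biotype", "chrom",
                                   "start", "end", "strand")])
  out$tss_csv <- vapply(catalog$tss, function(v) paste(v, collapse = ","), "")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene catalog from the tabular export
#'
#' @param path TSV written by \code{\link{write_gene_catalog}}.
#' @param annotation_tag provenance label.
#' @return a \code{gene_catalog}.
#' @export
read_gene_catalog <- function(path, annotation_tag = basename(path)) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(tss_csv = "character"))
  df$tss <- lapply(strsplit(df$tss_csv, ","), as.integer)
  df$tss_csv <- NULL
  new_gene_catalog(df, annotation_tag)
}
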