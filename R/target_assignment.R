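# Mechanism classification of scored genes. Direct p53 targets carry a
# recurrent p53-binding site within a TSS window (2.5 kb by convention);
# enhancer-mediated targets have a high-confidence ("elite") enhancer
# association whose enhancer overlaps a recurrent p53 site while the gene
# itself lacks any TSS-proximal site; DREAM and RB targets carry the
# respective recurrent sites within 1 kb of a TSS. Direct and enhancer calls
# are evaluated on the recurrently up-regulated set, DREAM/RB on the
# down-regulated set, mirroring p53's activating vs p21-mediated repressive
# arms.

#' Genes with a recurrent binding site near a TSS
#'
#' A gene is assigned when any site interval overlaps any of its TSS windows
#' by at least one base (inclusive distance: \code{|pos - tss| <= half_width}).
#'
#' @param catalog a \code{gene_catalog}.
#' @param sites a \code{recurrent_sites} set.
#' @param half_width TSS window half-width in bases; 2500 for p53, 1000 for
#'   DREAM and RB.
#' @param mode \code{"any_base"} (default) overlaps the full site interval;
#'   \code{"midpoint"} requires the site midpoint to fall inside the window.
#' @return character vector of assigned gene ids.
#' @export
assign_tss_proximal <- function(catalog, sites, half_width = 2500,
                                mode = c("any_base", "midpoint")) {
  mode <- match.arg(mode)
  if (nrow(sites) == 0L || nrow(catalog) == 0L) return(character(0))
  win <- extract_tss_windows(catalog, half_width)
  wgr <- bed0_to_granges(win)
  sdf <- sites
  if (mode == "midpoint") {
    mid <- (sdf$start + sdf$end) %/% 2L
    sdf <- data.frame(chrom = sdf$chrom, start = mid, end = mid + 1L)
  }
  sgr <- bed0_to_granges(sdf)
  hit <- IRanges::overlapsAny(wgr, sgr, minoverlap = 1L)
  unique(win$gene_id[hit])
}

#' Read an enhancer:gene association table
#'
#' @param path TSV with columns \code{chrom}, \code{start}, \code{end},
#'   \code{gene_id}, \code{elite} (logical or 0/1); 0-based half-open
#'   enhancer intervals.
#' @return data.frame of enhancer links.
#' @export
read_enhancer_links <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$elite <- as.logical(df$elite)
  df
}

#' Genes regulated through a bound enhancer but not TSS-proximally
#'
#' A gene is assigned when (a) at least one of its elite-linked enhancers
#' overlaps a recurrent site by one or more bases and (b) the gene has no
#' TSS-proximal site within \code{tss_half_width} of any of its TSSs (direct
#' binding takes precedence). Only elite links participate; links that
#' reference a gene absent from the catalog are skipped with a warning.
#'
#' @param catalog a \code{gene_catalog}.
#' @param sites \code{recurrent_sites} (the same recurrent p53 set used for
#'   direct assignment).
#' @param links enhancer link table (see \code{\link{read_enhancer_links}}).
#' @param tss_half_width exclusion window half-width (default 2500).
#' @return character vector of assigned gene ids.
#' @export
assign_enhancer_mediated <- function(catalog, sites, links,
                                     tss_half_width = 2500) {
  links <- links[links$elite, , drop = FALSE]
  unknown <- !(links$gene_id %in% catalog$gene_id)
  if (any(unknown)) {
    warning(sum(unknown), " enhancer link(s) reference unknown gene ids ",
            "and were skipped")
    links <- links[!unknown, , drop = FALSE]
  }
  if (nrow(links) == 0L || nrow(sites) == 0L) return(character(0))
  egr <- bed0_to_granges(links)
  sgr <- bed0_to_granges(sites)
  bound <- IRanges::overlapsAny(egr, sgr, minoverlap = 1L)
  candidates <- unique(links$gene_id[bound])
  direct <- assign_tss_proximal(catalog, sites, half_width = tss_half_width)
  setdiff(candidates, direct)
}

#' Build the per-gene mechanism annotation
#'
#' Evaluates direct-p53 and enhancer-p53 flags on the recurrently up-regulated
#' set and DREAM/RB flags on the down-regulated set (or on all scored genes in
#' \code{scope = "all"} mode for exploratory use).
#'
#' @param up_set,down_set character vectors of recurrently up/down gene ids.
#' @param p53_sites,dream,rb \code{recurrent_sites} sets per factor.
#' @param catalog a \code{gene_catalog}.
#' @param links enhancer link table (may be \code{NULL}; then no enhancer
#'   calls are made).
#' @param p53_half_width,dream_rb_half_width TSS window half-widths
#'   (defaults 2500 and 1000).
#' @param scope \code{"directional"} (default) or \code{"all"}.
#' @return data.frame with one row per scored gene in scope and logical
#'   columns \code{direct_p53}, \code{enhancer_p53}, \code{dream}, \code{rb},
#'   \code{dream_rb} (the joined union).
#' @export
build_target_annotation <- function(up_set, down_set, p53_sites, dream, rb,
                                    catalog, links = NULL,
                                    p53_half_width = 2500,
                                    dream_rb_half_width = 1000,
                                    scope = c("directional", "all")) {
  scope <- match.arg(scope)
  all_ids <- union(up_set, down_set)
  cat_up <- catalog[catalog$gene_id %in%
                      (if (scope == "all") all_ids else up_set), , drop = FALSE]
  cat_down <- catalog[catalog$gene_id %in%
                        (if (scope == "all") all_ids else down_set), , drop = FALSE]
  direct <- assign_tss_proximal(cat_up, p53_sites, p53_half_width)
  enh <- if (is.null(links)) character(0) else
    assign_enhancer_mediated(cat_up, p53_sites, links, p53_half_width)
  dr <- assign_tss_proximal(cat_down, dream, dream_rb_half_width)
  rbs <- assign_tss_proximal(cat_down, rb, dream_rb_half_width)
  out <- data.frame(gene_id = all_ids, stringsAsFactors = FALSE)
  out$regulation <- ifelse(out$gene_id %in% up_set, "up", "down")
  out$direct_p53 <- out$gene_id %in% direct
  out$enhancer_p53 <- out$gene_id %in% enh
  out$dream <- out$gene_id %in% dr
  out$rb <- out$gene_id %in% rbs
  out$dream_rb <- out$dream | out$rb
  out
}

#' Write the mechanism-annotation export
#' @param annotation annotation table from
#'   \code{\link{build_target_annotation}}.
#' @param path output TSV.
#' @export
write_target_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
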