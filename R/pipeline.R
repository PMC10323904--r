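# End-to-end orchestration: scoring -> binding recurrence -> mechanism
# assignment -> nested co-regulation -> optional perturbation-dependence and
# survival stages, from one validated config. Outputs are written as each
# stage completes, so a failing stage leaves the earlier exports in place; a
# manifest records the config and the gene counts at every stage of the
# funnel (annotated -> expressed/scored -> recurrent -> classified).

#' Build and validate a pipeline configuration
#'
#' Input entries may be file paths (TSV/BED/GTF in the dialects the module
#' readers accept) or the equivalent in-memory objects.
#'
#' @param de long-format DE table or TSV path.
#' @param annotation a \code{gene_catalog}, a catalog TSV path, or a GTF path
#'   (suffix-detected).
#' @param peaks named list: factor label -> list of per-dataset interval
#'   tables (or BED paths) to run recurrence on.
#' @param site_sets named list: factor label -> precompiled
#'   \code{recurrent_sites} (or BED path), used as-is.
#' @param enhancers enhancer link table or TSV path (optional).
#' @param recurrence_k named integer vector: factor -> recurrence threshold
#'   (defaults: p53 5, E2F4 4, p130p107 2, RB 3).
#' @param sig_fdr,min_expressed scoring parameters.
#' @param up_threshold,down_threshold recurrence-score cutoffs.
#' @param p53_half_width,dream_rb_half_width TSS window half-widths.
#' @param alpha significance level for co-regulation calls.
#' @param out_dir output directory (created if absent).
#' @param seed seed recorded in the manifest.
#' @return validated config list of class \code{landscape_config}.
#' @export
landscape_config <- function(de, annotation, peaks = list(),
                             site_sets = list(), enhancers = NULL,
                             recurrence_k = c(p53 = 5, E2F4 = 4,
                                              p130p107 = 2, RB = 3),
                             sig_fdr = 0.05, min_expressed = 3,
                             up_threshold = 10, down_threshold = -10,
                             p53_half_width = 2500, dream_rb_half_width = 1000,
                             alpha = 0.05, out_dir = tempfile("landscape"),
                             seed = 1) {
  stopifnot(sig_fdr > 0, sig_fdr < 1, min_expressed >= 1,
            up_threshold > 0, down_threshold < 0,
            p53_half_width > 0, dream_rb_half_width > 0,
            alpha > 0, alpha < 1)
  if (length(peaks) && is.null(names(peaks))) stop("peaks must be named by factor")
  if (length(site_sets) && is.null(names(site_sets))) {
    stop("site_sets must be named by factor")
  }
  structure(list(de = de, annotation = annotation, peaks = peaks,
                 site_sets = site_sets, enhancers = enhancers,
                 recurrence_k = recurrence_k, sig_fdr = sig_fdr,
                 min_expressed = min_expressed, up_threshold = up_threshold,
                 down_threshold = down_threshold,
                 p53_half_width = p53_half_width,
                 dream_rb_half_width = dream_rb_half_width, alpha = alpha,
                 out_dir = out_dir, seed = seed),
            class = "landscape_config")
}

resolve_de <- function(x) if (is.character(x)) read_de_tables(x) else x

resolve_annotation <- function(x) {
  if (inherits(x, "gene_catalog")) return(x)
  if (is.character(x)) {
    if (grepl("\\.gtf(\\.gz)?$", x, ignore.case = TRUE)) {
      return(read_gene_annotation(x))
    }
    return(read_gene_catalog(x))
  }
  stop("annotation must be a gene_catalog or a path")
}

resolve_site_set <- function(x, factor) {
  if (inherits(x, "recurrent_sites")) return(x)
  if (is.character(x)) return(load_recurrent_sites(x, factor = factor))
  new_recurrent_sites(as.data.frame(x), factor = factor)
}

resolve_peak_sets <- function(x) {
  lapply(x, function(p) if (is.character(p)) read_bed(p) else p)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the integrative landscape pipeline
#'
#' Executes scoring, binding recurrence (DREAM derived from E2F4 and
#' p130/p107 when both are present), mechanism assignment, and nested-pair
#' co-regulation, writing one export per stage plus a manifest of funnel
#' counts. Reruns with the same config and inputs produce identical outputs.
#'
#' @param config a \code{landscape_config}.
#' @return list with \code{scores}, \code{sets} (up/down), \code{sites},
#'   \code{annotation} (mechanism flags), \code{nested}, \code{manifest} and
#'   \code{out_dir}, invisibly written under \code{config$out_dir}.
#' @export
run_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$out_dir, f)

  de <- run_stage("meta_expression", resolve_de(config$de))
  catalog <- run_stage("annotation_io", resolve_annotation(config$annotation))

  scores <- run_stage("meta_expression", {
    s <- compute_scores(de, sig_fdr = config$sig_fdr,
                        min_expressed = config$min_expressed)
    write_score_table(s, outp("scores.tsv"))
    s
  })
  sets <- classify_recurrent(scores, config$up_threshold,
                             config$down_threshold)

  sites <- run_stage("binding_recurrence", {
    out <- list()
    for (fac in names(config$peaks)) {
      part <- multi_intersect(resolve_peak_sets(config$peaks[[fac]]))
      k <- config$recurrence_k[[fac]]
      if (is.null(k)) stop("no recurrence threshold for factor ", fac)
      out[[fac]] <- recurrent_sites(part, k = k, factor = fac)
    }
    for (fac in names(config$site_sets)) {
      out[[fac]] <- resolve_site_set(config$site_sets[[fac]], fac)
    }
    if (all(c("E2F4", "p130p107") %in% names(out))) {
      out$DREAM <- dream_sites(out$E2F4, out$p130p107)
    }
    for (fac in names(out)) {
      write_bed(out[[fac]], outp(paste0("sites_", fac, ".bed")))
    }
    out
  })

  annotation <- run_stage("target_assignment", {
    links <- config$enhancers
    if (is.character(links)) links <- read_enhancer_links(links)
    empty <- new_recurrent_sites(
      data.frame(chrom = character(), start = integer(), end = integer()),
      factor = "empty")
    ann <- build_target_annotation(
      up_set = sets$up_set, down_set = sets$down_set,
      p53_sites = if (is.null(sites$p53)) empty else sites$p53,
      dream = if (is.null(sites$DREAM)) empty else sites$DREAM,
      rb = if (is.null(sites$RB)) empty else sites$RB,
      catalog = catalog, links = links,
      p53_half_width = config$p53_half_width,
      dream_rb_half_width = config$dream_rb_half_width)
    write_target_annotation(ann, outp("annotation.tsv"))
    ann
  })

  nested <- run_stage("nested_coregulation", {
    lnc <- catalog[catalog$biotype == "lncRNA", , drop = FALSE]
    pc <- catalog[catalog$biotype == "protein_coding", , drop = FALSE]
    pairs <- find_nested(lnc, pc)
    pairs <- pairs[pairs$lnc_id %in% c(sets$up_set, sets$down_set), ,
                   drop = FALSE]
    pairs <- host_coregulation(pairs, de, alpha = config$alpha)
    write_nested_pairs(pairs, outp("nested_pairs.tsv"))
    pairs
  })

  manifest <- c(
    n_annotated = nrow(catalog),
    n_expressed = nrow(scores),
    n_up = length(sets$up_set),
    n_down = length(sets$down_set),
    n_direct = sum(annotation$direct_p53),
    n_enhancer = sum(annotation$enhancer_p53),
    n_dream = sum(annotation$dream),
    n_rb = sum(annotation$rb),
    n_dream_rb = sum(annotation$dream_rb),
    n_nested = nrow(nested),
    n_nested_coregulated = sum(nested$positive_coregulated),
    sig_fdr = config$sig_fdr,
    min_expressed = config$min_expressed,
    up_threshold = config$up_threshold,
    down_threshold = config$down_threshold,
    p53_half_width = config$p53_half_width,
    dream_rb_half_width = config$dream_rb_half_width,
    alpha = config$alpha,
    seed = config$seed
  )
  man_df <- data.frame(key = names(manifest), value = unname(manifest),
                       stringsAsFactors = FALSE)
  utils::write.table(man_df, outp("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(scores = scores, sets = sets, sites = sites,
                 annotation = annotation, nested = nested,
                 manifest = manifest, out_dir = config$out_dir))
}
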