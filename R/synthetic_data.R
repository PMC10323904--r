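# Synthetic inputs with planted ground truth. Every generator is a pure
# function of (parameters, seed) and emits the truth alongside the data, so
# precision and recall of every downstream classification can be computed
# without re-reading generator internals. Default scales mirror the study
# conditions the pipeline is built for: 44 DE datasets, ChIP-seq compendia of
# 28 (p53) / 9 (E2F4) / 4 (p130/p107) / 6 (RB) peak sets with recurrence
# thresholds 5/4/2/3, and TPM experiments with 3 replicates per arm.

#' Define a planted regulatory landscape
#'
#' Fixes the gene universe and the planted subsets used by the generators:
#' recurrently up/down genes, the direct-target subset (receives a
#' TSS-proximal p53 site), the enhancer-target subset (bound enhancer, no
#' TSS-proximal site), and the DREAM/RB subsets of the down set.
#'
#' @param n_genes total genes.
#' @param n_up,n_down planted recurrently up-/down-regulated genes.
#' @param n_direct,n_enhancer subsets of the up set (disjoint).
#' @param n_dream,n_rb subsets of the down set (they may overlap via
#'   \code{n_dream_rb_overlap}).
#' @param n_dream_rb_overlap genes planted with both DREAM and RB sites.
#' @param n_nested planted nested lncRNA/host pairs: the lncRNAs are drawn
#'   from the up and down sets and each receives a protein-coding host gene
#'   (ids \code{HOSTnnn}) that responds together with it.
#' @param seed RNG seed.
#' @return list of class \code{landscape_plant} with gene ids per role; the
#'   scored gene universe is \code{c(genes, hosts)}.
#' @export
landscape_plant <- function(n_genes = 2000, n_up = 60, n_down = 30,
                            n_direct = 20, n_enhancer = 8,
                            n_dream = 12, n_rb = 8, n_dream_rb_overlap = 6,
                            n_nested = 10, seed = 1) {
  stopifnot(n_up + n_down <= n_genes,
            n_direct + n_enhancer <= n_up,
            n_dream + n_rb - n_dream_rb_overlap <= n_down,
            n_dream_rb_overlap <= min(n_dream, n_rb),
            n_nested <= n_up + n_down)
  set.seed(seed)
  ids <- sprintf("G%05d", seq_len(n_genes))
  up <- sample(ids, n_up)
  down <- sample(setdiff(ids, up), n_down)
  direct <- sample(up, n_direct)
  enhancer <- sample(setdiff(up, direct), n_enhancer)
  both <- sample(down, n_dream_rb_overlap)
  dream_only <- sample(setdiff(down, both), n_dream - n_dream_rb_overlap)
  rb_only <- sample(setdiff(down, c(both, dream_only)),
                    n_rb - n_dream_rb_overlap)
  nested_lnc <- if (n_nested > 0) sample(c(up, down), n_nested) else character(0)
  hosts <- if (n_nested > 0) sprintf("HOST%03d", seq_len(n_nested)) else character(0)
  structure(list(
    genes = ids, up = sort(up), down = sort(down), direct = sort(direct),
    enhancer = sort(enhancer),
    dream = sort(c(both, dream_only)), rb = sort(c(both, rb_only)),
    nested = data.frame(lnc_id = nested_lnc, host_id = hosts,
                        stringsAsFactors = FALSE),
    hosts = hosts,
    seed = seed
  ), class = "landscape_plant")
}

#' Write the planted truth to a TSV
#' @param plant a \code{landscape_plant}.
#' @param path output TSV (gene_id plus one logical column per role and the
#'   host id for nested lncRNAs).
#' @export
write_plant_truth <- function(plant, path) {
  df <- data.frame(gene_id = c(plant$genes, plant$hosts),
                   stringsAsFactors = FALSE)
  for (role in c("up", "down", "direct", "enhancer", "dream", "rb")) {
    df[[role]] <- df$gene_id %in% plant[[role]]
  }
  m <- match(plant$nested$lnc_id, df$gene_id)
  df$nested_in <- NA_character_
  df$nested_in[m] <- plant$nested$host_id
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Lay the planted landscape onto a synthetic gene annotation
#'
#' Places every plant gene on its own block of one synthetic chromosome:
#' host genes are protein-coding spans that strictly contain their nested
#' lncRNA on the same strand; all other plant genes are lncRNA spans. Block
#' spacing is wide enough that TSS windows and planted enhancers of different
#' genes can never touch.
#'
#' @param plant a \code{landscape_plant}.
#' @param gene_len host (protein-coding) gene length.
#' @param lnc_len lncRNA gene length.
#' @param block block spacing in bases.
#' @param seed RNG seed.
#' @return a \code{gene_catalog} covering \code{c(plant$genes, plant$hosts)}.
#' @export
simulate_landscape_annotation <- function(plant, gene_len = 20000,
                                          lnc_len = 2000, block = 120000,
                                          seed = 1) {
  set.seed(seed)
  block <- as.integer(block)
  gene_len <- as.integer(gene_len)
  lnc_len <- as.integer(lnc_len)
  nested_lnc <- plant$nested$lnc_id
  own_block <- c(setdiff(plant$genes, nested_lnc), plant$hosts)
  rows <- vector("list", length(own_block) + length(nested_lnc))
  host_span <- list()
  for (i in seq_along(own_block)) {
    id <- own_block[i]
    is_host <- id %in% plant$hosts
    len <- if (is_host) gene_len else lnc_len
    s <- (i - 1L) * block
    strand <- sample(c("+", "-"), 1L)
    rows[[i]] <- data.frame(
      gene_id = id, name = id,
      biotype = if (is_host) "protein_coding" else "lncRNA",
      chrom = "chrS", start = s, end = s + len, strand = strand,
      stringsAsFactors = FALSE
    )
    if (is_host) host_span[[id]] <- rows[[i]]
  }
  for (j in seq_along(nested_lnc)) {
    h <- host_span[[plant$nested$host_id[j]]]
    # centre the lncRNA in the host span so planted sites near the lncRNA TSS
    # stay outside every host TSS window
    s <- h$start + (h$end - h$start) %/% 2L - lnc_len %/% 2L
    rows[[length(own_block) + j]] <- data.frame(
      gene_id = nested_lnc[j], name = nested_lnc[j], biotype = "lncRNA",
      chrom = h$chrom, start = s, end = s + lnc_len, strand = h$strand,
      stringsAsFactors = FALSE
    )
  }
  genes <- do.call(rbind, rows)
  genes$tss <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    n_tx <- sample(1:2, 1L)
    prim <- if (g$strand == "-") g$end - 1L else g$start
    extra <- if (n_tx > 1L) {
      off <- sample.int(max(2L, (g$end - g$start) %/% 4L), 1L)
      if (g$strand == "-") g$end - 1L - off else g$start + off
    } else integer(0)
    sort(unique(as.integer(c(prim, extra))))
  })
  new_gene_catalog(genes, annotation_tag = "synthetic landscape")
}

#' Simulate a differential-expression compendium with planted recurrence
#'
#' Planted up genes respond (significant, log2fc centred at
#' \code{+effect_mu}) in a \code{response_prob} fraction of the datasets where
#' they are testable; down genes mirror this; null genes are centred at zero
#' with uniform adjusted p-values. Presence is dropped independently per
#' (gene, dataset) with \code{missing_prob}, emulating sparse lncRNA
#' detectability.
#'
#' @param plant a \code{landscape_plant}.
#' @param n_datasets number of DE datasets (default 44).
#' @param response_prob per-dataset probability that a planted gene responds
#'   significantly (default 0.5).
#' @param effect_mu mean |log2fc| of a response (default 2).
#' @param noise_sd log2fc noise sd (default 0.5).
#' @param missing_prob probability a gene is not testable in a dataset
#'   (default 0.3).
#' @param sig_fdr significance level the generated fdr values respect
#'   (default 0.05).
#' @param min_expressed guard: error when \code{n_datasets} is below it.
#' @param host_noise_sd log2fc noise added to a host gene around its nested
#'   lncRNA's value (default 0.3), planting positive co-regulation.
#' @param seed RNG seed.
#' @return long-format DE data.frame (\code{dataset_id}, \code{gene_id},
#'   \code{log2fc}, \code{fdr}) covering the plant genes and their hosts.
#' @export
simulate_de_compendium <- function(plant, n_datasets = 44,
                                   response_prob = 0.5, effect_mu = 2,
                                   noise_sd = 0.5, missing_prob = 0.3,
                                   sig_fdr = 0.05, min_expressed = 3,
                                   host_noise_sd = 0.3, seed = 1) {
  stopifnot(response_prob >= 0, response_prob <= 1,
            missing_prob >= 0, missing_prob < 1)
  if (n_datasets < min_expressed) {
    stop("n_datasets must be at least min_expressed (", min_expressed, ")")
  }
  set.seed(seed)
  ids <- plant$genes
  n <- length(ids)
  role <- ifelse(ids %in% plant$up, 1L, ifelse(ids %in% plant$down, -1L, 0L))
  out <- vector("list", n_datasets)
  for (d in seq_len(n_datasets)) {
    present <- stats::runif(n) >= missing_prob
    respond <- role != 0L & stats::runif(n) < response_prob
    lfc <- stats::rnorm(n, mean = effect_mu * role * respond, sd = noise_sd)
    # responders get a significant call; everyone else a null-uniform fdr
    fdr <- ifelse(respond,
                  stats::runif(n, 0, sig_fdr * 0.98),
                  stats::runif(n, sig_fdr, 1))
    # make responder direction consistent with the planted sign
    flip <- respond & sign(lfc) != role
    lfc[flip] <- -lfc[flip]
    tab <- data.frame(
      dataset_id = sprintf("DS%02d", d), gene_id = ids,
      log2fc = lfc, fdr = fdr, stringsAsFactors = FALSE
    )[present, , drop = FALSE]
    # host genes shadow their nested lncRNA's fold-change (co-regulation)
    if (nrow(plant$nested)) {
      idx <- match(plant$nested$lnc_id, tab$gene_id)
      ok <- !is.na(idx)
      if (any(ok)) {
        hosts <- data.frame(
          dataset_id = sprintf("DS%02d", d),
          gene_id = plant$nested$host_id[ok],
          log2fc = tab$log2fc[idx[ok]] +
            stats::rnorm(sum(ok), 0, host_noise_sd),
          fdr = tab$fdr[idx[ok]], stringsAsFactors = FALSE
        )
        tab <- rbind(tab, hosts)
      }
    }
    out[[d]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a multi-dataset ChIP-seq peak compendium around truth sites
#'
#' Every truth site appears in each dataset with probability
#' \code{detect_prob}, with endpoints jittered by Gaussian noise; decoy sites
#' appear with a (low) probability of their own, emulating
#' dataset-specific noise peaks.
#'
#' @param truth_sites interval table of true binding sites.
#' @param n_datasets number of peak sets.
#' @param detect_prob per-dataset detection probability of a truth site.
#' @param jitter_sd endpoint jitter sd in bases.
#' @param decoy_sites optional interval table of decoys.
#' @param decoy_prob per-dataset detection probability of a decoy.
#' @param seed RNG seed.
#' @return named list of per-dataset interval tables.
#' @export
simulate_peak_compendium <- function(truth_sites, n_datasets,
                                     detect_prob = 0.8, jitter_sd = 10,
                                     decoy_sites = NULL, decoy_prob = 0.1,
                                     seed = 1) {
  stopifnot(jitter_sd >= 0, detect_prob >= 0, detect_prob <= 1)
  set.seed(seed)
  jitter_one <- function(df) {
    if (nrow(df) == 0L || jitter_sd == 0) return(df)
    df$start <- pmax(0L, as.integer(round(df$start +
                                            stats::rnorm(nrow(df), 0, jitter_sd))))
    df$end <- as.integer(round(df$end + stats::rnorm(nrow(df), 0, jitter_sd)))
    df$end <- pmax(df$end, df$start + 1L)
    df
  }
  out <- vector("list", n_datasets)
  for (d in seq_len(n_datasets)) {
    keep <- stats::runif(nrow(truth_sites)) < detect_prob
    peaks <- jitter_one(truth_sites[keep, c("chrom", "start", "end"),
                                    drop = FALSE])
    if (!is.null(decoy_sites) && nrow(decoy_sites)) {
      dk <- stats::runif(nrow(decoy_sites)) < decoy_prob
      peaks <- rbind(peaks, jitter_one(
        decoy_sites[dk, c("chrom", "start", "end"), drop = FALSE]))
    }
    peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
    rownames(peaks) <- NULL
    out[[d]] <- peaks
  }
  names(out) <- sprintf("peakset%02d", seq_len(n_datasets))
  out
}

#' Simulate a gene annotation with planted nested lncRNA/host pairs
#'
#' Lays protein-coding genes on non-overlapping blocks of one chromosome;
#' \code{n_nested} lncRNAs are placed strictly inside a host's span on the
#' same strand; the remaining lncRNAs are decoys: intergenic, partially
#' overlapping a host (overlap fraction about 0.5), or antisense inside a
#' host — none of which must ever be reported as nested.
#'
#' @param n_coding,n_lnc gene counts per biotype.
#' @param n_nested number of planted nested pairs (\code{<= n_lnc}).
#' @param genome_len chromosome length in bases.
#' @param gene_len coding-gene length.
#' @param seed RNG seed.
#' @return list with \code{catalog} (a \code{gene_catalog}) and
#'   \code{truth_pairs} (\code{lnc_id}, \code{host_id}).
#' @export
simulate_annotation <- function(n_coding = 30, n_lnc = 30, n_nested = 10,
                                genome_len = 2e6, gene_len = 20000, seed = 1) {
  stopifnot(n_nested <= n_lnc, n_nested <= n_coding)
  block <- gene_len * 2L
  if (n_coding * block + gene_len > genome_len) {
    stop("genome too small to place ", n_coding,
         " coding genes without unintended containment")
  }
  set.seed(seed)
  strands <- sample(c("+", "-"), n_coding, replace = TRUE)
  coding <- data.frame(
    gene_id = sprintf("PC%04d", seq_len(n_coding)),
    name = sprintf("PC%04d", seq_len(n_coding)),
    biotype = "protein_coding",
    chrom = "chr1",
    start = (seq_len(n_coding) - 1L) * block,
    end = (seq_len(n_coding) - 1L) * block + gene_len,
    strand = strands,
    stringsAsFactors = FALSE
  )
  lnc_rows <- list(); truth <- list()
  lnc_len <- gene_len %/% 10L
  for (i in seq_len(n_lnc)) {
    id <- sprintf("LNC%04d", i)
    if (i <= n_nested) {                       # nested: strictly inside host i
      h <- coding[i, ]
      s <- h$start + 2L * lnc_len
      lnc_rows[[i]] <- data.frame(gene_id = id, name = id, biotype = "lncRNA",
                                  chrom = h$chrom, start = s,
                                  end = s + lnc_len, strand = h$strand,
                                  stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(lnc_id = id,
                                                host_id = h$gene_id,
                                                stringsAsFactors = FALSE)
    } else {
      kind <- (i - n_nested) %% 3L
      h <- coding[1L + (i %% n_coding), ]
      if (kind == 0L) {                        # intergenic decoy
        s <- h$end + lnc_len * 2L
        st <- sample(c("+", "-"), 1L)
      } else if (kind == 1L) {                 # partial-overlap decoy (~0.5)
        s <- h$end - lnc_len %/% 2L
        st <- h$strand
      } else {                                 # antisense decoy inside host
        s <- h$start + 4L * lnc_len
        st <- if (h$strand == "+") "-" else "+"
      }
      lnc_rows[[i]] <- data.frame(gene_id = id, name = id, biotype = "lncRNA",
                                  chrom = h$chrom, start = s,
                                  end = s + lnc_len, strand = st,
                                  stringsAsFactors = FALSE)
    }
  }
  genes <- rbind(coding, do.call(rbind, lnc_rows))
  # one to three transcripts per gene; extra transcripts start inside the span
  genes$tss <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    n_tx <- sample(1:3, 1L)
    prim <- if (g$strand == "-") g$end - 1L else g$start
    extra <- if (n_tx > 1L) {
      off <- sample.int(max(2L, (g$end - g$start) %/% 4L), n_tx - 1L)
      if (g$strand == "-") g$end - 1L - off else g$start + off
    } else integer(0)
    sort(unique(c(prim, as.integer(extra))))
  })
  catalog <- new_gene_catalog(genes, annotation_tag = "synthetic")
  truth_pairs <- if (length(truth)) do.call(rbind, truth) else
    data.frame(lnc_id = character(), host_id = character())
  list(catalog = catalog, truth_pairs = truth_pairs)
}

#' Export a gene catalog as GTF (gene + transcript records)
#'
#' Writes 1-based closed GTF records, one gene feature per gene and one
#' transcript feature per TSS, carrying \code{gene_biotype}; round-trips
#' through \code{\link{read_gene_annotation}}.
#'
#' @param catalog a \code{gene_catalog}.
#' @param path output GTF path.
#' @export
write_gtf <- function(catalog, path) {
  lines <- character(0)
  for (i in seq_len(nrow(catalog))) {
    g <- catalog[i, ]
    attr_g <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                      g$gene_id, g$name, g$biotype)
    lines <- c(lines, paste(g$chrom, "synthetic", "gene", g$start + 1L, g$end,
                            ".", g$strand, ".", attr_g, sep = "\t"))
    tss <- g$tss[[1]]
    for (j in seq_along(tss)) {
      if (g$strand == "-") { s <- g$start + 1L; e <- tss[j] + 1L }
      else { s <- tss[j] + 1L; e <- g$end }
      attr_t <- sprintf(paste0('gene_id "%s"; transcript_id "%s.t%d"; ',
                               'gene_name "%s"; gene_biotype "%s";'),
                        g$gene_id, g$gene_id, j, g$name, g$biotype)
      lines <- c(lines, paste(g$chrom, "synthetic", "transcript", s, e,
                              ".", g$strand, ".", attr_t, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a TPM perturbation experiment with planted dependence
#'
#' Builds a genes x samples TPM matrix over a genotype x treatment design.
#' For the two-genotype (parental / knockout) design, planted dependent genes
#' are repressed by \code{effect_log2} in the parental treated arm only;
#' planted independent repressed genes are repressed in both genotypes. For
#' the four-genotype pocket-protein design, repression follows the planted
#' predominance class (RB-predominant genes lose repression in the
#' RB-depleted and triple arms, and so on).
#'
#' @param gene_roles named character vector: gene id -> role. Two-genotype
#'   roles: \code{dependent}, \code{independent}, \code{null}. Four-genotype
#'   roles: \code{rb_predominant}, \code{dream_predominant},
#'   \code{cooperative}, \code{null}.
#' @param design \code{"knockout"} (parental/knockout) or \code{"pocket"}
#'   (parental / RB-depleted / p130p107-depleted / triple-depleted).
#' @param n_replicates replicates per arm (default 3).
#' @param base_meanlog,base_sdlog log-normal base expression parameters
#'   (natural-log scale; defaults give typical TPMs in the tens).
#' @param effect_log2 planted repression effect in log2 units (default 2).
#' @param noise_sd replicate noise sd in log2 units (default 0.2).
#' @param seed RNG seed.
#' @return list with the \code{tpm_experiment} and the \code{roles} truth.
#' @export
simulate_tpm_experiment <- function(gene_roles,
                                    design = c("knockout", "pocket"),
                                    n_replicates = 3,
                                    base_meanlog = 3, base_sdlog = 1,
                                    effect_log2 = 2, noise_sd = 0.2,
                                    seed = 1) {
  design <- match.arg(design)
  stopifnot(n_replicates >= 2)
  set.seed(seed)
  genotypes <- if (design == "knockout") c("parental", "p21_null")
               else c("parental", "rb_depleted", "p130p107_depleted",
                      "triple_depleted")
  samples <- expand.grid(replicate = seq_len(n_replicates),
                         treatment = c("control", "treated"),
                         genotype = genotypes, stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_%s_r%d", samples$genotype, samples$treatment,
                            samples$replicate)
  genes <- names(gene_roles)
  base <- stats::rlnorm(length(genes), base_meanlog, base_sdlog)
  names(base) <- genes

  repressed_in <- function(role, genotype) {
    if (design == "knockout") {
      switch(role,
             dependent = genotype == "parental",
             independent = TRUE,
             null = FALSE)
    } else {
      switch(role,
             rb_predominant = !genotype %in% c("rb_depleted", "triple_depleted"),
             dream_predominant = !genotype %in% c("p130p107_depleted",
                                                  "triple_depleted"),
             cooperative = genotype != "triple_depleted",
             null = FALSE)
    }
  }
  tpm <- matrix(0, nrow = length(genes), ncol = nrow(samples),
                dimnames = list(genes, samples$sample))
  for (s in seq_len(nrow(samples))) {
    delta <- vapply(genes, function(g) {
      if (samples$treatment[s] == "treated" &&
          repressed_in(gene_roles[[g]], samples$genotype[s])) -effect_log2
      else 0
    }, 0)
    tpm[, s] <- base * 2^(delta + stats::rnorm(length(genes), 0, noise_sd))
  }
  list(experiment = tpm_experiment(tpm, samples), roles = gene_roles)
}

#' Simulate a survival cohort with planted group hazards
#'
#' Patients are assigned latent score groups (low/medium/high); survival
#' times are exponential with group-specific hazards, censoring replaces a
#' \code{censor_rate} fraction of times with a uniform draw below the event
#' time. A TPM matrix is generated in which the target gene set is shifted on
#' the log2 scale by \code{shift_sd} noise-standard-deviations per group step,
#' so single-sample enrichment plus tertiles approximately reconstruct the
#' planted groups.
#'
#' @param n patients.
#' @param group_fractions fractions of low/medium/high (sum to 1).
#' @param hr_medium,hr_high hazard ratios vs the low group.
#' @param baseline_hazard events per day in the low group.
#' @param censor_rate fraction of patients censored.
#' @param p53_mutant_fraction fraction of mutant-p53 patients.
#' @param n_genes background genes in the expression matrix.
#' @param set_size size of the target gene set.
#' @param shift_sd per-group-step log2 shift of set genes, in units of the
#'   log2 noise sd.
#' @param noise_sd log2 expression noise sd (default 1).
#' @param seed RNG seed.
#' @return list with \code{cohort} (data.frame), \code{expr} (genes x
#'   samples TPM matrix), \code{gene_set} and \code{truth_group}.
#' @export
simulate_cohort <- function(n = 600, group_fractions = c(1, 1, 1) / 3,
                            hr_medium = 1.5, hr_high = 2,
                            baseline_hazard = 1 / 2000, censor_rate = 0.3,
                            p53_mutant_fraction = 0.4,
                            n_genes = 200, set_size = 30, shift_sd = 1,
                            noise_sd = 1, seed = 1) {
  stopifnot(abs(sum(group_fractions) - 1) < 1e-8)
  set.seed(seed)
  grp <- sample(c("low", "medium", "high"), n, replace = TRUE,
                prob = group_fractions)
  hr <- c(low = 1, medium = hr_medium, high = hr_high)[grp]
  time <- stats::rexp(n, rate = baseline_hazard * hr)
  event <- rep(1L, n)
  cens <- stats::runif(n) < censor_rate
  time[cens] <- stats::runif(sum(cens), 0, time[cens])
  event[cens] <- 0L
  time <- pmax(time, 1)
  cohort <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    time = time, event = event,
    age = round(stats::rnorm(n, 62, 11)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    p53_status = ifelse(stats::runif(n) < p53_mutant_fraction,
                        "mutant", "wild_type"),
    stringsAsFactors = FALSE
  )
  genes <- sprintf("SG%04d", seq_len(n_genes))
  gene_set <- genes[seq_len(set_size)]
  gstep <- c(low = -1, medium = 0, high = 1)[grp]
  base <- stats::rnorm(n_genes, 5, 2)          # per-gene log2 baseline
  log2e <- matrix(stats::rnorm(n_genes * n, 0, noise_sd), n_genes, n) + base
  shift <- shift_sd * noise_sd
  log2e[seq_len(set_size), ] <- log2e[seq_len(set_size), ] +
    matrix(shift * gstep, set_size, n, byrow = TRUE)
  expr <- 2^log2e
  dimnames(expr) <- list(genes, cohort$sample_id)
  list(cohort = cohort, expr = expr, gene_set = gene_set,
       truth_group = stats::setNames(grp, cohort$sample_id))
}

#' Plant binding sites and enhancers on a synthetic annotation
#'
#' Places a true p53 site on a TSS of every planted direct-target gene, a
#' distal enhancer with a p53 site for every enhancer-target gene, and
#' DREAM/RB sites within 1 kb of the TSS of the respective down-set genes.
#' Decoy sites are placed far from all genes.
#'
#' @param catalog a \code{gene_catalog} covering the planted genes.
#' @param plant a \code{landscape_plant}.
#' @param n_decoys decoy sites per factor.
#' @param seed RNG seed.
#' @return list with per-factor truth site tables (\code{p53}, \code{e2f4},
#'   \code{p130p107}, \code{rb}), \code{decoys}, and the enhancer
#'   \code{links} table.
#' @export
plant_binding_landscape <- function(catalog, plant, n_decoys = 20, seed = 1) {
  set.seed(seed)
  tss1 <- vapply(catalog$tss, `[[`, 0L, 1L)
  names(tss1) <- catalog$gene_id
  chrom <- stats::setNames(catalog$chrom, catalog$gene_id)
  site_at <- function(gene, offset, width = 200L) {
    centre <- tss1[[gene]] + offset
    data.frame(chrom = chrom[[gene]], start = max(0L, centre - width %/% 2L),
               end = max(0L, centre - width %/% 2L) + width,
               stringsAsFactors = FALSE)
  }
  p53 <- do.call(rbind, lapply(plant$direct, site_at, offset = 500L))
  # enhancer targets: p53 site far from every TSS, linked via an enhancer
  enh_sites <- do.call(rbind, lapply(plant$enhancer, site_at, offset = 50000L))
  links <- NULL
  if (length(plant$enhancer)) {
    links <- data.frame(
      chrom = enh_sites$chrom,
      start = enh_sites$start - 200L, end = enh_sites$end + 200L,
      gene_id = plant$enhancer, elite = TRUE, stringsAsFactors = FALSE
    )
  }
  e2f4 <- do.call(rbind, lapply(plant$dream, site_at, offset = 300L))
  p130p107 <- do.call(rbind, lapply(plant$dream, site_at, offset = 300L))
  rb <- do.call(rbind, lapply(plant$rb, site_at, offset = -300L))
  far <- max(catalog$end) + 100000L
  decoys <- data.frame(
    chrom = catalog$chrom[1],
    start = far + seq_len(n_decoys) * 1000L,
    end = far + seq_len(n_decoys) * 1000L + 200L,
    stringsAsFactors = FALSE
  )
  list(p53 = rbind(p53, enh_sites), e2f4 = e2f4, p130p107 = p130p107,
       rb = rb, decoys = decoys, links = links)
}
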