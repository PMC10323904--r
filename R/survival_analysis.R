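# Gene-set survival stratification. Each patient is scored for a gene set
# with a single-sample rank-weighted running-sum enrichment statistic
# (ssGSEA-style), scores are range-normalized across the cohort, patients are
# split into score tertiles (low / medium / high), and the groups enter a Cox
# proportional-hazards model controlled for age and sex; Kaplan-Meier curves
# visualize the groups and the cohort can be split by p53 mutation status.

#' Single-sample gene-set enrichment scores
#'
#' Per sample, genes are ranked by expression in descending order (average
#' ranks on ties). Walking down the ranking, the running sum accumulates
#' \code{P_in(i) - P_out(i)} at every rank position i, where \code{P_in} is
#' the weighted fraction of gene-set members seen so far (weight = the gene's
#' ascending rank magnitude, i.e. the top gene weighs N, raised to
#' \code{alpha}) and \code{P_out} the unweighted fraction of non-members seen
#' so far. The enrichment score is the sum of the running-sum increments over
#' all positions.
#'
#' @param expr numeric genes x samples matrix (e.g. TPM); rownames are gene
#'   ids.
#' @param gene_set character vector of gene ids; must intersect the matrix
#'   genes and must not cover all of them.
#' @param alpha rank-weight exponent (default 0.75).
#' @return named numeric vector of raw enrichment scores, one per sample.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.75) {
  genes <- rownames(expr)
  in_set <- genes %in% gene_set
  if (!any(in_set)) stop("gene_set has empty intersection with the matrix")
  if (all(in_set)) stop("gene_set covers all genes; the complement is empty")
  n <- length(genes)
  apply(expr, 2L, function(x) {
    r <- rank(x, ties.method = "average")      # ascending: top gene gets N
    ord <- order(x, decreasing = TRUE)
    w <- r[ord]^alpha
    member <- in_set[ord]
    w_in <- cumsum(ifelse(member, w, 0)) / sum(w[member])
    f_out <- cumsum(!member) / sum(!member)
    sum(w_in - f_out)
  })
}

#' Range-normalize raw enrichment scores across a cohort
#'
#' @param raw named numeric vector of raw scores for one gene set.
#' @return scores divided by the cohort range (max - min); constant scores
#'   give all zeros with a warning, a single sample passes through with a
#'   warning.
#' @export
normalize_scores <- function(raw) {
  if (length(raw) < 2L) {
    warning("single sample: scores passed through unnormalized")
    return(raw)
  }
  rng <- max(raw) - min(raw)
  if (rng == 0) {
    warning("constant raw scores: normalized scores set to 0")
    return(raw * 0)
  }
  raw / rng
}

#' Split a cohort into score tertiles
#'
#' Samples are sorted by score ascending, ties broken by sample id for
#' determinism; the lowest third is labelled \code{low}, the middle
#' \code{medium}, the top \code{high}. When n is not divisible by 3 the
#' remainder goes to \code{low} first, then \code{high} (10 samples give
#' 4/3/3).
#'
#' @param scores named numeric vector (names = sample ids).
#' @return factor of labels \code{low}/\code{medium}/\code{high} named by
#'   sample id, in the input order.
#' @export
tertile_groups <- function(scores) {
  n <- length(scores)
  stopifnot(n >= 3)
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  base <- n %/% 3L
  r <- n %% 3L
  sizes <- c(low = base + (r >= 1L), medium = base, high = base + (r >= 2L))
  ord <- order(scores, ids)
  lab <- rep(c("low", "medium", "high"), times = sizes)
  out <- character(n)
  out[ord] <- lab
  factor(stats::setNames(out, ids), levels = c("low", "medium", "high"))
}

#' Fit a Cox proportional-hazards model on score groups
#'
#' Partial-likelihood fit (Efron tie handling) of
#' \code{Surv(time, event) ~ group + age + sex} with \code{low} as the
#' reference group, plus a likelihood-ratio test of the group indicators
#' against the same model without them.
#'
#' @param cohort data.frame with \code{sample_id}, \code{time}, \code{event},
#'   \code{age}, \code{sex}.
#' @param groups factor from \code{\link{tertile_groups}} aligned with (or
#'   named by) \code{cohort$sample_id}.
#' @return list of class \code{cox_group_fit}: hazard-ratio table (HR, 95%
#'   CI per coefficient), the LR test (\code{lr_stat}, \code{lr_df},
#'   \code{lr_p}), and the underlying \code{coxph} fit.
#' @export
cox_fit <- function(cohort, groups) {
  if (!is.null(names(groups))) groups <- groups[cohort$sample_id]
  stopifnot(length(groups) == nrow(cohort))
  if (sum(cohort$event) == 0) stop("no events in the cohort")
  d <- data.frame(time = cohort$time, event = cohort$event,
                  group = factor(groups, levels = c("low", "medium", "high")),
                  age = cohort$age, sex = factor(cohort$sex))
  present <- table(d$group[d$event == 1])
  if (sum(table(d$group) > 0) < 2) stop("need at least two non-empty groups")
  full <- survival::coxph(survival::Surv(time, event) ~ group + age + sex,
                          data = d, ties = "efron")
  reduced <- survival::coxph(survival::Surv(time, event) ~ age + sex,
                             data = d, ties = "efron")
  lr_stat <- 2 * (full$loglik[2] - reduced$loglik[2])
  lr_df <- length(stats::coef(full)) - length(stats::coef(reduced))
  lr_p <- stats::pchisq(lr_stat, df = lr_df, lower.tail = FALSE)
  ci <- stats::confint(full)
  hr <- data.frame(
    term = names(stats::coef(full)),
    hr = exp(unname(stats::coef(full))),
    ci_low = exp(ci[, 1]),
    ci_high = exp(ci[, 2]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(hr = hr, lr_stat = lr_stat, lr_df = lr_df, lr_p = lr_p,
                 fit = full, events_per_group = present),
            class = "cox_group_fit")
}

#' @export
print.cox_group_fit <- function(x, ...) {
  cat("Cox PH fit on score groups (reference: low)\n")
  print(x$hr, digits = 3)
  cat(sprintf("LR test (groups): chi2 = %.3f, df = %d, p = %.3g\n",
              x$lr_stat, x$lr_df, x$lr_p))
  invisible(x)
}

#' Kaplan-Meier estimates per score group
#'
#' Product-limit estimator per group; the plotting horizon truncates the
#' rendered range only, never the estimate.
#'
#' @param cohort cohort data.frame (see \code{\link{cox_fit}}).
#' @param groups group factor.
#' @param plot_horizon rendering horizon in days (default 5000).
#' @return list with a \code{survfit} object, a tidy step-function table
#'   (\code{group}, \code{time}, \code{surv}, \code{n_risk}, \code{n_event})
#'   and the horizon.
#' @export
km_estimate <- function(cohort, groups, plot_horizon = 5000) {
  if (!is.null(names(groups))) groups <- groups[cohort$sample_id]
  d <- data.frame(time = cohort$time, event = cohort$event, group = groups)
  empty <- setdiff(levels(factor(groups)), unique(as.character(groups)))
  if (length(empty)) warning("empty group(s) omitted: ",
                             paste(empty, collapse = ", "))
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  if (is.null(sf$strata)) {
    grp <- rep(as.character(d$group[1]), length(sf$time))
  } else {
    grp <- rep(sub("^group=", "", names(sf$strata)), sf$strata)
  }
  steps <- data.frame(group = grp, time = sf$time, surv = sf$surv,
                      n_risk = sf$n.risk, n_event = sf$n.event,
                      stringsAsFactors = FALSE)
  list(survfit = sf, steps = steps, plot_horizon = plot_horizon)
}

#' Plot Kaplan-Meier curves for score groups
#'
#' @param km result of \code{\link{km_estimate}}.
#' @param main plot title.
#' @export
plot_km <- function(km, main = "Overall survival by gene-set score group") {
  cols <- c(low = "#2166ac", medium = "#878787", high = "#b2182b")
  groups <- unique(km$steps$group)
  plot(km$survfit, col = cols[groups], lwd = 2, xlim = c(0, km$plot_horizon),
       xlab = "Days", ylab = "Survival probability", main = main)
  graphics::legend("bottomleft", legend = groups, col = cols[groups], lwd = 2,
                   bty = "n")
  invisible(km)
}

#' Split a cohort by p53 mutation status
#'
#' @param cohort data.frame with a \code{p53_status} column taking values
#'   \code{wild_type}, \code{mutant}, \code{unknown}.
#' @return list with \code{wild_type} and \code{mutant} subcohorts; unknowns
#'   are excluded from both.
#' @export
split_by_p53 <- function(cohort) {
  list(wild_type = cohort[cohort$p53_status == "wild_type", , drop = FALSE],
       mutant = cohort[cohort$p53_status == "mutant", , drop = FALSE])
}

#' Assign p53 mutation status from a somatic variant table
#'
#' Any sample carrying a TP53 variant whose classification is in the
#' non-silent list is called mutant; samples present in the cohort but absent
#' from the variant table are wild-type.
#'
#' @param cohort cohort data.frame with \code{sample_id}.
#' @param variants data.frame with \code{sample_id}, \code{gene},
#'   \code{classification}.
#' @param non_silent classifications that count as mutation.
#' @return the cohort with a filled \code{p53_status} column.
#' @export
assign_p53_status <- function(cohort, variants,
                              non_silent = c("missense", "nonsense",
                                             "frameshift", "splice_site",
                                             "inframe_indel")) {
  hit <- variants$gene == "TP53" & variants$classification %in% non_silent
  mutant_ids <- unique(variants$sample_id[hit])
  cohort$p53_status <- ifelse(cohort$sample_id %in% mutant_ids,
                              "mutant", "wild_type")
  cohort
}

#' Fisher's exact test for gene-set overlap
#'
#' Builds the 2x2 membership table of two sets over a background universe and
#' runs the two-sided exact test.
#'
#' @param set_a,set_b character vectors, subsets of \code{background}.
#' @param background character vector, the gene universe.
#' @return list with \code{odds_ratio} (sample odds ratio from the table),
#'   \code{p} (two-sided), \code{overlap}, and the \code{table}.
#' @export
overlap_fisher <- function(set_a, set_b, background) {
  if (length(background) == 0L) stop("empty background")
  stopifnot(all(set_a %in% background), all(set_b %in% background))
  a <- background %in% set_a
  b <- background %in% set_b
  tab <- table(in_a = factor(a, c(TRUE, FALSE)),
               in_b = factor(b, c(TRUE, FALSE)))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  or <- if (tab[1, 2] * tab[2, 1] == 0) Inf
        else (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  if (tab[1, 1] * tab[2, 2] == 0 && !is.finite(or)) or <- NaN
  list(odds_ratio = unname(or), p = ft$p.value,
       overlap = sum(a & b), table = tab)
}

#' Run the full gene-set survival stratification
#'
#' Scores every patient for a gene set, normalizes, forms tertiles, and fits
#' the Cox model; optionally repeats the analysis within p53 wild-type and
#' mutant subcohorts, re-deriving tertiles within each subcohort.
#'
#' @param expr genes x samples TPM matrix.
#' @param cohort cohort data.frame; \code{sample_id} must match matrix
#'   columns.
#' @param gene_set gene ids to score.
#' @param alpha ssGSEA rank-weight exponent.
#' @param by_p53 also analyze p53-status subcohorts (default TRUE when the
#'   status column is present).
#' @return list with \code{scores}, \code{groups}, \code{cox}, \code{km} and
#'   (optionally) \code{by_p53} sublists.
#' @export
survival_stratification <- function(expr, cohort, gene_set, alpha = 0.75,
                                    by_p53 = "p53_status" %in% names(cohort)) {
  expr <- expr[, cohort$sample_id, drop = FALSE]
  raw <- ssgsea_score(expr, gene_set, alpha)
  norm <- normalize_scores(raw)
  groups <- tertile_groups(norm)
  res <- list(scores = norm, groups = groups,
              cox = cox_fit(cohort, groups),
              km = km_estimate(cohort, groups))
  if (isTRUE(by_p53)) {
    sub <- split_by_p53(cohort)
    res$by_p53 <- lapply(sub, function(co) {
      if (nrow(co) < 6 || sum(co$event) == 0) {
        warning("subcohort too small or event-free; skipped")
        return(NULL)
      }
      e <- expr[, co$sample_id, drop = FALSE]
      nr <- normalize_scores(ssgsea_score(e, gene_set, alpha))
      g <- tertile_groups(nr)
      list(scores = nr, groups = g, cox = cox_fit(co, g),
           km = km_estimate(co, g))
    })
  }
  res
}
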