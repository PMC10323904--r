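# TPM-level perturbation-dependence tests. All contrasts are two-sided
# unpaired Student's t-tests with pooled variance on log2(TPM + 1) values
# (raw-scale mode available). A gene is p21-dependent when it is
# significantly repressed upon treatment in parental cells while the knockout
# fails to repress it (not significant, or repressing at less than half the
# parental log2 magnitude). The pocket-protein predominance call compares the
# repression pattern across a depletion series (parental, RB-depleted,
# p130/p107-depleted, triple-depleted). The same p21-dependence rule serves
# for mediator dependence (e.g. siControl vs siRFX7 knockdown series).

#' Two-sided unpaired Student's t-test (pooled variance)
#'
#' @param a,b numeric vectors with at least two values each.
#' @return list with \code{t}, \code{df}, \code{p} and a \code{degenerate}
#'   flag (zero pooled variance with unequal means).
#' @export
ttest_two_sided <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1,
                  degenerate = FALSE))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2L, p = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

# treated-vs-control contrast on one gene in one genotype arm.
# Returns the mean log2 change (treated - control), t, p.
contrast_repression <- function(treated, control, log_transform = TRUE) {
  if (log_transform) {
    treated <- log2(treated + 1)
    control <- log2(control + 1)
  }
  tt <- ttest_two_sided(treated, control)
  list(delta = mean(treated) - mean(control), t = tt$t, p = tt$p)
}

#' Assemble a TPM experiment from a matrix and sample sheet
#'
#' @param tpm numeric genes x samples matrix (TPM).
#' @param samples data.frame with columns \code{sample}, \code{genotype},
#'   \code{treatment} (and optionally \code{replicate}); \code{sample} must
#'   match the matrix column names.
#' @return list of class \code{tpm_experiment}.
#' @export
tpm_experiment <- function(tpm, samples) {
  stopifnot(all(samples$sample %in% colnames(tpm)))
  structure(list(tpm = tpm, samples = samples), class = "tpm_experiment")
}

# replicate TPM values for one gene / genotype / treatment
arm_values <- function(exp, gene_id, genotype, treatment) {
  sel <- exp$samples$genotype == genotype & exp$samples$treatment == treatment
  cols <- exp$samples$sample[sel]
  if (length(cols) == 0L) return(NULL)
  as.numeric(exp$tpm[gene_id, cols])
}

#' Classify p21 (or mediator) dependence of treatment-induced repression
#'
#' Condition (i): in the parental genotype, treated values are significantly
#' below control (\code{p < alpha}). Condition (ii): the knockout fails to
#' repress — its treated-vs-control contrast is not significant at
#' \code{alpha}, or its log2 repression magnitude is below
#' \code{failure_fraction} of the parental magnitude. A gene meeting (i) and
#' (ii) is \code{p21_dependent}; a gene failing (i) is
#' \code{not_p21_dependent} with a reason; missing arms make it
#' \code{untestable}.
#'
#' @param exp a \code{tpm_experiment} containing both genotypes.
#' @param gene_id gene to classify.
#' @param parental,knockout genotype labels.
#' @param treated,control treatment labels.
#' @param alpha significance level (default 0.05).
#' @param failure_fraction knockout-vs-parental repression ratio under which
#'   repression counts as failed (default 0.5).
#' @param log_transform test on log2(TPM + 1) (default) or raw TPM.
#' @return list with \code{call}, \code{reason} and the two contrast results.
#' @export
classify_p21_dependence <- function(exp, gene_id,
                                    parental = "parental",
                                    knockout = "p21_null",
                                    treated = "treated", control = "control",
                                    alpha = 0.05, failure_fraction = 0.5,
                                    log_transform = TRUE) {
  arms <- list(
    pt = arm_values(exp, gene_id, parental, treated),
    pc = arm_values(exp, gene_id, parental, control),
    kt = arm_values(exp, gene_id, knockout, treated),
    kc = arm_values(exp, gene_id, knockout, control)
  )
  if (any(vapply(arms, is.null, TRUE)) ||
      any(vapply(arms, length, 0L) < 2)) {
    return(list(call = "untestable", reason = "missing experimental arm",
                parental = NULL, knockout = NULL))
  }
  par <- contrast_repression(arms$pt, arms$pc, log_transform)
  ko <- contrast_repression(arms$kt, arms$kc, log_transform)
  if (!(par$delta < 0 && par$p < alpha)) {
    return(list(call = "not_p21_dependent",
                reason = "no significant repression in parental cells",
                parental = par, knockout = ko))
  }
  par_mag <- -par$delta
  ko_mag <- max(0, -ko$delta)
  failure <- (ko$p >= alpha) || (ko_mag < failure_fraction * par_mag)
  if (failure) {
    list(call = "p21_dependent", reason = "repression fails in knockout",
         parental = par, knockout = ko)
  } else {
    list(call = "not_p21_dependent",
         reason = "repression retained in knockout",
         parental = par, knockout = ko)
  }
}

#' Classify RB vs DREAM (p130/p107) predominance across a depletion series
#'
#' Requires significant repression (treated below control at \code{alpha}) in
#' the parental arm; genes below the detection floor or without parental
#' repression are \code{not_detected}. Among detected genes, repression must
#' be lost in the triple-depleted arm for any resolved call:
#' \code{RB_predominant} when repression is lost only in the RB-depleted arm,
#' \code{DREAM_predominant} when lost only in the p130/p107-depleted arm,
#' \code{cooperative} when retained in both single depletions, and
#' \code{unresolved} otherwise (including a triple arm that still represses).
#'
#' @param exp a \code{tpm_experiment} with genotypes \code{parental},
#'   \code{rb_depleted}, \code{p130p107_depleted}, \code{triple_depleted}.
#' @param gene_id gene to classify.
#' @param genotypes named character vector mapping the four roles to genotype
#'   labels in the sample sheet.
#' @param treated,control treatment labels.
#' @param alpha significance level (default 0.05).
#' @param detect_tpm detection floor: mean TPM in the parental control arm
#'   (default 1).
#' @param log_transform test on log2(TPM + 1) scale (default).
#' @return list with \code{call}, \code{reason} and per-genotype contrasts.
#' @export
classify_pocket_dependence <- function(exp, gene_id,
                                       genotypes = c(parental = "parental",
                                                     rb = "rb_depleted",
                                                     p130p107 = "p130p107_depleted",
                                                     triple = "triple_depleted"),
                                       treated = "treated", control = "control",
                                       alpha = 0.05, detect_tpm = 1,
                                       log_transform = TRUE) {
  res <- list()
  for (role in names(genotypes)) {
    tv <- arm_values(exp, gene_id, genotypes[[role]], treated)
    cv <- arm_values(exp, gene_id, genotypes[[role]], control)
    if (is.null(tv) || is.null(cv) || length(tv) < 2 || length(cv) < 2) {
      return(list(call = "unresolved",
                  reason = paste0("missing genotype arm: ", genotypes[[role]]),
                  contrasts = res))
    }
    res[[role]] <- contrast_repression(tv, cv, log_transform)
    res[[role]]$repressed <- res[[role]]$delta < 0 && res[[role]]$p < alpha
  }
  pc <- arm_values(exp, gene_id, genotypes[["parental"]], control)
  if (mean(pc) < detect_tpm) {
    return(list(call = "not_detected", reason = "below detection floor",
                contrasts = res))
  }
  if (!res$parental$repressed) {
    return(list(call = "not_detected",
                reason = "no significant repression in parental cells",
                contrasts = res))
  }
  if (res$triple$repressed) {
    return(list(call = "unresolved",
                reason = "triple depletion retains repression",
                contrasts = res))
  }
  rb_lost <- !res$rb$repressed
  dream_lost <- !res$p130p107$repressed
  call <- if (rb_lost && !dream_lost) "RB_predominant"
          else if (!rb_lost && dream_lost) "DREAM_predominant"
          else if (!rb_lost && !dream_lost) "cooperative"
          else "unresolved"
  reason <- switch(call,
    RB_predominant = "repression lost only upon RB depletion",
    DREAM_predominant = "repression lost only upon p130/p107 depletion",
    cooperative = "repression retained in both single depletions, lost in triple",
    unresolved = "repression lost in both single depletions")
  list(call = call, reason = reason, contrasts = res)
}

#' Run a dependence classification over many genes and export calls
#'
#' @param exp a \code{tpm_experiment}.
#' @param gene_ids genes to classify.
#' @param classifier \code{"p21"} or \code{"pocket"}.
#' @param ... passed to the classifier.
#' @return data.frame with one row per gene: call, reason, and (for p21) the
#'   parental/knockout delta and p.
#' @export
classify_dependence_table <- function(exp, gene_ids,
                                      classifier = c("p21", "pocket"), ...) {
  classifier <- match.arg(classifier)
  rows <- lapply(gene_ids, function(g) {
    r <- if (classifier == "p21") classify_p21_dependence(exp, g, ...)
         else classify_pocket_dependence(exp, g, ...)
    data.frame(gene_id = g, call = r$call, reason = r$reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
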