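# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's interval machinery: coverage is counted base by base.

# integer vector of length L: number of datasets covering each 0-based
# position (a dataset counts once however many overlapping peaks it has)
coverage_oracle <- function(peak_sets, L) {
  counts <- integer(L)
  for (df in peak_sets) {
    covered <- logical(L)
    for (i in seq_len(nrow(df))) {
      s <- max(0L, df$start[i]); e <- min(L, df$end[i])
      if (e > s) covered[(s + 1L):e] <- TRUE
    }
    counts <- counts + covered
  }
  counts
}

# 0-based positions (as 1..L indices) covered by an interval table
covered_positions <- function(df, L) {
  covered <- logical(L)
  for (i in seq_len(nrow(df))) {
    s <- max(0L, df$start[i]); e <- min(L, df$end[i])
    if (e > s) covered[(s + 1L):e] <- TRUE
  }
  which(covered)
}

# literal per-sample running-sum evaluation of the single-sample enrichment
# statistic, written independently of ssgsea_score()
ssgsea_oracle <- function(expr, gene_set, alpha) {
  vapply(seq_len(ncol(expr)), function(j) {
    x <- expr[, j]
    genes <- rownames(expr)
    ord <- order(x, decreasing = TRUE)
    r <- rank(x, ties.method = "average")
    es <- 0; pin <- 0; pout <- 0
    w_total <- 0
    for (g in ord) if (genes[g] %in% gene_set) w_total <- w_total + r[g]^alpha
    n_out <- sum(!(genes %in% gene_set))
    seen_out <- 0
    for (g in ord) {
      if (genes[g] %in% gene_set) {
        pin <- pin + r[g]^alpha / w_total
      } else {
        seen_out <- seen_out + 1
        pout <- seen_out / n_out
      }
      es <- es + (pin - pout)
    }
    es
  }, 0)
}

# exact two-sided permutation p-value for the Spearman statistic at small n
spearman_perm_oracle <- function(x, y) {
  n <- length(x)
  obs <- cor(x, y, method = "spearman")
  perms <- combinat_perms(n)
  rhos <- apply(perms, 1L, function(p) cor(x, y[p], method = "spearman"))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

combinat_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- combinat_perms(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

# exact permutation two-sided p for a difference in means over all splits
mean_perm_oracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pooled), na)
  obs <- abs(mean(a) - mean(b))
  diffs <- apply(idx, 2L, function(ii) {
    abs(mean(pooled[ii]) - mean(pooled[-ii]))
  })
  mean(diffs >= obs - 1e-12)
}

# random small peak compendium on one chromosome of length L
random_peak_sets <- function(n_datasets, L, max_peaks = 8) {
  lapply(seq_len(n_datasets), function(d) {
    n <- sample.int(max_peaks, 1L)
    s <- sample.int(L - 2L, n)
    w <- sample.int(max(2L, L %/% 10L), n)
    data.frame(chrom = "c", start = s, end = pmin(L, s + w))
  })
}

# small deterministic catalog builder; defaults one TSS per gene at the
# strand-appropriate span end
toy_catalog <- function(df) {
  if (is.null(df$name)) df$name <- df$gene_id
  if (is.null(df$biotype)) df$biotype <- "lncRNA"
  if (is.null(df$chrom)) df$chrom <- "c"
  if (is.null(df$tss)) {
    df$tss <- lapply(seq_len(nrow(df)), function(i) {
      as.integer(if (df$strand[i] == "-") df$end[i] - 1L else df$start[i])
    })
  }
  p53lncscape:::new_gene_catalog(df, annotation_tag = "toy")
}

# TPM experiment with explicit per-arm log2 means and tiny replicate spread,
# so contrast outcomes are forced
arm_tpm <- function(mu, spread = 0.05) 2^(mu + c(-spread, 0, spread)) - 1

make_knockout_exp <- function(par_ctrl, par_trt, ko_ctrl, ko_trt,
                              gene_id = "g1") {
  samples <- expand.grid(replicate = 1:3, treatment = c("control", "treated"),
                         genotype = c("parental", "p21_null"),
                         stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_%s_r%d", samples$genotype, samples$treatment,
                            samples$replicate)
  vals <- c(arm_tpm(par_ctrl), arm_tpm(par_trt), arm_tpm(ko_ctrl),
            arm_tpm(ko_trt))
  tpm <- matrix(vals, nrow = 1, dimnames = list(gene_id, samples$sample))
  tpm_experiment(tpm, samples)
}

make_pocket_exp <- function(mu_ctrl = 6, repressed = c(parental = TRUE,
                                                       rb = FALSE,
                                                       p130p107 = TRUE,
                                                       triple = FALSE),
                            effect = 2, gene_id = "g1") {
  genotypes <- c(parental = "parental", rb = "rb_depleted",
                 p130p107 = "p130p107_depleted", triple = "triple_depleted")
  samples <- expand.grid(replicate = 1:3, treatment = c("control", "treated"),
                         genotype = unname(genotypes),
                         stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_%s_r%d", samples$genotype, samples$treatment,
                            samples$replicate)
  vals <- numeric(0)
  for (role in names(genotypes)) {
    trt_mu <- if (repressed[[role]]) mu_ctrl - effect else mu_ctrl
    vals <- c(vals, arm_tpm(mu_ctrl), arm_tpm(trt_mu))
  }
  tpm <- matrix(vals, nrow = 1, dimnames = list(gene_id, samples$sample))
  tpm_experiment(tpm, samples)
}
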