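# generators: determinism, saturation limits, and statistical expectations

test_that("generators are pure functions of parameters and seed", {
  plant <- landscape_plant(n_genes = 50, n_up = 8, n_down = 4, n_direct = 3,
                           n_enhancer = 2, n_dream = 2, n_rb = 1,
                           n_dream_rb_overlap = 1, n_nested = 2, seed = 4)
  plant2 <- landscape_plant(n_genes = 50, n_up = 8, n_down = 4, n_direct = 3,
                            n_enhancer = 2, n_dream = 2, n_rb = 1,
                            n_dream_rb_overlap = 1, n_nested = 2, seed = 4)
  expect_identical(plant[names(plant) != "seed"], plant2[names(plant2) != "seed"])
  expect_identical(simulate_de_compendium(plant, n_datasets = 10, seed = 4),
                   simulate_de_compendium(plant, n_datasets = 10, seed = 4))
  sim1 <- simulate_tpm_experiment(c(a = "dependent", b = "null"), seed = 4)
  sim2 <- simulate_tpm_experiment(c(a = "dependent", b = "null"), seed = 4)
  expect_identical(sim1$experiment$tpm, sim2$experiment$tpm)
  expect_identical(simulate_cohort(n = 30, seed = 4)$cohort,
                   simulate_cohort(n = 30, seed = 4)$cohort)
})

test_that("planted subsets are mutually consistent", {
  plant <- landscape_plant(seed = 2)
  expect_true(all(plant$direct %in% plant$up))
  expect_true(all(plant$enhancer %in% plant$up))
  expect_length(intersect(plant$direct, plant$enhancer), 0)
  expect_true(all(plant$dream %in% plant$down))
  expect_true(all(plant$rb %in% plant$down))
  expect_true(all(plant$nested$lnc_id %in% c(plant$up, plant$down)))
})

test_that("full response without missingness saturates the score", {
  plant <- landscape_plant(n_genes = 60, n_up = 6, n_down = 3, n_direct = 2,
                           n_enhancer = 1, n_dream = 1, n_rb = 1,
                           n_dream_rb_overlap = 0, n_nested = 0, seed = 8)
  de <- simulate_de_compendium(plant, n_datasets = 44, response_prob = 1,
                               missing_prob = 0, seed = 8)
  sc <- compute_scores(de)
  expect_true(all(sc$score[sc$gene_id %in% plant$up] == 44))
  expect_true(all(sc$score[sc$gene_id %in% plant$down] == -44))
})

test_that("mean planted score matches its binomial expectation", {
  plant <- landscape_plant(n_genes = 300, n_up = 200, n_down = 0,
                           n_direct = 0, n_enhancer = 0, n_dream = 0,
                           n_rb = 0, n_dream_rb_overlap = 0, n_nested = 0,
                           seed = 10)
  p <- 12 / 44
  de <- simulate_de_compendium(plant, n_datasets = 44, response_prob = p,
                               missing_prob = 0, seed = 10)
  sc <- compute_scores(de)
  mean_score <- mean(sc$score[sc$gene_id %in% plant$up])
  expect_lt(abs(mean_score - 12), 2)
})

test_that("an undersized compendium is rejected", {
  plant <- landscape_plant(n_genes = 20, n_up = 2, n_down = 1, n_direct = 1,
                           n_enhancer = 0, n_dream = 1, n_rb = 0,
                           n_dream_rb_overlap = 0, n_nested = 0, seed = 1)
  expect_error(simulate_de_compendium(plant, n_datasets = 2), "min_expressed")
})

test_that("noiseless peak compendia recover the truth at k = n", {
  truth <- data.frame(chrom = "c", start = c(1000L, 5000L, 9000L),
                      end = c(1400L, 5400L, 9400L))
  peaks <- simulate_peak_compendium(truth, n_datasets = 5, detect_prob = 1,
                                    jitter_sd = 0, seed = 3)
  rs <- recurrent_sites(multi_intersect(peaks), k = 5)
  expect_equal(rs$start, truth$start)
  expect_equal(rs$end, truth$end)
})

test_that("recovery under partial detection matches the binomial tail", {
  set.seed(30)
  n_sites <- 500
  starts <- seq(1000L, by = 2000L, length.out = n_sites)
  truth <- data.frame(chrom = "c", start = starts, end = starts + 300L)
  peaks <- simulate_peak_compendium(truth, n_datasets = 9, detect_prob = 0.6,
                                    jitter_sd = 0, seed = 30)
  rs <- recurrent_sites(multi_intersect(peaks), k = 4)
  tgr <- p53lncscape:::bed0_to_granges(truth)
  rgr <- p53lncscape:::bed0_to_granges(rs)
  frac <- mean(IRanges::overlapsAny(tgr, rgr))
  want <- 1 - pbinom(3, 9, 0.6)       # P(X >= 4)
  expect_lt(abs(frac - want), 3 * sqrt(want * (1 - want) / n_sites) + 0.01)
})

test_that("rare decoys almost never become recurrent", {
  set.seed(33)
  n_decoys <- 300
  starts <- seq(1000L, by = 2000L, length.out = n_decoys)
  decoys <- data.frame(chrom = "c", start = starts, end = starts + 300L)
  empty_truth <- decoys[0, ]
  peaks <- simulate_peak_compendium(empty_truth, n_datasets = 9,
                                    decoy_sites = decoys, decoy_prob = 0.1,
                                    jitter_sd = 0, seed = 33)
  rs <- recurrent_sites(multi_intersect(peaks), k = 4)
  dgr <- p53lncscape:::bed0_to_granges(decoys)
  false_frac <- if (nrow(rs) == 0) 0 else
    mean(IRanges::overlapsAny(dgr, p53lncscape:::bed0_to_granges(rs)))
  expect_lt(false_frac, 0.02)
})

test_that("synthetic annotations plant exactly the stated nested pairs", {
  sim <- simulate_annotation(n_coding = 20, n_lnc = 20, n_nested = 7, seed = 5)
  lnc <- sim$catalog[sim$catalog$biotype == "lncRNA", ]
  pc <- sim$catalog[sim$catalog$biotype == "protein_coding", ]
  pairs <- find_nested(lnc, pc)
  expect_setequal(paste(pairs$lnc_id, pairs$host_id),
                  paste(sim$truth_pairs$lnc_id, sim$truth_pairs$host_id))
  # decoys: verify partial-overlap decoys really overlap partially (< 1)
  decoy_ids <- setdiff(lnc$gene_id, sim$truth_pairs$lnc_id)
  for (id in decoy_ids) {
    d <- lnc[lnc$gene_id == id, ]
    for (j in seq_len(nrow(pc))) {
      ov <- max(0, min(d$end, pc$end[j]) - max(d$start, pc$start[j]))
      frac <- ov / (d$end - d$start)
      same_strand <- d$strand == pc$strand[j]
      expect_false(frac >= 1 && same_strand, info = id)
    }
  }
})

test_that("a genome too small for clean placement errors out", {
  expect_error(simulate_annotation(n_coding = 50, genome_len = 1e4),
               "too small")
})

test_that("planted cohort hazards are recovered by the Cox model", {
  sim <- simulate_cohort(n = 600, hr_medium = 1.5, hr_high = 2, seed = 27)
  fit <- cox_fit(sim$cohort,
                 factor(sim$truth_group, levels = c("low", "medium", "high")))
  ci <- fit$hr[fit$hr$term == "grouphigh", ]
  expect_lt(ci$ci_low, 2)
  expect_gt(ci$ci_high, 2)
})
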