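# single-sample enrichment, tertile stratification, Cox PH, KM, Fisher overlap

test_that("the unweighted running sum matches the hand-computed toy example", {
  expr <- matrix(c(4, 3, 2, 1), ncol = 1,
                 dimnames = list(c("a", "b", "c", "d"), "s1"))
  es <- ssgsea_score(expr, "a", alpha = 0)
  expect_equal(unname(es), 1 + 2 / 3 + 1 / 3 + 0)
})

test_that("scores are invariant under strictly increasing transforms", {
  set.seed(3)
  expr <- matrix(rlnorm(200), nrow = 20,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  set <- c("g01", "g05", "g10")
  base <- ssgsea_score(expr, set)
  expect_equal(ssgsea_score(log1p(expr), set), base)
  expect_equal(ssgsea_score(expr^2, set), base)
})

test_that("the weighted score matches a literal-summation oracle to 1e-9", {
  set.seed(8)
  expr <- matrix(rlnorm(500), nrow = 50,
                 dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:10)))
  set <- sample(rownames(expr), 12)
  for (alpha in c(0, 0.75, 1)) {
    got <- ssgsea_score(expr, set, alpha)
    want <- ssgsea_oracle(expr, set, alpha)
    expect_equal(unname(got), want, tolerance = 1e-9)
  }
})

test_that("degenerate gene sets are rejected", {
  expr <- matrix(1:4, ncol = 1, dimnames = list(letters[1:4], "s"))
  expect_error(ssgsea_score(expr, c("x", "y")), "intersection")
  expect_error(ssgsea_score(expr, letters[1:4]), "complement")
})

test_that("normalization rescales by the cohort range", {
  expect_equal(unname(normalize_scores(c(a = 0, b = 5, c = 10))),
               c(0, 0.5, 1))
  expect_warning(z <- normalize_scores(c(a = 2, b = 2)), "constant")
  expect_equal(unname(z), c(0, 0))
  expect_warning(one <- normalize_scores(c(a = 3)), "single")
  expect_equal(unname(one), 3)
})

test_that("tertiles follow the remainder rule with deterministic ties", {
  g9 <- tertile_groups(setNames(1:9, sprintf("s%d", 1:9)))
  expect_equal(as.vector(table(g9)), c(3L, 3L, 3L))
  g10 <- tertile_groups(setNames(1:10, sprintf("s%02d", 1:10)))
  expect_equal(as.vector(table(g10)[c("low", "medium", "high")]),
               c(4L, 3L, 3L))
  # all-tied scores break by sample id, sizes per rule
  tied <- tertile_groups(setNames(rep(1, 10), sprintf("s%02d", 1:10)))
  expect_equal(as.vector(table(tied)[c("low", "medium", "high")]),
               c(4L, 3L, 3L))
  expect_equal(as.character(tied[c("s01", "s10")]), c("low", "high"))
  # group sizes never differ by more than one
  for (n in 3:12) {
    sz <- table(tertile_groups(setNames(seq_len(n), sprintf("x%02d", seq_len(n)))))
    expect_lte(max(sz) - min(sz), 1)
  }
  # affine shifts of the scores change nothing downstream
  sc <- setNames(rnorm(12), sprintf("s%02d", 1:12))
  expect_equal(tertile_groups(sc), tertile_groups(3 * sc + 10))
})

test_that("Kaplan-Meier estimates match product-limit hand calculations", {
  cohort <- data.frame(sample_id = c("a", "b"), time = c(1, 2),
                       event = c(1, 1), age = 60, sex = "female")
  groups <- factor(c("low", "low"), levels = c("low", "medium", "high"))
  km <- km_estimate(cohort, groups)
  expect_equal(km$steps$surv, c(0.5, 0))
  # no events -> flat at 1
  cohort2 <- transform(cohort, event = 0)
  km2 <- km_estimate(cohort2, groups)
  expect_true(all(km2$steps$surv == 1))
  # the horizon is cosmetic
  km3 <- km_estimate(cohort, groups, plot_horizon = 1)
  expect_equal(km3$steps, km$steps)
})

test_that("KM equals one minus the ECDF without censoring", {
  set.seed(12)
  t <- sort(sample(1:100, 20))
  cohort <- data.frame(sample_id = sprintf("s%02d", 1:20), time = t,
                       event = 1, age = 60, sex = "male")
  groups <- factor(rep("low", 20), levels = c("low", "medium", "high"))
  km <- km_estimate(cohort, groups)
  ecdf_surv <- 1 - ecdf(t)(km$steps$time)
  expect_equal(km$steps$surv, ecdf_surv)
})

test_that("Cox fit rejects event-free cohorts and recovers a planted hazard", {
  cohort <- data.frame(sample_id = c("a", "b", "c"), time = 1:3, event = 0,
                       age = 60, sex = "male")
  groups <- factor(c("low", "medium", "high"),
                   levels = c("low", "medium", "high"))
  expect_error(cox_fit(cohort, groups), "no events")

  sim <- simulate_cohort(n = 600, hr_medium = 1.5, hr_high = 2, seed = 2)
  fit <- cox_fit(sim$cohort, factor(sim$truth_group,
                                    levels = c("low", "medium", "high")))
  hr_high <- fit$hr$hr[fit$hr$term == "grouphigh"]
  expect_gt(hr_high, 1.4)
  expect_lt(hr_high, 2.8)
  expect_lt(fit$lr_p, 0.01)
})

test_that("p53-status splits partition the cohort and re-derive tertiles", {
  sim <- simulate_cohort(n = 90, p53_mutant_fraction = 0.4, seed = 6)
  sub <- split_by_p53(sim$cohort)
  expect_equal(nrow(sub$wild_type) + nrow(sub$mutant), nrow(sim$cohort))
  res <- survival_stratification(sim$expr, sim$cohort, sim$gene_set,
                                 by_p53 = TRUE)
  for (co in names(sub)) {
    g <- res$by_p53[[co]]$groups
    sz <- table(g)
    expect_equal(sum(sz), nrow(sub[[co]]))
    expect_lte(max(sz) - min(sz), 1)
  }
})

test_that("unknown p53 status is excluded from both subcohorts", {
  cohort <- data.frame(sample_id = sprintf("s%d", 1:10),
                       p53_status = c(rep("wild_type", 4), rep("mutant", 5),
                                      "unknown"))
  sub <- split_by_p53(cohort)
  expect_equal(nrow(sub$wild_type), 4)
  expect_equal(nrow(sub$mutant), 5)
})

test_that("variant tables assign p53 status by non-silent classification", {
  cohort <- data.frame(sample_id = c("s1", "s2", "s3"))
  variants <- data.frame(sample_id = c("s1", "s2", "s3"),
                         gene = c("TP53", "TP53", "KRAS"),
                         classification = c("missense", "silent", "missense"))
  got <- assign_p53_status(cohort, variants)
  expect_equal(got$p53_status, c("mutant", "wild_type", "wild_type"))
})

test_that("Fisher overlap matches hypergeometric enumeration", {
  bg <- sprintf("g%02d", 1:20)
  a <- bg[1:5]
  res <- overlap_fisher(a, a, bg)
  # enrichment tail for a complete 5/5 overlap is 1/C(20,5)
  expect_equal(stats::dhyper(5, 5, 15, 5), 1 / choose(20, 5))
  # two-sided enumeration oracle: sum of table probabilities <= observed
  probs <- stats::dhyper(0:5, 5, 15, 5)
  want <- sum(probs[probs <= probs[6] * (1 + 1e-7)])
  expect_equal(res$p, want, tolerance = 1e-12)
  expect_equal(res$overlap, 5)

  # no overlap with tiny sets in a large background: no enrichment signal
  bg2 <- sprintf("h%03d", 1:500)
  res2 <- overlap_fisher(bg2[1:3], bg2[4:6], bg2)
  expect_gte(res2$p, 0.9)
  # saturated table
  res3 <- overlap_fisher(bg, bg, bg)
  expect_equal(res3$p, 1)
  expect_error(overlap_fisher("a", "a", character(0)), "background")
})

test_that("group reconstruction from expression reaches planted accuracy", {
  sim <- simulate_cohort(n = 300, shift_sd = 1, seed = 14)
  raw <- ssgsea_score(sim$expr, sim$gene_set)
  groups <- tertile_groups(normalize_scores(raw))
  acc <- mean(as.character(groups) == sim$truth_group[names(groups)])
  expect_gte(acc, 0.8)
})
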