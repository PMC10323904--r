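# pooled t-test and perturbation-dependence classification rules

test_that("pooled t statistic matches the closed-form example", {
  got <- ttest_two_sided(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$t, -3.674, tolerance = 1e-3)
  expect_equal(got$df, 4)
  expect_equal(got$p, 0.0213, tolerance = 1e-2)
})

test_that("degenerate and identity cases are handled", {
  same <- ttest_two_sided(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  deg <- ttest_two_sided(c(2, 2), c(5, 5))
  expect_equal(deg$p, 0)
  expect_true(deg$degenerate)
})

test_that("the t statistic is translation invariant", {
  a <- c(1.2, 2.5, 3.1); b <- c(2.2, 4.0, 4.4)
  expect_equal(ttest_two_sided(a, b)$t, ttest_two_sided(a + 7, b + 7)$t)
})

test_that("t-test decisions agree with an exact permutation test under the null", {
  set.seed(31)
  agree <- 0
  n_draws <- 100
  for (i in seq_len(n_draws)) {
    a <- rnorm(5); b <- rnorm(5)
    t_dec <- ttest_two_sided(a, b)$p < 0.05
    p_dec <- mean_perm_oracle(a, b) < 0.05
    agree <- agree + (t_dec == p_dec)
  }
  expect_gte(agree / n_draws, 0.95)
})

test_that("p21 dependence follows the two-branch repression-failure rule", {
  # parental -2 log2 (significant), knockout +0.1 (ns) -> dependent
  dep <- classify_p21_dependence(make_knockout_exp(8, 6, 8, 8.1), "g1")
  expect_equal(dep$call, "p21_dependent")
  # parental not significantly repressed -> not dependent, with reason
  flat <- classify_p21_dependence(make_knockout_exp(8, 8.02, 8, 6), "g1")
  expect_equal(flat$call, "not_p21_dependent")
  expect_match(flat$reason, "parental")
  # knockout represses almost as strongly -> no failure
  both <- classify_p21_dependence(make_knockout_exp(8, 6, 8, 6.1), "g1")
  expect_equal(both$call, "not_p21_dependent")
  expect_match(both$reason, "retained")
  # knockout significant but below half the parental magnitude -> dependent
  half <- classify_p21_dependence(make_knockout_exp(8, 6, 8, 7.4), "g1")
  expect_equal(half$call, "p21_dependent")
  # induction instead of repression in parental -> not dependent
  induced <- classify_p21_dependence(make_knockout_exp(6, 8, 6, 6), "g1")
  expect_equal(induced$call, "not_p21_dependent")
})

test_that("missing arms make a gene untestable", {
  exp <- make_knockout_exp(8, 6, 8, 8)
  exp$samples <- exp$samples[exp$samples$genotype == "parental", ]
  got <- classify_p21_dependence(exp, "g1")
  expect_equal(got$call, "untestable")
})

test_that("pocket-protein predominance follows the exhaustive rule table", {
  # repressed pattern (parental, rb-depleted, p130/p107-depleted, triple)
  patterns <- expand.grid(parental = c(TRUE, FALSE), rb = c(TRUE, FALSE),
                          p130p107 = c(TRUE, FALSE), triple = c(TRUE, FALSE))
  rule_oracle <- function(p) {
    if (!p$parental) return("not_detected")
    if (p$triple) return("unresolved")
    if (!p$rb && p$p130p107) return("RB_predominant")
    if (p$rb && !p$p130p107) return("DREAM_predominant")
    if (p$rb && p$p130p107) return("cooperative")
    "unresolved"
  }
  for (i in seq_len(nrow(patterns))) {
    p <- patterns[i, ]
    exp <- make_pocket_exp(repressed = c(parental = p$parental, rb = p$rb,
                                         p130p107 = p$p130p107,
                                         triple = p$triple))
    got <- classify_pocket_dependence(exp, "g1")
    expect_equal(got$call, rule_oracle(p), info = paste(unlist(p), collapse = "/"))
  }
})

test_that("genes below the detection floor are not_detected", {
  exp <- make_pocket_exp(mu_ctrl = 0.5,
                         repressed = c(parental = TRUE, rb = FALSE,
                                       p130p107 = TRUE, triple = FALSE))
  got <- classify_pocket_dependence(exp, "g1", detect_tpm = 1)
  expect_equal(got$call, "not_detected")
  expect_match(got$reason, "floor")
})

test_that("planted p21-dependent genes are recovered with high sensitivity", {
  roles <- setNames(c(rep("dependent", 30), rep("independent", 15),
                      rep("null", 55)),
                    sprintf("T%03d", 1:100))
  sim <- simulate_tpm_experiment(roles, design = "knockout",
                                 n_replicates = 3, effect_log2 = 2,
                                 noise_sd = 0.2, seed = 17)
  calls <- classify_dependence_table(sim$experiment, names(roles), "p21")
  sens <- mean(calls$call[roles == "dependent"] == "p21_dependent")
  expect_gte(sens, 0.9)
  fp <- mean(calls$call[roles == "null"] == "p21_dependent")
  expect_lte(fp, 0.1)
})

test_that("null TPM effects keep the false-positive rate near alpha", {
  roles <- setNames(rep("null", 200), sprintf("N%03d", 1:200))
  sim <- simulate_tpm_experiment(roles, design = "knockout", effect_log2 = 0,
                                 seed = 23)
  calls <- classify_dependence_table(sim$experiment, names(roles), "p21")
  # being called dependent requires significant parental repression;
  # under the null that branch fires at most alpha of the time
  expect_lte(mean(calls$call == "p21_dependent"), 0.05 + 0.035)
})

test_that("planted pocket predominance classes are recovered", {
  roles <- setNames(c(rep("rb_predominant", 8), rep("dream_predominant", 8),
                      rep("cooperative", 8), rep("null", 16)),
                    sprintf("P%03d", 1:40))
  sim <- simulate_tpm_experiment(roles, design = "pocket", effect_log2 = 2,
                                 noise_sd = 0.2, seed = 19)
  calls <- classify_dependence_table(sim$experiment, names(roles), "pocket",
                                     detect_tpm = 0)
  for (cls in c("rb_predominant", "dream_predominant", "cooperative")) {
    want <- c(rb_predominant = "RB_predominant",
              dream_predominant = "DREAM_predominant",
              cooperative = "cooperative")[[cls]]
    expect_gte(mean(calls$call[roles == cls] == want), 0.7)
  }
  expect_gte(mean(calls$call[roles == "null"] == "not_detected"), 0.9)
})
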