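test_that("simulation is deterministic given the seed and schema-conformant", {
  a <- simulate_cohort(sim_config(), seed = 7)
  b <- simulate_cohort(sim_config(), seed = 7)
  expect_equal(as.data.frame(a$patients), as.data.frame(b$patients))
  expect_equal(as.data.frame(a$pdl1), as.data.frame(b$pdl1))
  expect_equal(a$truth, b$truth)
  expect_identical(nrow(cohort_violations(a$patients)), 0L)
  expect_identical(nrow(cohort_violations(a$pdl1)), 0L)
  expect_identical(nrow(a$truth), 31L)
  expect_identical(nrow(as.data.frame(a$patients)), 93L)
  c <- simulate_cohort(sim_config(), seed = 8)
  expect_false(identical(as.data.frame(a$patients), as.data.frame(c$patients)))
})

test_that("invalid configs name the offending fields", {
  expect_error(sim_config(p_exact = 1.5), "p_exact")
  expect_error(sim_config(til_probs = c(0.5, 0.5)), "til_probs")
  expect_error(sim_config(dfs_hazard = c(mpr = -1, non_mpr = 0.01)), "dfs_hazard")
  expect_error(sim_config(n_raters = 1), "n_raters")
})

test_that("a perfect confusion model propagates to perfect downstream agreement", {
  cfg <- sim_config(p_exact = 1, p_plasma_flip = 0)
  sim <- simulate_cohort(cfg, seed = 3)
  df <- as.data.frame(sim$patients)
  # every rater reproduces the latent grades exactly
  sc <- irhpc_score(df$til_grade, df$eos_grade, df$neut_grade, df$dense_plasma)
  truth_rep <- sim$truth$score_true[match(df$case_id, sim$truth$case_id)]
  expect_identical(sc, truth_rep)
  wide <- matrix(sc, ncol = 3, byrow = TRUE)
  expect_equal(opa(wide)$opa, 100)
})

test_that("forced slips never reproduce interior true grades", {
  set.seed(9)
  truth <- rep(1:2, 50)
  m <- simulate_raters(truth, p_exact = 0, n_raters = 3)
  expect_true(all(m != truth))
  expect_true(all(m >= 0 & m <= 3))
})

test_that("expected pairwise agreement closed forms", {
  expect_equal(expected_opa(binary_confusion(0)), 1)
  expect_equal(expected_opa(binary_confusion(0.5)), 0.5)
  expect_equal(expected_opa(binary_confusion(0.1)), 0.82)  # (1-q)^2 + q^2
  expect_equal(expected_opa(ordinal_confusion(1)), 1)
  # independent of the truth distribution for a symmetric flip
  expect_equal(expected_opa(binary_confusion(0.2), c(0.9, 0.1)),
               expected_opa(binary_confusion(0.2), c(0.3, 0.7)))
  expect_error(expected_opa(matrix(c(0.7, 0.5, 0.4, 0.5), 2, 2)), "sum to 1")
})

test_that("simulated binary raters hit the closed-form agreement at n = 10^4", {
  set.seed(123)
  q <- 0.1
  truth <- stats::rbinom(1e4, 1, 0.5)
  m <- simulate_binary_raters(truth, q, 2)
  agree <- mean(m[, 1] == m[, 2])
  expected <- expected_opa(binary_confusion(q))
  se <- sqrt(expected * (1 - expected) / 1e4)
  expect_lt(abs(agree - expected), 3 * se)
})

test_that("ordinal slip agreement matches its confusion-matrix expectation", {
  set.seed(77)
  p_true <- c(0.2, 0.3, 0.3, 0.2)
  truth <- sample(0:3, 1e4, TRUE, p_true)
  m <- simulate_raters(truth, p_exact = 0.8, n_raters = 2)
  agree <- mean(m[, 1] == m[, 2])
  expected <- expected_opa(ordinal_confusion(0.8), p_true)
  se <- sqrt(expected * (1 - expected) / 1e4)
  expect_lt(abs(agree - expected), 3 * se)
})

test_that("survival simulation: tiny hazard censors everyone; closed form holds", {
  d0 <- simulate_survival(rep("g", 100), c(g = 1e-9), censor_time = 45)
  expect_true(all(d0$event == 0))
  expect_true(all(d0$time == 45))
  set.seed(31)
  d <- simulate_survival(rep("g", 2000), c(g = 0.01), censor_time = 45)
  km <- km_fit(d$time, d$event)
  s_true <- exp(-0.01 * 24)
  se <- sqrt(s_true * (1 - s_true) / 2000)
  expect_lt(abs(rate_at(km, 24) - s_true), 3 * se)
  expect_error(simulate_survival("x", c(g = 0.1), 45), "hazard")
})

test_that("the configured score effect on MPR is re-estimable in direction", {
  cfg <- sim_config(n_patients = 1000)
  sim <- simulate_cohort(cfg, seed = 55)
  fit <- stats::glm(responder ~ score_true, family = stats::binomial(),
                    data = sim$truth)
  expect_gt(stats::coef(fit)["score_true"], 0)
  expect_lt(summary(fit)$coefficients["score_true", "Pr(>|z|)"], 0.01)
})

test_that("default cohort is study-shaped in its marginals", {
  # large-n check of the calibrated marginal rates
  sim <- simulate_cohort(sim_config(n_patients = 2000, n_pdl1 = 2000), seed = 17)
  expect_equal(mean(sim$truth$responder), 0.484, tolerance = 0.15)
  ev <- filter_pdl1_evaluable(sim$pdl1)$retained
  expect_equal(mean(ev$eos_both_compartments), 45 / 108, tolerance = 0.15)
  t50 <- eosinophil_pdl1_table(ev, 50)
  p_high_eos <- t50$table[1, 1] / sum(t50$table[1, ])
  p_high_other <- t50$table[2, 1] / sum(t50$table[2, ])
  expect_gt(p_high_eos, p_high_other)  # configured enrichment direction
})
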