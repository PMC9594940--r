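test_that("OPA from counts reproduces the 35-of-45 headline", {
  r <- opa_from_counts(35, 15, 3)
  expect_identical(r$n_pairs, 45L)
  expect_equal(round(r$opa, 1), 77.8)
  expect_true(r$ci_low < r$opa && r$opa < r$ci_high)
  expect_equal(opa_from_counts(45, 15, 3)$opa, 100)
  expect_equal(opa_from_counts(0, 15, 3)$opa, 0)
  expect_error(opa_from_counts(46, 15, 3), "impossible")
})

test_that("a 10-unanimous + 5-split design yields 35/45 pairs", {
  m <- rbind(matrix(1L, 6, 3), matrix(0L, 4, 3),
             matrix(c(1L, 1L, 0L), 5, 3, byrow = TRUE))
  r <- opa(m)
  expect_identical(r$n_pairs, 45L)
  expect_identical(r$n_concordant, 35L)
  expect_equal(round(r$opa, 1), 77.8)
})

test_that("OPA equals the brute-force pairwise loop on random matrices", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(3:20, 1)
    k <- sample(2:5, 1)
    m <- matrix(sample(0:2, n * k, replace = TRUE), n, k)
    if (i %% 3 == 0) m[sample(length(m), ceiling(length(m) / 6))] <- NA
    bf <- brute_force_opa(m)
    if (bf$n_pairs == 0) next
    r <- opa(m)
    expect_identical(r$n_pairs, bf$n_pairs)
    expect_identical(r$n_concordant, bf$n_concordant)
  }
})

test_that("identical raters give 100% agreement; no pairs is an error", {
  m <- matrix(rep(c(0, 1, 1, 0), 3), 4, 3)
  expect_equal(opa(m)$opa, 100)
  expect_error(opa(matrix(c(1, NA, NA, NA, 1, NA), 3, 2)), "no contributing")
})

test_that("Wilson and Clopper-Pearson intervals both cover the estimate", {
  w <- opa_from_counts(35, 15, 3, conf_method = "wilson")
  cp <- opa_from_counts(35, 15, 3, conf_method = "clopper-pearson")
  for (r in list(w, cp)) {
    expect_true(r$ci_low <= r$opa && r$opa <= r$ci_high)
    expect_true(r$ci_low >= 0 && r$ci_high <= 100)
  }
  # frozen Wilson values for 35/45 at 95%, computed from the closed form
  expect_equal(w$ci_low, 63.7307, tolerance = 1e-4)
  expect_equal(w$ci_high, 87.4553, tolerance = 1e-4)
})

test_that("Fleiss kappa matches the hand-worked 4-case table", {
  # ratings AAB / ABB / BBB / AAA; by hand: P_i = 1/3,1/3,1,1 so
  # P_bar = 2/3, pooled p = (1/2,1/2) so P_e = 1/2, kappa = 1/3
  m <- rbind(c("A", "A", "B"), c("A", "B", "B"),
             c("B", "B", "B"), c("A", "A", "A"))
  fk <- fleiss_kappa(m)
  expect_equal(fk$kappa, 1 / 3)
  expect_equal(fk$p_bar, 2 / 3)
  expect_equal(fk$p_e, 1 / 2)
  expect_identical(fk$label, "poor to fair")
})

test_that("kappa is 1 on unanimous multi-category matrices and invariant to relabelling", {
  m <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2), c(1, 1, 1))
  expect_equal(fleiss_kappa(m)$kappa, 1)
  set.seed(5)
  m2 <- matrix(sample(0:2, 60, replace = TRUE), 20, 3)
  relab <- matrix(c("x", "y", "z")[m2 + 1], 20, 3)
  expect_equal(fleiss_kappa(m2)$kappa, fleiss_kappa(relab)$kappa)
})

test_that("kappa is near zero for independent uniform ratings", {
  set.seed(99)
  m <- matrix(sample(0:3, 2000 * 3, replace = TRUE), 2000, 3)
  expect_lt(abs(fleiss_kappa(m)$kappa), 0.05)
})

test_that("single-category matrices leave kappa undefined, and unequal rows drop", {
  m <- matrix(1L, 5, 3)
  fk <- fleiss_kappa(m)
  expect_true(fk$undefined)
  expect_true(is.na(fk$kappa))
  m2 <- rbind(c(0, 1, 1), c(1, 1, NA), c(0, 0, 0))
  expect_warning(fk2 <- fleiss_kappa(m2), "dropped")
  expect_identical(fk2$n_cases, 2L)
})

test_that("kappa labels follow the printed bands with two-decimal rounding", {
  expect_identical(interpret_kappa(0.54), "moderate")
  expect_identical(interpret_kappa(0.40), "poor to fair")
  expect_identical(interpret_kappa(0.41), "moderate")
  expect_identical(interpret_kappa(0.60), "moderate")
  expect_identical(interpret_kappa(0.61), "substantial")
  expect_identical(interpret_kappa(0.80), "substantial")
  expect_identical(interpret_kappa(0.81), "almost perfect")
  expect_identical(interpret_kappa(1), "almost perfect")
  expect_identical(interpret_kappa(0.405), "moderate")  # gap closed by rounding
  expect_identical(interpret_kappa(-1), "poor to fair")
  expect_error(interpret_kappa(1.2), "must be in")
})
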