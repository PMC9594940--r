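test_that("the two %RVT formulas give 10% and 25% on the 10/60/30 bed", {
  expect_equal(percent_rvt(10, 60, 30), 10)
  expect_equal(percent_rvt(10, 60, 30, include_necrosis = FALSE), 25)
  expect_identical(as.character(classify_response(10)), "MPR")
  expect_identical(as.character(classify_response(25)), "pPR")
  # no residual tumour: 0% in either mode
  expect_equal(percent_rvt(0, 20, 80), 0)
  expect_equal(percent_rvt(0, 20, 80, include_necrosis = FALSE), 0)
})

test_that("degenerate tumour beds raise explicit errors", {
  expect_error(percent_rvt(0, 0, 0), "denominator")
  expect_error(percent_rvt(0, 20, 0, include_necrosis = FALSE),
               "without-necrosis")
  expect_error(percent_rvt(-1, 10, 10), "non-negative")
  expect_error(percent_rvt(NA, 10, 10), "missing")
})

test_that("response classes partition [0,100] with the stated boundaries", {
  expect_identical(as.character(classify_response(0)), "cPR")
  expect_identical(as.character(classify_response(1e-9)), "MPR")
  expect_identical(as.character(classify_response(10)), "MPR")
  expect_identical(as.character(classify_response(10 + 1e-9)), "pPR")
  expect_identical(as.character(classify_response(90)), "pPR")
  expect_identical(as.character(classify_response(90.1)), "nPR")
  expect_identical(as.character(classify_response(95)), "nPR")
  expect_identical(as.character(classify_response(100)), "nPR")
  grid <- seq(0, 100, by = 0.25)
  cls <- classify_response(grid)
  expect_false(anyNA(cls))          # every value classified
  expect_error(classify_response(101), "must be in")
  expect_error(classify_response(-0.1), "must be in")
})

test_that("dropping necrosis never lowers %RVT, with equality iff necrosis = 0", {
  set.seed(42)
  for (i in 1:200) {
    a <- stats::runif(3, 0, 50)
    if (i %% 4 == 0) a[2] <- 0
    if (a[1] + a[3] == 0) a[1] <- 1
    w <- percent_rvt(a[1], a[2], a[3])
    wo <- percent_rvt(a[1], a[2], a[3], include_necrosis = FALSE)
    expect_gte(wo, w)
    if (a[2] == 0 || a[1] == 0) expect_equal(wo, w) else expect_gt(wo, w)
  }
})

test_that("MPR pools cPR and MPR", {
  expect_identical(mpr_achieved(c("cPR", "MPR", "pPR", "nPR")),
                   c(TRUE, TRUE, FALSE, FALSE))
  expect_error(mpr_achieved("CR"), "unknown response")
})

test_that("cross-rater mean is permutation invariant and flags thin input", {
  expect_equal(mean_rvt_across_raters(c(10, 10, 10)), 10)
  expect_equal(mean_rvt_across_raters(c(5, 10, 15)), 10)
  set.seed(7)
  x <- stats::runif(5, 0, 100)
  expect_equal(mean_rvt_across_raters(x), mean_rvt_across_raters(sample(x)))
  expect_warning(expect_warning(mean_rvt_across_raters(c(25, NA)),
                                "missing"), "single rater")
  expect_equal(suppressWarnings(mean_rvt_across_raters(c(25, NA))), 25)
  expect_warning(mean_rvt_across_raters(25), "single rater")
  expect_error(mean_rvt_across_raters(c(NA_real_, NA_real_)), "all rater")
})

test_that("necrosis sensitivity flags exactly the patient-14-style change", {
  ex <- example_cohort()
  ns <- necrosis_sensitivity(ex$patients)
  expect_identical(ns$n_changed, 1L)
  expect_identical(ns$changed_cases, "C14")
  row14 <- ns$table[ns$table$case_id == "C14", ]
  expect_equal(row14$rvt_with, 10)
  expect_equal(row14$rvt_without, 25)
  expect_identical(row14$class_with, "MPR")
  expect_identical(row14$class_without, "pPR")
  # 17 cases with necrosis and residual tumour give 17 positive differences
  expect_identical(sum(ns$table$difference > 0), 17L)
  expect_identical(ns$wilcoxon$n_nonzero, 17L)
})

test_that("necrosis sensitivity degenerates cleanly when no bed has necrosis", {
  ex <- example_cohort()
  df <- as.data.frame(ex$patients)
  df$regression_area <- df$regression_area + df$necrosis_area
  df$necrosis_area <- 0
  ns <- necrosis_sensitivity(df)
  expect_identical(ns$n_changed, 0L)
  expect_null(ns$wilcoxon)
  expect_true(all(ns$table$difference == 0))
})
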