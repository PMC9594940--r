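# Synthetic neoadjuvant cohorts.
#
# The generator emulates the statistical structure of the study cohort so
# every analysis stage can be exercised without patient data: latent biopsy
# feature grades drive a latent irHPC score; a logistic link maps the score
# to the probability of achieving MPR; responder status determines the %RVT
# mixture (a point mass at 0 for cPR, a low band for MPR, a high band
# otherwise) and the survival hazards; raters observe the grades through a
# symmetric +/-1 slip model; blood counts tie the neutrophil fraction to the
# neutrophil grade so the dNLR carries signal; and an eosinophil-compartment
# flag shifts the PD-L1 TPS category distribution.  Defaults reproduce the
# study's marginal counts in expectation (about 48% MPR of n = 31 with 6
# cPR, roughly a third of patients with dNLR > 3, 45/108 eosinophil-both
# with TPS >= 50% enriched).

#' Simulation configuration
#'
#' Builds and validates the parameter set for [simulate_cohort()].  All
#' probabilities must lie in \[0,1\] (grade distributions are normalised),
#' hazards are per month and must be positive.
#'
#' @param n_patients Number of neoadjuvant patients (default 31).
#' @param n_raters Number of pathologists reading each biopsy/resection
#'   (default 3).
#' @param n_pdl1 Number of cases in the PD-L1 series (default 109).
#' @param til_probs,eos_probs,neut_probs Probabilities of true grades
#'   0..3 for TILs, eosinophils and neutrophils.
#' @param plasma_prev Prevalence of dense plasma cells.
#' @param p_exact Probability a rater reproduces the true ordinal grade;
#'   the remainder splits equally into +/-1 slips, clipped to \[0,3\].
#' @param p_plasma_flip Probability a rater flips the plasma flag.
#' @param mpr_intercept,mpr_slope Logistic link from the true irHPC score
#'   to the probability of achieving MPR.
#' @param p_cpr_given_mpr Probability an MPR-achieving patient is cPR.
#' @param rvt_mpr_range,rvt_nonmpr_range Uniform %RVT bands for MPR (with
#'   residual tumour) and non-MPR cases.
#' @param p_necrosis,p_necrosis_cpr Probability a (non-cPR / cPR) tumour
#'   bed contains necrosis.
#' @param necrosis_frac_range Uniform range for the necrosis fraction of
#'   the non-viable tumour bed, when present.
#' @param rvt_rater_sd Between-rater SD of the observed %RVT (percentage
#'   points).
#' @param leuko_mean,leuko_sd Pretreatment leukocyte count distribution
#'   (10^9/L).
#' @param neut_frac_base,neut_frac_slope,neut_frac_sd Neutrophil fraction
#'   of leukocytes: `base + slope * neut_grade + Normal(0, sd)`, clipped to
#'   (0.05, 0.95).
#' @param dfs_hazard,os_hazard Named exponential hazards per month,
#'   `c(mpr = ..., non_mpr = ...)`.
#' @param censor_time Administrative censoring horizon (months).
#' @param p_death_unrelated Probability of a death unrelated to treatment
#'   (those patients get `os_event = 1`, `death_unrelated = 1`).
#' @param eos_both_prob Probability eosinophils appear in both parenchyma
#'   and stroma (PD-L1 series).
#' @param tps_probs_eos_both,tps_probs_other Probabilities of the TPS
#'   categories (negative, positive-low, high) given the eosinophil flag.
#' @param p_insufficient Probability a PD-L1 slide has fewer than 100
#'   viable tumour cells.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 31,
                       n_raters = 3,
                       n_pdl1 = 109,
                       til_probs = c(0.20, 0.30, 0.30, 0.20),
                       eos_probs = c(0.40, 0.30, 0.20, 0.10),
                       neut_probs = c(0.50, 0.30, 0.15, 0.05),
                       plasma_prev = 0.40,
                       p_exact = 0.80,
                       p_plasma_flip = 0.10,
                       mpr_intercept = -2.4,
                       mpr_slope = 1.1,
                       p_cpr_given_mpr = 0.40,
                       rvt_mpr_range = c(1, 10),
                       rvt_nonmpr_range = c(11, 100),
                       p_necrosis = 0.60,
                       p_necrosis_cpr = 1 / 6,
                       necrosis_frac_range = c(0.05, 0.30),
                       rvt_rater_sd = 2,
                       leuko_mean = 7,
                       leuko_sd = 1.2,
                       neut_frac_base = 0.66,
                       neut_frac_slope = 0.05,
                       neut_frac_sd = 0.08,
                       dfs_hazard = c(mpr = 0.004, non_mpr = 0.012),
                       os_hazard = c(mpr = 0.001, non_mpr = 0.003),
                       censor_time = 45,
                       p_death_unrelated = 2 / 31,
                       eos_both_prob = 45 / 108,
                       tps_probs_eos_both = c(0.400, 0.333, 0.267),
                       tps_probs_other = c(0.492, 0.445, 0.063),
                       p_insufficient = 1 / 109) {
  cfg <- as.list(environment())
  problems <- character()
  chk_probs <- function(p, nm, len) {
    if (length(p) != len || anyNA(p) || any(p < 0) || sum(p) <= 0)
      problems <<- c(problems, sprintf("%s must be %d non-negative probabilities", nm, len))
  }
  chk_probs(cfg$til_probs, "til_probs", 4)
  chk_probs(cfg$eos_probs, "eos_probs", 4)
  chk_probs(cfg$neut_probs, "neut_probs", 4)
  chk_probs(cfg$tps_probs_eos_both, "tps_probs_eos_both", 3)
  chk_probs(cfg$tps_probs_other, "tps_probs_other", 3)
  for (nm in c("plasma_prev", "p_exact", "p_plasma_flip", "p_cpr_given_mpr",
               "p_necrosis", "p_necrosis_cpr", "p_death_unrelated",
               "eos_both_prob", "p_insufficient"))
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 ||
        is.na(cfg[[nm]]) || cfg[[nm]] < 0 || cfg[[nm]] > 1)
      problems <- c(problems, sprintf("%s must be a probability in [0,1]", nm))
  for (nm in c("dfs_hazard", "os_hazard"))
    if (length(cfg[[nm]]) != 2 || anyNA(cfg[[nm]]) || any(cfg[[nm]] <= 0) ||
        !setequal(names(cfg[[nm]]), c("mpr", "non_mpr")))
      problems <- c(problems, sprintf("%s must be positive and named (mpr, non_mpr)", nm))
  if (cfg$n_patients < 1) problems <- c(problems, "n_patients must be >= 1")
  if (cfg$n_raters < 2) problems <- c(problems, "n_raters must be >= 2")
  if (cfg$censor_time <= 0) problems <- c(problems, "censor_time must be positive")
  if (length(problems))
    stop("invalid simulation config:\n  ", paste(problems, collapse = "\n  "))
  cfg$til_probs <- cfg$til_probs / sum(cfg$til_probs)
  cfg$eos_probs <- cfg$eos_probs / sum(cfg$eos_probs)
  cfg$neut_probs <- cfg$neut_probs / sum(cfg$neut_probs)
  cfg$tps_probs_eos_both <- cfg$tps_probs_eos_both / sum(cfg$tps_probs_eos_both)
  cfg$tps_probs_other <- cfg$tps_probs_other / sum(cfg$tps_probs_other)
  structure(cfg, class = "sim_config")
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Per-rater ordinal grades under the +/-1 slip model
#'
#' Each rater independently reproduces the true grade with probability
#' `p_exact`; otherwise the grade slips one level up or down with equal
#' probability, clipped to the grade range (so a slip off the boundary
#' stays at the boundary).
#'
#' @param true_grades Integer vector of true grades.
#' @param p_exact Probability of reproducing the true grade.
#' @param n_raters Number of raters.
#' @param levels Grade range (default `0:3`).
#' @return Integer matrix, cases x raters.
#' @export
simulate_raters <- function(true_grades, p_exact, n_raters, levels = 0:3) {
  n <- length(true_grades)
  lo <- min(levels); hi <- max(levels)
  out <- matrix(0L, n, n_raters)
  for (r in seq_len(n_raters)) {
    slip <- stats::runif(n) >= p_exact
    dir <- sample(c(-1L, 1L), n, replace = TRUE)
    out[, r] <- as.integer(clip(true_grades + slip * dir, lo, hi))
  }
  out
}

#' Per-rater binary calls under a flip model
#'
#' Each rater independently flips the true binary value with probability
#' `q`.
#'
#' @param truth Binary vector (0/1).
#' @param q Flip probability.
#' @param n_raters Number of raters.
#' @return Integer matrix, cases x raters.
#' @export
simulate_binary_raters <- function(truth, q, n_raters) {
  n <- length(truth)
  flips <- matrix(stats::rbinom(n * n_raters, 1, q), n, n_raters)
  (matrix(as.integer(truth), n, n_raters) + flips) %% 2L
}

#' Confusion matrix of the ordinal slip model
#'
#' Row `t`, column `c` holds the probability a rater reports grade `c`
#' when the truth is `t`; boundary slips are clipped back onto the
#' boundary.
#'
#' @inheritParams simulate_raters
#' @return Row-stochastic matrix over `levels`.
#' @export
ordinal_confusion <- function(p_exact, levels = 0:3) {
  k <- length(levels)
  slip <- (1 - p_exact) / 2
  m <- matrix(0, k, k, dimnames = list(levels, levels))
  for (i in seq_len(k)) {
    m[i, i] <- p_exact
    m[i, max(i - 1, 1)] <- m[i, max(i - 1, 1)] + slip
    m[i, min(i + 1, k)] <- m[i, min(i + 1, k)] + slip
  }
  m
}

#' Confusion matrix of the binary flip model
#' @param q Flip probability.
#' @return 2x2 row-stochastic matrix over `0:1`.
#' @export
binary_confusion <- function(q) {
  matrix(c(1 - q, q, q, 1 - q), 2, 2, byrow = TRUE,
         dimnames = list(0:1, 0:1))
}

#' Expected pairwise agreement of two independent noisy raters
#'
#' Exact expectation of the probability that two raters sharing the same
#' confusion model agree on a case:
#' `sum_t P(t) sum_c P(c|t)^2`.  For the symmetric binary flip with
#' probability `q` this reduces to `(1-q)^2 + q^2` regardless of the truth
#' distribution.
#'
#' @param confusion Row-stochastic confusion matrix (rows = true category).
#' @param true_probs Distribution of the true category (default uniform).
#' @return Expected agreement probability.
#' @export
expected_opa <- function(confusion, true_probs = NULL) {
  m <- as.matrix(confusion)
  if (any(abs(rowSums(m) - 1) > 1e-8)) stop("confusion rows must sum to 1")
  if (is.null(true_probs)) true_probs <- rep(1 / nrow(m), nrow(m))
  if (length(true_probs) != nrow(m) || any(true_probs < 0))
    stop("true_probs must be a distribution over the true categories")
  true_probs <- true_probs / sum(true_probs)
  sum(true_probs * rowSums(m^2))
}

#' Exponential survival times with administrative censoring
#'
#' @param group Character/factor group per subject, matching `names(hazards)`.
#' @param hazards Named positive hazards per month.
#' @param censor_time Administrative censoring horizon (months).
#' @return Data frame with `time` and `event`.
#' @export
simulate_survival <- function(group, hazards, censor_time) {
  group <- as.character(group)
  if (!all(group %in% names(hazards)))
    stop("every group must have a hazard")
  rate <- unname(hazards[group])
  t_event <- ifelse(rate > 0, stats::rexp(length(rate), pmax(rate, 1e-300)), Inf)
  data.frame(time = pmin(t_event, censor_time),
             event = as.integer(t_event <= censor_time))
}

#' Simulate a full study cohort
#'
#' Draws a complete synthetic cohort under `config` (see [sim_config()]):
#' a patients table (one row per case and rater, the `patients.csv`
#' schema), a PD-L1 table (`pdl1.csv` schema) and a truth table of the
#' latent quantities.  Output is deterministic given `seed`.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @return List with `patients`, `pdl1` (both `irhpc_cohort` tables) and
#'   `truth` (data frame of latent grades, true score, responder status,
#'   true response class and %RVT).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cf <- config
  n <- cf$n_patients

  # latent biopsy features and score
  til <- sample(0:3, n, TRUE, cf$til_probs)
  eos <- sample(0:3, n, TRUE, cf$eos_probs)
  neut <- sample(0:3, n, TRUE, cf$neut_probs)
  plasma <- stats::rbinom(n, 1, cf$plasma_prev)
  score <- irhpc_score(til, eos, neut, plasma)

  # response: logistic link score -> MPR, cPR subset among responders
  p_resp <- stats::plogis(cf$mpr_intercept + cf$mpr_slope * score)
  responder <- stats::rbinom(n, 1, p_resp) == 1
  cpr <- responder & stats::rbinom(n, 1, cf$p_cpr_given_mpr) == 1

  # true %RVT and tumour-bed composition (total bed area 100)
  rvt_true <- numeric(n)
  rvt_true[responder & !cpr] <- stats::runif(sum(responder & !cpr),
                                             cf$rvt_mpr_range[1], cf$rvt_mpr_range[2])
  rvt_true[!responder] <- stats::runif(sum(!responder),
                                       cf$rvt_nonmpr_range[1], cf$rvt_nonmpr_range[2])
  p_nec <- ifelse(cpr, cf$p_necrosis_cpr, cf$p_necrosis)
  has_nec <- stats::rbinom(n, 1, p_nec) == 1
  nec_frac <- ifelse(has_nec,
                     stats::runif(n, cf$necrosis_frac_range[1], cf$necrosis_frac_range[2]),
                     0)
  class_true <- as.character(classify_response(rvt_true))

  # immune-activated %RVT of the residual tumour (cPR has no RVT)
  ia_true <- rep(NA_real_, n)
  is_mpr_res <- responder & !cpr
  ia_true[is_mpr_res] <- ifelse(stats::runif(sum(is_mpr_res)) < 8 / 9, 100, 80)
  ia_true[!responder] <- stats::runif(sum(!responder), 20, 90)

  # blood counts: neutrophil fraction tied to the neutrophil grade
  leuko <- clip(stats::rnorm(n, cf$leuko_mean, cf$leuko_sd), 3, 15)
  frac <- clip(cf$neut_frac_base + cf$neut_frac_slope * neut +
                 stats::rnorm(n, 0, cf$neut_frac_sd), 0.05, 0.95)
  neut_count <- round(frac * leuko, 2)
  leuko <- round(leuko, 2)

  # survival
  grp <- ifelse(responder, "mpr", "non_mpr")
  dfs <- simulate_survival(grp, cf$dfs_hazard, cf$censor_time)
  os <- simulate_survival(grp, cf$os_hazard, cf$censor_time)
  unrel <- stats::rbinom(n, 1, cf$p_death_unrelated)
  os$event[unrel == 1] <- 1L

  case_id <- sprintf("C%02d", seq_len(n))
  truth <- data.frame(case_id = case_id,
                      til = til, eos = eos, neut = neut, plasma = plasma,
                      score_true = score, responder = responder, cpr = cpr,
                      response_class_true = class_true,
                      rvt_pct_true = rvt_true,
                      necrosis_frac = nec_frac,
                      stringsAsFactors = FALSE)

  # per-rater observations
  r <- cf$n_raters
  til_m <- simulate_raters(til, cf$p_exact, r)
  eos_m <- simulate_raters(eos, cf$p_exact, r)
  neut_m <- simulate_raters(neut, cf$p_exact, r)
  plasma_m <- simulate_binary_raters(plasma, cf$p_plasma_flip, r)
  rows <- vector("list", n * r)
  for (i in seq_len(n)) {
    for (j in seq_len(r)) {
      rvt_obs <- if (cpr[i]) 0 else
        clip(rvt_true[i] + stats::rnorm(1, 0, cf$rvt_rater_sd), 0.5, 100)
      rest <- 100 - rvt_obs
      nec_area <- rest * nec_frac[i]
      ia_obs <- if (is.na(ia_true[i])) NA_real_ else
        clip(ia_true[i] + stats::rnorm(1, 0, 5), 0, 100)
      rows[[(i - 1) * r + j]] <- data.frame(
        case_id = case_id[i], rater_id = sprintf("R%d", j),
        til_grade = til_m[i, j], eos_grade = eos_m[i, j],
        neut_grade = neut_m[i, j], dense_plasma = plasma_m[i, j],
        rvt_area = round(rvt_obs, 2),
        necrosis_area = round(nec_area, 2),
        regression_area = round(rest - nec_area, 2),
        immune_activated_rvt_pct = round(ia_obs, 1),
        neutrophil_count = neut_count[i], leukocyte_count = leuko[i],
        dfs_months = round(dfs$time[i], 2), dfs_event = dfs$event[i],
        os_months = round(os$time[i], 2), os_event = os$event[i],
        death_unrelated = unrel[i],
        stringsAsFactors = FALSE)
    }
  }
  patients <- do.call(rbind, rows)

  # PD-L1 series
  np <- cf$n_pdl1
  eos_both <- stats::rbinom(np, 1, cf$eos_both_prob)
  cat_draw <- function(p) sample(c("negative", "positive_low", "high"), 1, prob = p)
  tps_cat <- vapply(eos_both, function(e)
    cat_draw(if (e == 1) cf$tps_probs_eos_both else cf$tps_probs_other),
    character(1))
  tps <- vapply(tps_cat, function(cc) switch(cc,
    negative = stats::runif(1, 0, 0.99),
    positive_low = stats::runif(1, 1, 49.9),
    high = stats::runif(1, 50, 100)), numeric(1))
  insufficient <- stats::rbinom(np, 1, cf$p_insufficient) == 1
  cells <- ifelse(insufficient,
                  sample(10:99, np, replace = TRUE),
                  sample(150:5000, np, replace = TRUE))
  pdl1 <- data.frame(case_id = sprintf("P%03d", seq_len(np)),
                     viable_tumour_cells = as.integer(cells),
                     tps_percent = round(tps, 1),
                     eos_both_compartments = eos_both,
                     stringsAsFactors = FALSE)

  list(patients = as_cohort(patients, "patients"),
       pdl1 = as_cohort(pdl1, "pdl1"),
       truth = truth)
}
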