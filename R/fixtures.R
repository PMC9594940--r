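# A deterministic, fully synthetic example cohort whose marginal counts
# mirror the published study: 31 neoadjuvant patients (6 cPR, 9 MPR, 13
# pPR, 3 nPR, so 15/31 = 48.4% achieve MPR), 15 of them with paired
# pretreatment biopsies read by 3 pathologists (10 unanimous and 5
# two-against-one rows at the 2-point cutoff, hence 35/45 concordant
# pairs, OPA 77.8%), reference scores splitting 7/8 at-or-above cutoff in
# the cPR/MPR group and 7/7 below in the pPR/nPR group, 17 cases whose
# %RVT rises when necrosis is dropped from the denominator (including the
# patient-14 reconstruction with areas 10/60/30), 10 cases with dNLR > 3,
# and a 109-case PD-L1 series with one insufficient slide and
# eosinophil-by-TPS tables [[12,33],[4,59]] at 50% and [[27,18],[32,31]]
# at 1%.  No real patient data enter this construction.

# map an irHPC score back onto a plausible grade combination
score_to_grades <- function(s) {
  if (s < 0) c(til = 0L, eos = 0L, neut = -s, plasma = 0L)
  else if (s <= 3) c(til = s, eos = 0L, neut = 0L, plasma = 0L)
  else if (s <= 6) c(til = 3L, eos = s - 3L, neut = 0L, plasma = 0L)
  else c(til = 3L, eos = 3L, neut = 0L, plasma = 1L)
}

#' Synthetic study-shaped example cohort
#'
#' Returns a deterministic synthetic cohort reproducing the study's printed
#' marginal counts (see the source comment for the full inventory), suitable
#' for worked examples and end-to-end tests.  Entirely synthetic: the
#' per-patient values are constructed, not measured.
#'
#' @return List with `patients` (93 rows: 31 cases x 3 raters), `pdl1`
#'   (109 rows), and `ref_scores` (reference irHPC score and achieved
#'   response class for the 15 biopsy cases).
#' @examples
#' ex <- example_cohort()
#' table(classify_response(tapply(
#'   percent_rvt(ex$patients$rvt_area, ex$patients$necrosis_area,
#'               ex$patients$regression_area),
#'   ex$patients$case_id, mean)))
#' @export
example_cohort <- function() {
  case_id <- sprintf("C%02d", 1:31)

  # tumour-bed composition per case (total bed area 100)
  rvt <- c(rep(0, 6),                                   # cPR
           2, 3, 4, 5, 6, 7, 8, 10, 9,                  # MPR (case 14 special)
           20, 25, 30, 35, 40, 45, 50, 55,              # pPR with necrosis
           60, 65, 70, 75, 80,                          # pPR without necrosis
           92, 95, 99)                                  # nPR
  nec <- c(10, rep(0, 5),
           10, 12, 14, 16, 18, 20, 10, 60, 5,
           rep(10, 8),
           rep(0, 5),
           rep(0, 3))
  reg <- 100 - rvt - nec
  reg[14] <- 30; nec[14] <- 60; rvt[14] <- 10   # patient 14: (10, 60, 30)

  # biopsy cases and their per-rater irHPC scores (binarised at 2:
  # 10 unanimous rows + 5 split rows -> 35/45 concordant pairs)
  biopsy_cases <- c(1:8, 16:22)
  rater_scores <- rbind(
    c(2, 2, 2), c(3, 3, 3), c(4, 4, 4), c(5, 5, 5), c(2, 2, 1),
    c(3, 2, 0), c(0, 0, 0), c(2, 2, 2),
    c(-2, -2, -2), c(-1, -1, -1), c(0, 0, 2), c(0, 1, 1), c(1, 1, 2),
    c(1, 2, 2), c(1, 1, 1))
  ref_score <- c(2, 3, 4, 5, 2, 3, 0, 2, -2, -1, 0, 0, 1, 1, 1)

  grades <- array(NA_integer_, dim = c(31, 3, 4),
                  dimnames = list(NULL, NULL, c("til", "eos", "neut", "plasma")))
  for (b in seq_along(biopsy_cases)) {
    i <- biopsy_cases[b]
    for (j in 1:3) grades[i, j, ] <- score_to_grades(rater_scores[b, j])
  }

  # blood counts: dNLR 4.0 for the 10 high cases, 1.0 otherwise
  high_dnlr <- c(2, 7, 15, 16, 17, 24, 25, 26, 29, 30)
  neut_count <- ifelse(1:31 %in% high_dnlr, 6.4, 4.0)
  leuko <- rep(8.0, 31)

  # immune-activated %RVT of the residual tumour (absent for cPR)
  ia <- rep(NA_real_, 31)
  ia[7:15] <- 100; ia[13] <- 80
  ia[16:31] <- 20 + (16:31 - 16) * 4

  # survival: 7 relapses, 4 deaths of which 2 unrelated to treatment
  dfs_event <- as.integer(1:31 %in% c(13, 16, 17, 24, 25, 29, 30))
  dfs_months <- c(40, 38, 42, 36, 39, 41, 37, 35, 43, 44, 34, 33, 14, 32, 45,
                  8, 11, 30, 31, 29, 28, 27, 26, 6, 9, 25, 24, 23, 5, 7, 19)
  os_event <- as.integer(1:31 %in% c(16, 24, 30, 31))
  unrelated <- as.integer(1:31 %in% c(30, 31))
  os_months <- dfs_months + 2
  os_months[c(16, 24)] <- c(20, 18)
  os_months[c(30, 31)] <- c(25, 22)

  rows <- vector("list", 31 * 3)
  for (i in 1:31) for (j in 1:3) {
    rows[[(i - 1) * 3 + j]] <- data.frame(
      case_id = case_id[i], rater_id = sprintf("R%d", j),
      til_grade = grades[i, j, "til"], eos_grade = grades[i, j, "eos"],
      neut_grade = grades[i, j, "neut"], dense_plasma = grades[i, j, "plasma"],
      rvt_area = rvt[i], necrosis_area = nec[i], regression_area = reg[i],
      immune_activated_rvt_pct = ia[i],
      neutrophil_count = neut_count[i], leukocyte_count = leuko[i],
      dfs_months = dfs_months[i], dfs_event = dfs_event[i],
      os_months = os_months[i], os_event = os_event[i],
      death_unrelated = unrelated[i],
      stringsAsFactors = FALSE)
  }
  patients <- do.call(rbind, rows)

  # PD-L1 series: 45 eosinophil-both (12 high / 15 low / 18 negative TPS)
  # and 63 others (4 / 28 / 31), plus one insufficient slide
  tps <- c(rep(55, 12), rep(10, 15), rep(0, 18),
           rep(60, 4), rep(5, 28), rep(0, 31),
           0)
  eos_both <- c(rep(1, 45), rep(0, 63), 0)
  cells <- c(rep(500L, 108), 80L)
  pdl1 <- data.frame(case_id = sprintf("P%03d", 1:109),
                     viable_tumour_cells = cells,
                     tps_percent = tps,
                     eos_both_compartments = eos_both,
                     stringsAsFactors = FALSE)

  ref <- data.frame(case_id = case_id[biopsy_cases],
                    ref_score = ref_score,
                    stringsAsFactors = FALSE)
  rvt_mean <- percent_rvt(rvt, nec, reg)[biopsy_cases]
  ref$response <- as.character(classify_response(rvt_mean))

  list(patients = as_cohort(patients, "patients"),
       pdl1 = as_cohort(pdl1, "pdl1"),
       ref_scores = ref)
}
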