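# Blood and IHC biomarkers: the derived neutrophil-to-lymphocyte ratio
# (dNLR) with its >3 cutoff, PD-L1 tumour proportion score (TPS) rules, and
# the eosinophil-compartment association table.

#' Derived neutrophil-to-lymphocyte ratio
#'
#' `dNLR = neutrophils / (leukocytes - neutrophils)` from the pretreatment
#' complete blood count, dichotomised at a strict `> 3` by default.
#'
#' @param neutrophils,leukocytes Absolute counts (10^9/L), vectorised;
#'   requires `0 < neutrophils < leukocytes`.
#' @param threshold Dichotomisation threshold (default 3; `high` is strict
#'   `>`).
#' @return Data frame with columns `value` and `high`.
#' @export
dnlr <- function(neutrophils, leukocytes, threshold = 3) {
  n <- max(length(neutrophils), length(leukocytes))
  neutrophils <- rep_len(neutrophils, n)
  leukocytes <- rep_len(leukocytes, n)
  if (anyNA(neutrophils) || anyNA(leukocytes))
    stop("blood counts must not be missing")
  if (any(neutrophils <= 0)) stop("neutrophil count must be positive")
  if (any(leukocytes <= neutrophils))
    stop("leukocytes must exceed neutrophils (non-positive lymphocyte-derived denominator)")
  value <- neutrophils / (leukocytes - neutrophils)
  data.frame(value = value, high = value > threshold)
}

#' Filter PD-L1 records for evaluability
#'
#' PD-L1 TPS can be assessed only when the IHC slide carries at least
#' `min_cells` viable tumour cells (inclusive threshold).
#'
#' @param pdl1 PD-L1 cohort table (columns `case_id`,
#'   `viable_tumour_cells`, `tps_percent`, `eos_both_compartments`).
#' @param min_cells Minimum viable tumour cells (default 100).
#' @return List with `retained` (evaluable subset) and `excluded` (data
#'   frame of `case_id`, `viable_tumour_cells`, `reason`).
#' @export
filter_pdl1_evaluable <- function(pdl1, min_cells = 100) {
  df <- as.data.frame(pdl1)
  keep <- !is.na(df$viable_tumour_cells) & df$viable_tumour_cells >= min_cells
  excluded <- df[!keep, c("case_id", "viable_tumour_cells"), drop = FALSE]
  excluded$reason <- ifelse(is.na(excluded$viable_tumour_cells),
                            "viable tumour-cell count missing",
                            sprintf("fewer than %d viable tumour cells", min_cells))
  rownames(excluded) <- NULL
  retained <- df[keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, excluded = excluded)
}

#' TPS category at the 1% and 50% cutoffs
#'
#' Bands `[0, 1)` = negative, `[1, 50)` = positive-low, `[50, 100]` = high;
#' both cutoffs are inclusive on the upper side (TPS of exactly 1% is
#' positive, exactly 50% is high).
#'
#' @param tps TPS percent(s) in `[0, 100]`.
#' @return Factor with levels `negative`, `positive_low`, `high`.
#' @export
tps_category <- function(tps) {
  if (anyNA(tps) || any(tps < 0 | tps > 100))
    stop("tps must be in [0, 100] with no missing values")
  cls <- ifelse(tps < 1, "negative", ifelse(tps < 50, "positive_low", "high"))
  factor(cls, levels = c("negative", "positive_low", "high"))
}

#' Eosinophil-compartment by PD-L1 TPS contingency table
#'
#' Cross-tabulates cases with eosinophils in both the tumour parenchyma and
#' the stroma against PD-L1 TPS at the chosen cutoff, and attaches Pearson's
#' chi-square test without continuity correction.  Records must already be
#' filtered for evaluability (see [filter_pdl1_evaluable()]).
#'
#' @param pdl1 Evaluable PD-L1 records.
#' @param tps_cutoff TPS cutoff in percent, 1 or 50 (any value in (0,100]
#'   accepted).
#' @return List with `table` (2x2 integer matrix, rows eos-both yes/no,
#'   columns TPS at/above vs below cutoff), `tps_cutoff`, `degenerate`
#'   (`TRUE` when a margin is empty), and `test` (from [pearson_chi2()];
#'   `NULL` when degenerate).
#' @export
eosinophil_pdl1_table <- function(pdl1, tps_cutoff = 50) {
  df <- as.data.frame(pdl1)
  if (!nrow(df)) stop("no PD-L1 records")
  if (anyNA(df$tps_percent) || anyNA(df$eos_both_compartments))
    stop("tps_percent and eos_both_compartments must not be missing")
  eos <- factor(ifelse(df$eos_both_compartments == 1, "eos_both", "eos_not"),
                levels = c("eos_both", "eos_not"))
  tps <- factor(ifelse(df$tps_percent >= tps_cutoff, "tps_high", "tps_below"),
                levels = c("tps_high", "tps_below"))
  tab <- table(eos, tps)
  m <- matrix(as.integer(tab), 2, 2, dimnames = dimnames(tab))
  degenerate <- any(rowSums(m) == 0) || any(colSums(m) == 0)
  list(table = m,
       tps_cutoff = tps_cutoff,
       degenerate = degenerate,
       test = if (degenerate) NULL else pearson_chi2(m))
}
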