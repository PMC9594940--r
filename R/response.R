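# Pathologic response in the resected specimen: per cent residual viable
# tumour (%RVT) and the cPR/MPR/pPR/nPR response classes.
#
# %RVT (with necrosis)    = RVT / (RVT + necrosis + regression bed) * 100
# %RVT (without necrosis) = RVT / (RVT + regression bed) * 100
# Classes partition [0, 100]: cPR = {0}, MPR = (0, 10], pPR = (10, 90],
# nPR = (90, 100].  Inclusive upper bounds are the only continuous reading
# consistent with integer class labels like "1-10%" while a value of exactly
# 10% remains MPR.  "MPR achieved" pools cPR and MPR.

#' Per cent residual viable tumour
#'
#' Computes %RVT from the tumour-bed component areas, summed across all
#' slides of a case, in any mutually consistent units.  With
#' `include_necrosis = TRUE` (the irPRC baseline) the denominator is the full
#' tumour bed; with `FALSE`, necrosis is dropped from the denominator.
#'
#' @param rvt_area,necrosis_area,regression_area Non-negative component
#'   areas (vectorised).
#' @param include_necrosis Include necrosis in the denominator?  Default
#'   `TRUE`.
#' @return Percent(s) in `[0, 100]`, unrounded.
#' @examples
#' percent_rvt(10, 60, 30)                            # 10
#' percent_rvt(10, 60, 30, include_necrosis = FALSE)  # 25
#' @export
percent_rvt <- function(rvt_area, necrosis_area, regression_area,
                        include_necrosis = TRUE) {
  n <- max(length(rvt_area), length(necrosis_area), length(regression_area))
  rvt_area <- rep_len(rvt_area, n)
  necrosis_area <- rep_len(necrosis_area, n)
  regression_area <- rep_len(regression_area, n)
  areas <- cbind(rvt_area, necrosis_area, regression_area)
  if (anyNA(areas)) stop("areas must not be missing")
  if (any(areas < 0)) stop("areas must be non-negative")
  denom <- if (include_necrosis) rowSums(areas) else rvt_area + regression_area
  if (any(denom <= 0)) {
    bad <- which(denom <= 0)
    stop("zero tumour-bed denominator for case index ",
         paste(bad, collapse = ", "),
         if (!include_necrosis) " (rvt_area + regression_area = 0 in without-necrosis mode)")
  }
  100 * rvt_area / denom
}

#' Pathologic response class from %RVT
#'
#' @param rvt_percent %RVT value(s) in `[0, 100]`.
#' @return Factor with levels `cPR`, `MPR`, `pPR`, `nPR`.
#' @export
classify_response <- function(rvt_percent) {
  if (anyNA(rvt_percent) || any(rvt_percent < 0 | rvt_percent > 100))
    stop("rvt_percent must be in [0, 100] with no missing values")
  cls <- ifelse(rvt_percent == 0, "cPR",
         ifelse(rvt_percent <= 10, "MPR",
         ifelse(rvt_percent <= 90, "pPR", "nPR")))
  factor(cls, levels = c("cPR", "MPR", "pPR", "nPR"))
}

#' Major pathologic response achieved?
#'
#' Pools cPR and MPR, the convention under which 15 of 31 patients "achieved
#' MPR" while only 9 resections carried residual tumour in the MPR band.
#'
#' @param response Factor/character response class(es).
#' @return Logical vector.
#' @export
mpr_achieved <- function(response) {
  response <- as.character(response)
  bad <- setdiff(unique(response), c("cPR", "MPR", "pPR", "nPR", NA))
  if (length(bad))
    stop("unknown response class(es): ", paste(bad, collapse = ", "))
  response %in% c("cPR", "MPR")
}

#' Cross-rater mean %RVT
#'
#' Arithmetic mean of per-rater %RVT values; missing raters are excluded
#' with a warning, and a single contributing rater is flagged.
#'
#' @param x Numeric vector of per-rater percents (may contain `NA`).
#' @return The mean percent.
#' @export
mean_rvt_across_raters <- function(x) {
  miss <- sum(is.na(x))
  x <- x[!is.na(x)]
  if (!length(x)) stop("all rater values missing")
  if (miss > 0) warning(miss, " missing rater value(s) excluded")
  if (length(x) == 1L) warning("single rater: mean equals the sole value")
  mean(x)
}

#' Sensitivity of the response grouping to necrosis
#'
#' For every case, computes %RVT with and without necrosis in the
#' denominator (cross-rater means), classifies both, flags cases whose
#' response class changes, and tests the paired without-minus-with
#' differences with the Wilcoxon signed-rank test (zero differences
#' dropped).
#'
#' @param patients Patients cohort table (one row per case and rater) as
#'   returned by [read_cohort()] or [simulate_cohort()].
#' @return List with `table` (per-case percents, classes, `changed` flag and
#'   `difference`), `n_changed`, `changed_cases`, and `wilcoxon` (see
#'   [wilcoxon_signed_rank()]; `NULL` when every difference is zero).
#' @export
necrosis_sensitivity <- function(patients) {
  cases <- split(as.data.frame(patients), patients$case_id)
  rows <- lapply(cases, function(d) {
    with_n <- mean(percent_rvt(d$rvt_area, d$necrosis_area, d$regression_area,
                               include_necrosis = TRUE))
    without_n <- mean(percent_rvt(d$rvt_area, d$necrosis_area, d$regression_area,
                                  include_necrosis = FALSE))
    data.frame(case_id = d$case_id[1],
               rvt_with = with_n, rvt_without = without_n,
               class_with = as.character(classify_response(with_n)),
               class_without = as.character(classify_response(without_n)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$difference <- tab$rvt_without - tab$rvt_with
  tab$changed <- tab$class_with != tab$class_without
  wt <- if (any(tab$difference != 0)) wilcoxon_signed_rank(tab$difference) else NULL
  list(table = tab,
       n_changed = sum(tab$changed),
       changed_cases = tab$case_id[tab$changed],
       wilcoxon = wt)
}
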