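# The irHPC pretreatment score.
#
# Four immune-related features of the pretreatment biopsy enter an additive
# score: tumour-infiltrating lymphocytes (TILs), eosinophils and dense plasma
# cells count positively, neutrophils negatively.  TILs, eosinophils and
# neutrophils are graded 0/1+/2+/3+ on HE; dense plasma cells are recorded as
# present/absent.  The neutrophil grade is subtracted with mirrored magnitude
# (grade g contributes -g), so the attainable range is -3 to 7.  A total of
# at least 2 points predicts pathologic response (cPR/MPR) to neoadjuvant
# anti-PD-1 treatment.

check_grade <- function(x, what) {
  if (any(!is_grade(x), na.rm = FALSE) || anyNA(x))
    stop(what, " grade must be in {0,1,2,3} with no missing values")
  as.integer(x)
}

#' irHPC pretreatment score
#'
#' Additive score over the four irHPC biopsy features: `til + eosinophils -
#' neutrophils + 1[dense plasma cells present]`.  All arguments are
#' vectorised and recycled to a common length.
#'
#' @param til,eosinophils,neutrophils Ordinal grades in `{0,1,2,3}`
#'   (0/1+/2+/3+).
#' @param dense_plasma Presence of dense plasma cells in the tumour-related
#'   stroma: 0/1 or logical.
#' @return Integer score(s) in `[-3, 7]`.
#' @examples
#' irhpc_score(til = 3, eosinophils = 0, neutrophils = 0, dense_plasma = 0)  # 3
#' irhpc_score(1, 0, 3, FALSE)                                               # -2
#' @export
irhpc_score <- function(til, eosinophils, neutrophils, dense_plasma) {
  til <- check_grade(til, "TIL")
  eosinophils <- check_grade(eosinophils, "eosinophil")
  neutrophils <- check_grade(neutrophils, "neutrophil")
  if (anyNA(dense_plasma) || !all(dense_plasma %in% c(0, 1, TRUE, FALSE)))
    stop("dense_plasma must be binary (0/1 or logical) with no missing values")
  til + eosinophils - neutrophils + as.integer(dense_plasma)
}

#' Predicted response at the irHPC cutoff
#'
#' A case is predicted to respond (achieve cPR/MPR) when its irHPC score
#' reaches the cutoff; the default cutoff of 2 points uses the
#' greater-or-equal rule, so a score of exactly 2 predicts response.
#'
#' @param score Integer irHPC score(s) in `[-3, 7]`.
#' @param cutoff Integer cutoff (default 2).
#' @return Factor with levels `non_responder`, `responder`.
#' @export
classify_prediction <- function(score, cutoff = 2) {
  if (anyNA(score) || any(score < -3 | score > 7))
    stop("score must be in [-3, 7] with no missing values")
  factor(ifelse(score >= cutoff, "responder", "non_responder"),
         levels = c("non_responder", "responder"))
}

#' Cross-tabulate reference scores against achieved response
#'
#' For each pooled response group (cPR/MPR vs pPR/nPR) reports how many cases
#' scored at or above the cutoff, mirroring the headline splits of the kind
#' "87.5% (7/8) of responders scored no less than 2 points".
#'
#' @param score Reference irHPC score per case.
#' @param response Achieved response class per case: factor/character with
#'   values in `cPR`, `MPR`, `pPR`, `nPR`.
#' @param cutoff Score cutoff (default 2).
#' @return Data frame with one row per group (`cPR/MPR`, `pPR/nPR`):
#'   `n`, `n_ge_cutoff`, `pct_ge_cutoff`, `n_lt_cutoff`, `pct_lt_cutoff`
#'   (percentages to one decimal; `NA` and `undefined = TRUE` for an empty
#'   group).
#' @export
score_group_summary <- function(score, response, cutoff = 2) {
  if (length(score) != length(response))
    stop("score and response must have the same length")
  response <- as.character(response)
  bad <- setdiff(unique(response), c("cPR", "MPR", "pPR", "nPR"))
  if (length(bad))
    stop("unknown response class(es): ", paste(bad, collapse = ", "))
  group <- ifelse(response %in% c("cPR", "MPR"), "cPR/MPR", "pPR/nPR")
  out <- lapply(c("cPR/MPR", "pPR/nPR"), function(g) {
    s <- score[group == g]
    n <- length(s)
    n_ge <- sum(s >= cutoff)
    data.frame(group = g, n = n, n_ge_cutoff = n_ge,
               pct_ge_cutoff = if (n) round(100 * n_ge / n, 1) else NA_real_,
               n_lt_cutoff = n - n_ge,
               pct_lt_cutoff = if (n) round(100 * (n - n_ge) / n, 1) else NA_real_,
               undefined = n == 0L,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
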