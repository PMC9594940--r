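# Inter-rater agreement: overall per cent agreement (OPA) over all pairwise
# rater comparisons with a binomial confidence interval, and Fleiss' kappa
# with the standard interpretation bands.
#
# OPA treats every unordered rater pair within a case as one comparison;
# pairs are pooled over cases and treated as independent for the CI — an
# approximation, but the one implied by quoting "35 concordant of 45 pairs"
# as a single proportion.  The default interval is the Wilson score interval,
# which behaves sensibly at proportions near 0 or 1; Clopper-Pearson is
# available as an alternative.

#' Wilson score confidence interval for a proportion
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf_level Confidence level (default 0.95).
#' @return Numeric `c(low, high)` on the proportion scale.
#' @keywords internal
wilson_ci <- function(x, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(max(0, centre - half), min(1, centre + half))
}

agreement_result <- function(n_concordant, n_pairs, n_cases, n_raters,
                             conf_method, conf_level) {
  ci <- switch(conf_method,
    wilson = wilson_ci(n_concordant, n_pairs, conf_level),
    `clopper-pearson` = as.numeric(
      stats::binom.test(n_concordant, n_pairs,
                        conf.level = conf_level)$conf.int))
  structure(list(n_cases = n_cases, n_raters = n_raters,
                 n_pairs = n_pairs, n_concordant = n_concordant,
                 opa = 100 * n_concordant / n_pairs,
                 ci_low = 100 * ci[1], ci_high = 100 * ci[2],
                 conf_method = conf_method, conf_level = conf_level),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("OPA %.1f%% (%d/%d pairs), %d%% CI [%.1f, %.1f] (%s)\n",
              x$opa, x$n_concordant, x$n_pairs,
              round(100 * x$conf_level), x$ci_low, x$ci_high, x$conf_method))
  invisible(x)
}

#' Overall per cent agreement over rater pairs
#'
#' For each case, every unordered pair of raters with both ratings present
#' contributes one comparison; a pair is concordant when the two ratings are
#' equal.  OPA is the percentage of concordant pairs, with a 95% confidence
#' interval.
#'
#' @param ratings Cases-by-raters matrix (or data frame) of categorical
#'   ratings; `NA` marks a missing rating.  At least 2 rater columns.
#' @param conf_method `"wilson"` (default) or `"clopper-pearson"`.
#' @param conf_level Confidence level (default 0.95).
#' @return An `agreement_result`: `n_cases`, `n_raters`, `n_pairs`,
#'   `n_concordant`, `opa` (percent), `ci_low`, `ci_high`.
#' @export
opa <- function(ratings, conf_method = c("wilson", "clopper-pearson"),
                conf_level = 0.95) {
  conf_method <- match.arg(conf_method)
  m <- as.matrix(ratings)
  if (ncol(m) < 2L) stop("need at least 2 raters")
  n_pairs <- 0L
  n_conc <- 0L
  for (i in seq_len(nrow(m))) {
    r <- m[i, ]
    r <- r[!is.na(r)]
    k <- length(r)
    if (k < 2L) next
    n_pairs <- n_pairs + choose(k, 2)
    counts <- table(r)
    n_conc <- n_conc + sum(choose(counts, 2))
  }
  if (n_pairs == 0L) stop("no contributing rater pairs")
  agreement_result(as.integer(n_conc), as.integer(n_pairs), nrow(m), ncol(m),
                   conf_method, conf_level)
}

#' Overall per cent agreement from summary counts
#'
#' Builds the same result as [opa()] from the concordant-pair count and the
#' design size, assuming complete ratings (`n_pairs = n_cases *
#' choose(n_raters, 2)`).
#'
#' @param n_concordant Number of concordant pairs.
#' @param n_cases Number of cases.
#' @param n_raters Number of raters per case.
#' @inheritParams opa
#' @return An `agreement_result`.
#' @export
opa_from_counts <- function(n_concordant, n_cases, n_raters,
                            conf_method = c("wilson", "clopper-pearson"),
                            conf_level = 0.95) {
  conf_method <- match.arg(conf_method)
  n_pairs <- n_cases * choose(n_raters, 2)
  if (n_concordant < 0 || n_concordant > n_pairs)
    stop("impossible counts: n_concordant must be in [0, ", n_pairs, "]")
  agreement_result(as.integer(n_concordant), as.integer(n_pairs),
                   as.integer(n_cases), as.integer(n_raters),
                   conf_method, conf_level)
}

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement for n cases each rated by the same number of
#' raters: per-case agreement `P_i = (sum_j n_ij^2 - n) / (n (n - 1))`,
#' mean observed agreement `P_bar`, chance agreement `P_e = sum_j p_j^2`
#' from the pooled category proportions, and
#' `kappa = (P_bar - P_e) / (1 - P_e)`.  Cases whose number of non-missing
#' ratings differs from the majority are dropped with a warning.  When a
#' single category is used throughout (`P_e = 1`) kappa is undefined and
#' flagged.
#'
#' @param ratings Cases-by-raters matrix of categorical ratings (`NA` =
#'   missing).
#' @return List with `kappa`, `label` (see [interpret_kappa()]), `p_bar`,
#'   `p_e`, `n_cases`, `n_raters`, `categories`, `undefined`.
#' @export
fleiss_kappa <- function(ratings) {
  m <- as.matrix(ratings)
  per_row <- rowSums(!is.na(m))
  usable <- per_row >= 2
  if (!any(usable)) stop("no case has at least 2 ratings")
  n_mode <- as.integer(names(which.max(table(per_row[usable]))))
  keep <- per_row == n_mode
  if (any(usable & !keep))
    warning(sum(usable & !keep),
            " case(s) dropped: number of ratings differs from the modal ",
            n_mode)
  m <- m[keep, , drop = FALSE]
  cats <- sort(unique(stats::na.omit(as.vector(m))))
  N <- nrow(m)
  nij <- t(apply(m, 1, function(r)
    as.numeric(table(factor(r[!is.na(r)], levels = cats)))))
  if (length(cats) == 1L) nij <- matrix(nij, ncol = 1L)
  n <- n_mode
  p_i <- (rowSums(nij^2) - n) / (n * (n - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(nij) / (N * n)
  p_e <- sum(p_j^2)
  undefined <- (1 - p_e) < .Machine$double.eps^0.5
  kappa <- if (undefined) NA_real_ else (p_bar - p_e) / (1 - p_e)
  list(kappa = kappa,
       label = if (undefined) NA_character_ else interpret_kappa(kappa),
       p_bar = p_bar, p_e = p_e,
       n_cases = N, n_raters = n, categories = cats,
       undefined = undefined)
}

#' Interpretation band for a kappa value
#'
#' Bands: poor to fair (<= 0.40), moderate (0.41-0.60), substantial
#' (0.61-0.80), almost perfect (0.81-1.00).  Kappa is rounded to two
#' decimals before banding, matching the two-decimal band edges (so 0.404
#' is "poor to fair" and 0.405 rounds into "moderate").
#'
#' @param kappa Kappa value(s) in `[-1, 1]`.
#' @return Character label(s).
#' @export
interpret_kappa <- function(kappa) {
  if (anyNA(kappa) || any(kappa < -1 - 1e-8 | kappa > 1 + 1e-8))
    stop("kappa must be in [-1, 1] and defined")
  k <- round(kappa, 2)
  ifelse(k <= 0.40, "poor to fair",
  ifelse(k <= 0.60, "moderate",
  ifelse(k <= 0.80, "substantial", "almost perfect")))
}
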