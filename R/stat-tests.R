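# Nonparametric tests used by the response and biomarker analyses, wrapped
# with the zero-handling and correction conventions fixed for this package.

#' Wilcoxon signed-rank test on paired differences
#'
#' Classic Wilcoxon handling: zero differences are dropped before ranking.
#' With at most `exact_limit` non-zero differences and no ties among their
#' absolute values, the exact null distribution is used; otherwise the
#' tie-corrected normal approximation (no continuity correction).
#'
#' @param x Differences, or first members of pairs when `y` is given.
#' @param y Optional second members of pairs (`d = x - y`).
#' @param exact_limit Largest non-zero sample size for the exact
#'   distribution (default 25).
#' @return List with `statistic` (V, the positive-rank sum), `p_value`
#'   (two-sided), `n_nonzero`, `n_zero`, `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 25) {
  d <- if (is.null(y)) x else x - y
  if (anyNA(d)) stop("differences must not be missing")
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero: signed-rank test degenerate")
  exact <- n <= exact_limit && !any(duplicated(abs(d)))
  res <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       n_nonzero = n, n_zero = n_zero, exact = exact)
}

#' Kruskal-Wallis rank-sum test
#'
#' Rank-based H statistic with tie correction, referred to the chi-square
#' distribution with k - 1 degrees of freedom.
#'
#' @param groups List of numeric samples (at least 2 non-empty groups).
#' @return List with `statistic` (H), `df`, `p_value`, `n_groups`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups)) stop("groups must be a list of numeric samples")
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  if (length(groups) < 2L) stop("need at least 2 non-empty groups")
  res <- stats::kruskal.test(groups)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, n_groups = length(groups))
}

#' Pearson's chi-square test on a contingency table
#'
#' Pearson statistic without continuity correction (the convention fixed for
#' the eosinophil-by-TPS tables).  A table with an empty row or column
#' margin is flagged degenerate instead of tested.
#'
#' @param table Contingency table as a matrix of non-negative counts.
#' @return List with `statistic`, `df`, `p_value`, `expected`,
#'   `degenerate`.
#' @export
pearson_chi2 <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || sum(m) == 0) stop("table must hold non-negative counts with a positive total")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
                expected = NULL, degenerate = TRUE))
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = res$expected, degenerate = FALSE)
}
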