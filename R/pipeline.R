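# End-to-end study pipeline: validate -> score -> respond -> biomarkers ->
# agreement -> survival, assembling a structured, serialisable report.

default_run_config <- function() {
  list(cutoff = 2,
       dnlr_threshold = 3,
       min_cells = 100,
       tps_cutoffs = c(1, 50),
       km_times = c(12, 24),
       include_necrosis = TRUE,
       conf_method = "wilson",
       ref_scores = NULL)
}

first_per_case <- function(df, cols) {
  idx <- !duplicated(df$case_id)
  df[idx, c("case_id", cols), drop = FALSE]
}

#' Run the full study analysis
#'
#' Executes the analysis flow on a patients table and an optional PD-L1
#' table: validation, per-rater irHPC scoring and predicted response,
#' cross-rater %RVT and pathologic response classes, the necrosis
#' sensitivity analysis, dNLR, inter-rater agreement (OPA and Fleiss'
#' kappa on the binarised predictions), Kaplan-Meier DFS/OS overall and by
#' grouping (MPR achieved, irHPC at the cutoff, dNLR), and the
#' eosinophil-by-TPS tables.  Deterministic given its inputs.
#'
#' @param patients Patients table: path to a CSV or a data frame/cohort in
#'   the documented schema.
#' @param pdl1 Optional PD-L1 table (path or data frame).
#' @param config Named list overriding the defaults: `cutoff` (irHPC
#'   cutoff, 2), `dnlr_threshold` (3), `min_cells` (100), `tps_cutoffs`
#'   (`c(1, 50)`), `km_times` (`c(12, 24)` months), `include_necrosis`
#'   (`TRUE`), `conf_method` (`"wilson"`), and `ref_scores` (optional data
#'   frame `case_id`, `ref_score` of reference scores for the
#'   score-response cross-tab; defaults to the per-case mean rater score).
#' @return A `study_report` list; see [render_report()].
#' @export
run_study <- function(patients, pdl1 = NULL, config = list()) {
  cf <- utils::modifyList(default_run_config(), config)
  if (is.character(patients)) patients <- read_cohort(patients, "patients")
  if (!inherits(patients, "irhpc_cohort")) patients <- as_cohort(patients, "patients")
  if (is.character(pdl1)) pdl1 <- read_cohort(pdl1, "pdl1")
  if (!is.null(pdl1) && !inherits(pdl1, "irhpc_cohort")) pdl1 <- as_cohort(pdl1, "pdl1")
  if (!nrow(patients)) stop("empty patients table")
  v <- cohort_violations(patients)
  if (nrow(v))
    stop("patients table fails validation:\n",
         paste(sprintf("  row %d, %s: %s", v$row, v$field, v$rule), collapse = "\n"))
  if (!is.null(pdl1)) {
    vp <- cohort_violations(pdl1)
    if (nrow(vp))
      stop("pdl1 table fails validation:\n",
           paste(sprintf("  row %d, %s: %s", vp$row, vp$field, vp$rule), collapse = "\n"))
  }
  df <- as.data.frame(patients)
  message("stage validate: ", length(unique(df$case_id)), " cases, ",
          nrow(df), " rater rows in")

  # pathologic response: cross-rater mean %RVT, both denominators
  ns <- necrosis_sensitivity(df)
  resp_tab <- ns$table
  resp_tab$rvt_mean <- if (cf$include_necrosis) resp_tab$rvt_with else resp_tab$rvt_without
  resp_tab$response <- if (cf$include_necrosis) resp_tab$class_with else resp_tab$class_without
  resp_tab$mpr_achieved <- mpr_achieved(resp_tab$response)
  n_cases <- nrow(resp_tab)
  mpr <- list(n_mpr = sum(resp_tab$mpr_achieved), n = n_cases,
              rate_percent = round(100 * mean(resp_tab$mpr_achieved), 1))
  message("stage respond: MPR ", mpr$n_mpr, "/", mpr$n)

  # irHPC per (case, rater) where grades are complete
  gr <- df[stats::complete.cases(df[, c("til_grade", "eos_grade",
                                        "neut_grade", "dense_plasma")]), ]
  scores <- NULL
  agreement <- NULL
  mean_scores <- NULL
  if (nrow(gr)) {
    scores <- data.frame(case_id = gr$case_id, rater_id = gr$rater_id,
                         score = irhpc_score(gr$til_grade, gr$eos_grade,
                                             gr$neut_grade, gr$dense_plasma),
                         stringsAsFactors = FALSE)
    scores$predicted <- as.character(classify_prediction(scores$score, cf$cutoff))
    mean_scores <- stats::aggregate(score ~ case_id, scores, mean)
    names(mean_scores) <- c("case_id", "mean_score")
    # agreement on the binarised prediction, cases x raters
    wide <- stats::reshape(scores[, c("case_id", "rater_id", "score")],
                           idvar = "case_id", timevar = "rater_id",
                           direction = "wide")
    mat <- as.matrix(wide[, -1, drop = FALSE]) >= cf$cutoff
    storage.mode(mat) <- "integer"
    agreement <- list(opa = opa(mat, conf_method = cf$conf_method),
                      kappa = fleiss_kappa(mat))
    message("stage agreement: ", agreement$opa$n_concordant, "/",
            agreement$opa$n_pairs, " concordant pairs")
  }

  # score-response cross-tab at the cutoff (reference scores if supplied)
  group_summary <- NULL
  ref <- cf$ref_scores
  if (!is.null(ref)) {
    ref <- as.data.frame(ref)[, c("case_id", "ref_score")]
  } else if (!is.null(mean_scores)) {
    ref <- mean_scores
    names(ref) <- c("case_id", "ref_score")
  }
  if (!is.null(ref)) {
    m <- merge(ref, resp_tab[, c("case_id", "response")], by = "case_id")
    group_summary <- score_group_summary(m$ref_score, m$response, cf$cutoff)
  }

  # dNLR on case-level blood counts
  blood <- first_per_case(df, c("neutrophil_count", "leukocyte_count"))
  blood <- blood[stats::complete.cases(blood), ]
  dnlr_tab <- NULL
  if (nrow(blood)) {
    dnlr_tab <- cbind(blood["case_id"],
                      dnlr(blood$neutrophil_count, blood$leukocyte_count,
                           cf$dnlr_threshold))
  }

  # survival: drop treatment-unrelated deaths, KM overall and by group
  surv_cols <- c("dfs_months", "dfs_event", "os_months", "os_event",
                 "death_unrelated")
  cases <- first_per_case(df, surv_cols)
  cases <- merge(cases, resp_tab[, c("case_id", "mpr_achieved")], by = "case_id")
  if (!is.null(ref))
    cases <- merge(cases, ref, by = "case_id", all.x = TRUE)
  if (!is.null(dnlr_tab))
    cases <- merge(cases, dnlr_tab[, c("case_id", "high")], by = "case_id",
                   all.x = TRUE)
  fs <- filter_survival_cohort(cases)
  an <- fs$analysed
  an <- an[stats::complete.cases(an[, c("dfs_months", "dfs_event",
                                        "os_months", "os_event")]), ]
  survival_res <- NULL
  if (nrow(an)) {
    groupings <- list(mpr_achieved = ifelse(an$mpr_achieved, "MPR", "non-MPR"))
    if (!is.null(an$ref_score))
      groupings$irhpc <- ifelse(is.na(an$ref_score), NA,
                                ifelse(an$ref_score >= cf$cutoff,
                                       "score>=cutoff", "score<cutoff"))
    if (!is.null(an$high))
      groupings$dnlr <- ifelse(is.na(an$high), NA,
                               ifelse(an$high, "dNLR>thr", "dNLR<=thr"))
    by_group <- function(endpoint) {
      tm <- an[[paste0(endpoint, "_months")]]
      ev <- an[[paste0(endpoint, "_event")]]
      overall <- km_fit(tm, ev)
      rates <- data.frame(group = "all", time = cf$km_times,
                          rate_percent = 100 * suppressWarnings(
                            rate_at(overall, cf$km_times)))
      per_group <- lapply(groupings, function(g) {
        ok <- !is.na(g)
        if (!any(ok)) return(NULL)
        suppressWarnings(km_by_group(tm[ok], ev[ok], g[ok], at = cf$km_times))
      })
      list(overall = overall, rates = rates,
           by_group = per_group[!vapply(per_group, is.null, logical(1))],
           median_followup = median_followup(tm))
    }
    survival_res <- list(n_analysed = nrow(an),
                         excluded_ids = fs$excluded_ids,
                         dfs = by_group("dfs"), os = by_group("os"))
    message("stage survival: ", nrow(an), " analysed, ",
            length(fs$excluded_ids), " excluded")
  }

  # PD-L1: evaluability filter and the eosinophil tables
  pdl1_res <- NULL
  if (!is.null(pdl1)) {
    flt <- filter_pdl1_evaluable(pdl1, cf$min_cells)
    tabs <- lapply(cf$tps_cutoffs, function(ct)
      eosinophil_pdl1_table(flt$retained, ct))
    names(tabs) <- paste0("cutoff_", cf$tps_cutoffs)
    pdl1_res <- list(n_input = nrow(pdl1),
                     n_evaluable = nrow(flt$retained),
                     excluded = flt$excluded,
                     tables = tabs)
    message("stage biomarkers: ", pdl1_res$n_evaluable, "/",
            pdl1_res$n_input, " PD-L1 evaluable")
  }

  structure(list(
    cohort = list(n_enrolled = n_cases,
                  n_biopsy_scored = if (is.null(scores)) 0L else
                    length(unique(scores$case_id)),
                  n_survival = if (is.null(survival_res)) 0L else
                    survival_res$n_analysed,
                  n_pdl1_evaluable = if (is.null(pdl1_res)) NA_integer_ else
                    pdl1_res$n_evaluable),
    response = list(table = resp_tab, mpr = mpr),
    irhpc = list(scores = scores, mean_scores = mean_scores,
                 group_summary = group_summary),
    agreement = agreement,
    necrosis = list(n_changed = ns$n_changed,
                    changed_cases = ns$changed_cases,
                    wilcoxon = ns$wilcoxon),
    dnlr = if (is.null(dnlr_tab)) NULL else
      list(table = dnlr_tab, n_high = sum(dnlr_tab$high), n = nrow(dnlr_tab)),
    survival = survival_res,
    pdl1 = pdl1_res,
    meta = list(package = "irhpc",
                version = as.character(utils::packageVersion("irhpc")),
                config = cf[setdiff(names(cf), "ref_scores")])),
    class = "study_report")
}

km_to_list <- function(curve) {
  curve[c("time", "surv", "n_risk", "n_event", "n_censor", "n_start")]
}

report_to_list <- function(report) {
  x <- unclass(report)
  strip <- function(v) {
    if (inherits(v, "km_curve")) return(km_to_list(v))
    if (inherits(v, "agreement_result")) return(unclass(v))
    if (is.factor(v)) return(as.character(v))
    if (is.data.frame(v)) {
      v[] <- lapply(v, function(col) if (is.factor(col)) as.character(col) else col)
      return(v)
    }
    if (is.matrix(v)) return(v)
    if (is.list(v)) return(lapply(v, strip))
    v
  }
  lapply(x, strip)
}

#' Serialise a study report
#'
#' `"json"` writes a machine-readable report that round-trips through
#' [jsonlite::fromJSON()]; `"text"` writes a human-readable summary in the
#' analysis order, percentages to one decimal and kappa to two.  Every
#' number in the text rendering is also present in the JSON.
#'
#' @param report A `study_report` from [run_study()].
#' @param format `"json"` or `"text"`.
#' @param path Optional output file; when `NULL` the rendering is returned
#'   only.
#' @return The rendered character scalar, invisibly.
#' @export
render_report <- function(report, format = c("json", "text"), path = NULL) {
  stopifnot(inherits(report, "study_report"))
  format <- match.arg(format)
  out <- if (format == "json") {
    as.character(jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                                  digits = NA, na = "null", null = "null"))
  } else {
    render_report_text(report)
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

render_report_text <- function(r) {
  ln <- character()
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("irHPC study report (package %s %s)", r$meta$package, r$meta$version)
  add("Cohort: %d enrolled, %d biopsy-scored, %d in survival analysis",
      r$cohort$n_enrolled, r$cohort$n_biopsy_scored, r$cohort$n_survival)
  add("MPR achieved: %d/%d (%.1f%%)",
      r$response$mpr$n_mpr, r$response$mpr$n, r$response$mpr$rate_percent)
  if (!is.null(r$irhpc$group_summary)) {
    gs <- r$irhpc$group_summary
    for (i in seq_len(nrow(gs)))
      add("Scores >= cutoff in %s: %d/%d (%.1f%%)", gs$group[i],
          gs$n_ge_cutoff[i], gs$n[i], gs$pct_ge_cutoff[i])
  }
  if (!is.null(r$agreement)) {
    a <- r$agreement$opa
    add("OPA: %.1f%% (%d/%d pairs), 95%% CI [%.1f, %.1f]",
        a$opa, a$n_concordant, a$n_pairs, a$ci_low, a$ci_high)
    k <- r$agreement$kappa
    if (!k$undefined)
      add("Fleiss kappa: %.2f (%s)", k$kappa, k$label)
  }
  add("Necrosis sensitivity: %d case(s) change response class", r$necrosis$n_changed)
  if (!is.null(r$necrosis$wilcoxon))
    add("  Wilcoxon signed-rank on %d non-zero differences: p = %.3g",
        r$necrosis$wilcoxon$n_nonzero, r$necrosis$wilcoxon$p_value)
  if (!is.null(r$dnlr))
    add("dNLR high: %d/%d", r$dnlr$n_high, r$dnlr$n)
  if (!is.null(r$survival)) {
    for (ep in c("dfs", "os")) {
      s <- r$survival[[ep]]
      add("%s median follow-up: %.1f (%.1f-%.1f) months", toupper(ep),
          s$median_followup$median, s$median_followup$min, s$median_followup$max)
      rt <- s$rates
      for (i in seq_len(nrow(rt)))
        add("  %s S(%g mo) = %.1f%%", toupper(ep), rt$time[i], rt$rate_percent[i])
      for (g in names(s$by_group)) {
        rg <- s$by_group[[g]]$rates
        for (i in seq_len(nrow(rg)))
          add("  %s [%s = %s] S(%g mo) = %.1f%%", toupper(ep), g, rg$group[i],
              rg$time[i], rg$rate_percent[i])
      }
    }
  }
  if (!is.null(r$pdl1)) {
    add("PD-L1 evaluable: %d/%d", r$pdl1$n_evaluable, r$pdl1$n_input)
    for (nm in names(r$pdl1$tables)) {
      tb <- r$pdl1$tables[[nm]]
      add("  eosinophil x TPS at %g%%: [[%d,%d],[%d,%d]]%s", tb$tps_cutoff,
          tb$table[1, 1], tb$table[1, 2], tb$table[2, 1], tb$table[2, 2],
          if (tb$degenerate) " (degenerate)" else
            sprintf(", chi2 = %.2f, p = %.3g",
                    tb$test$statistic, tb$test$p_value))
    }
  }
  paste(ln, collapse = "\n")
}
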