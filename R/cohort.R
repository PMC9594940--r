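# Cohort tables: schemas, readers/writers, record validation.
#
# Two tabular layouts are supported:
#   * "patients": one row per (case, rater) — biopsy feature grades, tumour-bed
#     component areas, immune-activated %RVT, pretreatment blood counts and
#     survival record.  Blood counts and survival are case-level quantities and
#     must be repeated identically on every rater row of a case.
#   * "pdl1": one row per case — viable tumour-cell count on the IHC slide,
#     PD-L1 tumour proportion score (TPS) and the eosinophil compartment flag.
# Missing values are empty cells; they surface as NA and are never imputed.

#' Column order of the patients table
#' @keywords internal
patients_cols <- c(
  "case_id", "rater_id",
  "til_grade", "eos_grade", "neut_grade", "dense_plasma",
  "rvt_area", "necrosis_area", "regression_area",
  "immune_activated_rvt_pct",
  "neutrophil_count", "leukocyte_count",
  "dfs_months", "dfs_event", "os_months", "os_event", "death_unrelated"
)

#' Column order of the PD-L1 table
#' @keywords internal
pdl1_cols <- c("case_id", "viable_tumour_cells", "tps_percent",
               "eos_both_compartments")

cohort_schema <- function(table_kind) {
  switch(table_kind, patients = patients_cols, pdl1 = pdl1_cols,
         stop("unknown table_kind: ", table_kind))
}

#' Read a cohort table
#'
#' Reads a CSV cohort table (UTF-8, comma-separated, header row, "." decimal
#' mark), coerces the numeric columns, and validates every row against the
#' type invariants.  Rows that violate an invariant are kept in the table;
#' the violations are returned alongside so the caller decides how to treat
#' them (see [cohort_violations()]).  The file is rejected outright if a
#' required column is missing or an unknown column is present.
#'
#' @param path Path to a CSV file.
#' @param table_kind `"patients"` (one row per case and rater) or `"pdl1"`
#'   (one row per case).
#' @return A `data.frame` of class `"irhpc_cohort"` with attributes `kind`
#'   and `violations` (a data frame with columns `row`, `case_id`, `field`,
#'   `rule`).
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path, table_kind = c("patients", "pdl1")) {
  table_kind <- match.arg(table_kind)
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  expected <- cohort_schema(table_kind)
  miss <- setdiff(expected, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(raw), expected)
  if (length(extra))
    stop("unknown column(s): ", paste(extra, collapse = ", "))
  df <- raw[, expected, drop = FALSE]
  num_cols <- setdiff(expected, c("case_id", "rater_id"))
  for (cc in num_cols) {
    v <- df[[cc]]
    v[!nzchar(v)] <- NA_character_
    df[[cc]] <- suppressWarnings(as.numeric(v))
  }
  as_cohort(df, table_kind)
}

#' @rdname read_cohort
#' @param df A data frame already holding the documented columns.
#' @export
as_cohort <- function(df, table_kind = c("patients", "pdl1")) {
  table_kind <- match.arg(table_kind)
  expected <- cohort_schema(table_kind)
  miss <- setdiff(expected, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, expected, drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            class = c("irhpc_cohort", "data.frame"),
            kind = table_kind,
            violations = validate_cohort(df, table_kind))
}

#' Per-row validation violations of a cohort
#' @param cohort An object returned by [read_cohort()] or [as_cohort()].
#' @return Data frame with columns `row`, `case_id`, `field`, `rule`.
#' @export
cohort_violations <- function(cohort) attr(cohort, "violations")

# Accumulate one violation row per failing record.
viol <- function(rows, case_id, field, rule) {
  if (!length(rows)) return(NULL)
  data.frame(row = rows, case_id = as.character(case_id), field = field,
             rule = rule, stringsAsFactors = FALSE)
}

is_binary <- function(x) is.na(x) | x %in% c(0, 1)
is_grade  <- function(x) is.na(x) | x %in% 0:3

#' Validate a cohort table against its type invariants
#'
#' Checks every invariant of the underlying record types: ordinal grades in
#' 0..3, binary flags in \{0,1\}, non-negative areas with a non-empty tumour
#' bed, blood counts with 0 < neutrophils < leukocytes, non-negative survival
#' times, TPS in \[0,100\], non-negative cell counts, and uniqueness of
#' (case, rater) rows.  Violations are data, not exceptions.
#'
#' @param df Data frame with the documented columns.
#' @param table_kind `"patients"` or `"pdl1"`.
#' @return Data frame with columns `row`, `case_id`, `field`, `rule`
#'   (zero rows when the table is fully valid).
#' @export
validate_cohort <- function(df, table_kind = c("patients", "pdl1")) {
  table_kind <- match.arg(table_kind)
  out <- list()
  n <- nrow(df)
  empty <- data.frame(row = integer(), case_id = character(),
                      field = character(), rule = character(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  rows <- seq_len(n)
  if (table_kind == "patients") {
    for (f in c("til_grade", "eos_grade", "neut_grade")) {
      bad <- rows[!is_grade(df[[f]])]
      out <- c(out, list(viol(bad, df$case_id[bad], f, "ordinal grade must be in 0..3")))
    }
    for (f in c("dense_plasma", "dfs_event", "os_event", "death_unrelated")) {
      bad <- rows[!is_binary(df[[f]])]
      out <- c(out, list(viol(bad, df$case_id[bad], f, "flag must be 0 or 1")))
    }
    for (f in c("rvt_area", "necrosis_area", "regression_area")) {
      bad <- rows[!is.na(df[[f]]) & df[[f]] < 0]
      out <- c(out, list(viol(bad, df$case_id[bad], f, "area must be non-negative")))
    }
    bed <- df$rvt_area + df$necrosis_area + df$regression_area
    bad <- rows[!is.na(bed) & bed <= 0]
    out <- c(out, list(viol(bad, df$case_id[bad], "rvt_area",
                            "tumour bed empty (all component areas zero)")))
    bad <- rows[!is.na(df$neutrophil_count) & df$neutrophil_count <= 0]
    out <- c(out, list(viol(bad, df$case_id[bad], "neutrophil_count",
                            "blood count must be positive")))
    bad <- rows[!is.na(df$neutrophil_count) & !is.na(df$leukocyte_count) &
                  df$leukocyte_count <= df$neutrophil_count]
    out <- c(out, list(viol(bad, df$case_id[bad], "leukocyte_count",
                            "leukocytes must exceed neutrophils")))
    for (f in c("dfs_months", "os_months")) {
      bad <- rows[!is.na(df[[f]]) & df[[f]] < 0]
      out <- c(out, list(viol(bad, df$case_id[bad], f, "time must be non-negative")))
    }
    bad <- rows[!is.na(df$immune_activated_rvt_pct) &
                  (df$immune_activated_rvt_pct < 0 | df$immune_activated_rvt_pct > 100)]
    out <- c(out, list(viol(bad, df$case_id[bad], "immune_activated_rvt_pct",
                            "percent must be in [0,100]")))
    key <- paste(df$case_id, df$rater_id, sep = "\r")
    bad <- rows[duplicated(key)]
    out <- c(out, list(viol(bad, df$case_id[bad], "rater_id",
                            "(case_id, rater_id) must be unique")))
  } else {
    bad <- rows[!is.na(df$viable_tumour_cells) & df$viable_tumour_cells < 0]
    out <- c(out, list(viol(bad, df$case_id[bad], "viable_tumour_cells",
                            "cell count must be non-negative")))
    bad <- rows[!is.na(df$tps_percent) &
                  (df$tps_percent < 0 | df$tps_percent > 100)]
    out <- c(out, list(viol(bad, df$case_id[bad], "tps_percent",
                            "TPS must be in [0,100]")))
    bad <- rows[!is_binary(df$eos_both_compartments)]
    out <- c(out, list(viol(bad, df$case_id[bad], "eos_both_compartments",
                            "flag must be 0 or 1")))
    bad <- rows[duplicated(df$case_id)]
    out <- c(out, list(viol(bad, df$case_id[bad], "case_id",
                            "case_id must be unique")))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$row, res$field), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Validate a single patient record
#'
#' Convenience wrapper over [validate_cohort()] for one (case, rater) row
#' supplied as a named list or one-row data frame.
#'
#' @param record Named list or one-row data frame with patients-table fields;
#'   omitted fields are treated as missing.
#' @return Violations data frame (zero rows when valid).
#' @export
validate_record <- function(record) {
  row <- as.list(record)
  full <- stats::setNames(as.list(rep(NA_real_, length(patients_cols))),
                          patients_cols)
  full$case_id <- "record"
  full$rater_id <- "R1"
  for (nm in intersect(names(row), patients_cols)) full[[nm]] <- row[[nm]]
  validate_cohort(as.data.frame(full, stringsAsFactors = FALSE), "patients")
}

#' Write a cohort table
#'
#' Serialises the table as CSV in the documented column order.  The output is
#' deterministic and readable by [read_cohort()]; writing a table read from
#' disk reproduces the same bytes given the same dialect.
#'
#' @param cohort A cohort data frame (class `"irhpc_cohort"` or a plain data
#'   frame with the documented columns).
#' @param path Output file path.
#' @param table_kind Table layout; defaults to the cohort's own `kind`
#'   attribute.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path,
                         table_kind = attr(cohort, "kind") %||% "patients") {
  expected <- cohort_schema(table_kind)
  miss <- setdiff(expected, names(cohort))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(cohort)[, expected, drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
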