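# Independent oracles used across the suite.

# brute-force pairwise agreement: explicit double loop over cases and
# unordered rater pairs, deliberately naive
brute_force_opa <- function(m) {
  n_pairs <- 0L
  n_conc <- 0L
  for (i in seq_len(nrow(m))) {
    for (a in seq_len(ncol(m) - 1)) {
      for (b in (a + 1):ncol(m)) {
        if (is.na(m[i, a]) || is.na(m[i, b])) next
        n_pairs <- n_pairs + 1L
        if (m[i, a] == m[i, b]) n_conc <- n_conc + 1L
      }
    }
  }
  list(n_pairs = n_pairs, n_concordant = n_conc)
}

# small valid patients row for validation tests
valid_patient_row <- function() {
  list(case_id = "C01", rater_id = "R1",
       til_grade = 2, eos_grade = 1, neut_grade = 0, dense_plasma = 1,
       rvt_area = 10, necrosis_area = 20, regression_area = 70,
       immune_activated_rvt_pct = 80,
       neutrophil_count = 4, leukocyte_count = 8,
       dfs_months = 24, dfs_event = 0, os_months = 26, os_event = 0,
       death_unrelated = 0)
}
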