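test_that("well-formed tables parse with zero violations and round-trip", {
  ex <- example_cohort()
  for (kind in c("patients", "pdl1")) {
    tab <- ex[[kind]]
    expect_identical(nrow(cohort_violations(tab)), 0L)
    f <- withr::local_tempfile(fileext = ".csv")
    write_cohort(tab, f)
    back <- read_cohort(f, kind)
    expect_equal(as.data.frame(back), as.data.frame(tab))
    # re-serialisation is byte-stable
    f2 <- withr::local_tempfile(fileext = ".csv")
    write_cohort(back, f2)
    expect_identical(readLines(f), readLines(f2))
  }
})

test_that("a small hand-written CSV parses row by row", {
  f <- withr::local_tempfile(fileext = ".csv")
  hdr <- paste(c("case_id", "rater_id", "til_grade", "eos_grade", "neut_grade",
                 "dense_plasma", "rvt_area", "necrosis_area", "regression_area",
                 "immune_activated_rvt_pct", "neutrophil_count",
                 "leukocyte_count", "dfs_months", "dfs_event", "os_months",
                 "os_event", "death_unrelated"), collapse = ",")
  writeLines(c(hdr,
               "A,R1,2,1,0,1,10,20,70,80,4,8,24,0,26,0,0",
               "A,R2,1,1,0,1,10,20,70,80,4,8,24,0,26,0,0",
               "B,R1,0,0,3,0,50,0,50,,6,8,12,1,14,1,0"), f)
  ch <- read_cohort(f, "patients")
  expect_identical(nrow(ch), 3L)
  expect_identical(nrow(cohort_violations(ch)), 0L)
  expect_true(is.na(ch$immune_activated_rvt_pct[3]))
})

test_that("schema errors reject the file outright", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("case_id,viable_tumour_cells", "A,500"), f)
  expect_error(read_cohort(f, "pdl1"), "missing required column")
  writeLines(c("case_id,viable_tumour_cells,tps_percent,eos_both_compartments,extra",
               "A,500,10,1,x"), f)
  expect_error(read_cohort(f, "pdl1"), "unknown column")
  expect_error(read_cohort(file.path(tempdir(), "nope.csv"), "patients"),
               "file not found")
})

test_that("out-of-range values become violations naming row and field", {
  ex <- example_cohort()
  df <- as.data.frame(ex$patients)
  df$til_grade[1] <- 4
  df$rvt_area[5] <- -1
  v <- validate_cohort(df, "patients")
  expect_true(any(v$row == 1 & v$field == "til_grade" &
                    grepl("0..3", v$rule, fixed = TRUE)))
  expect_true(any(v$row == 5 & v$field == "rvt_area"))
})

test_that("validate_record covers the blood-count and empty-bed invariants", {
  rec <- valid_patient_row()
  expect_identical(nrow(validate_record(rec)), 0L)
  bad <- rec; bad$neutrophil_count <- 9
  v <- validate_record(bad)
  expect_true(any(v$field == "leukocyte_count" & grepl("exceed", v$rule)))
  bad <- rec; bad$rvt_area <- 0; bad$necrosis_area <- 0; bad$regression_area <- 0
  v <- validate_record(bad)
  expect_true(any(grepl("tumour bed empty", v$rule)))
  bad <- rec; bad$dense_plasma <- 2
  expect_true(any(validate_record(bad)$field == "dense_plasma"))
  bad <- rec; bad$dfs_months <- -3
  expect_true(any(validate_record(bad)$field == "dfs_months"))
  bad <- rec; bad$tps <- NULL  # irrelevant field silently ignored
  expect_identical(nrow(validate_record(bad)), 0L)
})

test_that("duplicate (case, rater) rows are flagged", {
  df <- rbind(as.data.frame(valid_patient_row()),
              as.data.frame(valid_patient_row()))
  v <- validate_cohort(df, "patients")
  expect_true(any(grepl("unique", v$rule)))
})

test_that("an empty cohort writes a header-only file", {
  ex <- example_cohort()
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(as.data.frame(ex$pdl1)[0, ], f, table_kind = "pdl1")
  expect_identical(length(readLines(f)), 1L)
  expect_identical(nrow(read_cohort(f, "pdl1")), 0L)
})
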