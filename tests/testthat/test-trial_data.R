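test_that("lesion tables round-trip through delimited text with validation", {
  rec <- make_records("P1", c("L1", "L1", "L2"), "liver", "metastatic",
                      c(0, 8, 0), c(30, 25, 12))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(rec, path, row.names = FALSE)
  got <- read_lesion_table(path)
  expect_equal(nrow(got), 3)
  expect_equal(got$size, c(30, 25, 12))

  # column-name mapping
  rec2 <- rec
  names(rec2)[names(rec2) == "size"] <- "TUMSIZE"
  write.csv(rec2, path, row.names = FALSE)
  got2 <- read_lesion_table(path, col_map = c(size = "TUMSIZE"))
  expect_equal(got2, got)
})

test_that("invalid rows are rejected with row-indexed diagnostics", {
  rec <- make_records("P1", "L1", "liver", "metastatic", c(0, 8), c(30, -4))
  expect_error(validate_lesion_records(rec), "negative size.*2")

  dup <- make_records("P1", "L1", "liver", "metastatic", c(0, 0), c(30, 31))
  expect_error(validate_lesion_records(dup), "duplicated.*P1, L1, 0")

  path <- withr::local_tempfile(fileext = ".csv")
  bad <- make_records("P1", "L1", "liver", "metastatic", 0, 30)
  bad$size <- NULL
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_lesion_table(path), "missing required column.*size")

  nonnum <- make_records("P1", "L1", "liver", "metastatic", c(0, 8), c(30, 20))
  nonnum$time <- c("0", "eight")
  expect_error(validate_lesion_records(nonnum), "non-numeric time.*2")

  mixed <- make_records(c("P1", "P1"), c("L1", "L2"), "liver", "metastatic",
                        c(0, 0), c(30, 20))
  mixed$metric <- c("SLD", "SOPD")
  expect_error(validate_lesion_records(mixed), "metric must be constant")
})

test_that("preprocessing applies the baseline-only and post-surgery exclusions", {
  rec <- rbind(
    make_records("A", "L1", "liver", "metastatic", c(0, 8, 16), c(30, 25, 22)),
    make_records("B", "L1", "lung", "metastatic", 0, 15),          # baseline only
    make_records("C", "L1", "liver", "metastatic", c(0, 8, 16), c(40, 30, 20))
  )
  cov <- make_covariates(c("A", "B", "C"),
                         surgery_time = c(NA, NA, 10))
  out <- preprocess_lesions(rec, cov)

  # B dropped entirely; C loses its post-surgery visit, keeps t = {0, 8}
  expect_false("B" %in% out$records$patient_id)
  expect_equal(sort(out$records$time[out$records$patient_id == "C"]), c(0, 8))
  # A untouched
  expect_equal(sum(out$records$patient_id == "A"), 3)
  expect_equal(out$report$n_patients_baseline_only, 1)
  expect_equal(out$report$n_records_post_surgery, 1)
  expect_equal(out$report$n_records_in,
               out$report$n_records_out + out$report$n_records_removed)

  # surgery truncation that leaves only baseline re-triggers the first rule
  rec2 <- make_records("D", "L1", "liver", "metastatic", c(0, 8), c(30, 25))
  cov2 <- make_covariates("D", surgery_time = 4)
  out2 <- preprocess_lesions(rec2, cov2)
  expect_equal(nrow(out2$records), 0)
  expect_equal(out2$report$n_patients_baseline_only_after_surgery, 1)
})

test_that("preprocessing is idempotent and errors on unknown patients", {
  sim <- simulate_trial(sim_config(n_patients = 40, seed = 3))
  rec <- validate_lesion_records(sim$records)
  once <- preprocess_lesions(rec, sim$covariates)
  twice <- preprocess_lesions(once$records, sim$covariates)
  expect_equal(twice$records, once$records)
  expect_equal(twice$report$n_records_removed, 0)
  expect_lte(nrow(once$records), nrow(rec))

  expect_error(preprocess_lesions(rec, sim$covariates[-1, ]),
               "covariates missing for patient")
})

test_that("build_series sorts by time and preserves the record multiset", {
  rec <- make_records("P1", c("L1", "L1", "L2", "L2"), "liver", "metastatic",
                      c(8, 0, 0, 8), c(25, 30, 10, 8))
  series <- build_series(rec)
  expect_equal(names(series), "P1")
  expect_equal(names(series$P1), c("L1", "L2"))
  expect_equal(series$P1$L1$times, c(0, 8))
  expect_equal(series$P1$L1$sizes, c(30, 25))
  expect_equal(build_series(rec[0, ]), list())

  # flattening a simulated dataset reproduces the preprocessed records
  sim <- simulate_trial(sim_config(n_patients = 30, seed = 9))
  pre <- preprocess_lesions(validate_lesion_records(sim$records),
                            sim$covariates)
  series <- build_series(pre$records)
  flat <- do.call(rbind, lapply(series, function(lesions) {
    do.call(rbind, lapply(lesions, function(s) {
      data.frame(patient_id = s$patient_id, lesion_id = s$series_id,
                 time = s$times, size = s$sizes, stringsAsFactors = FALSE)
    }))
  }))
  a <- flat[order(flat$patient_id, flat$lesion_id, flat$time), ]
  b <- pre$records[order(pre$records$patient_id, pre$records$lesion_id,
                         pre$records$time),
                   c("patient_id", "lesion_id", "time", "size")]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("total tumor size uses nearest-visit matching within tolerance", {
  rec <- make_records("P1", c("L1", "L1", "L2", "L2"), "liver", "metastatic",
                      c(0, 7.5, 0, 9), c(30, 26, 20, 18))
  series <- build_series(rec)
  expect_equal(unname(total_ts(series, 0, 0)), 50)      # 30 + 20 at baseline
  # t=8, tolerance 2: candidate visits 7.5 and 9; 7.5 is nearer; only L1
  # measured there
  cand <- c(7.5, 9)
  expect_equal(cand[which.min(abs(cand - 8))], 7.5)
  expect_equal(unname(total_ts(series, 8, 2)), 26)
  expect_true(is.na(total_ts(series, 20, 2)))
})
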