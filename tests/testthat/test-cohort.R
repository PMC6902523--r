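# Data model, CSV round-trips, pulse-pressure derivation, z-normalization.

test_that("cohort CSV round-trip is the identity up to float formatting", {
  coh <- vital_cohort(list(make_record("a", 1L, seed = 1),
                           make_record("b", 0L, seed = 2)), "synthetic")
  sp <- tempfile(fileext = ".csv"); lp <- tempfile(fileext = ".csv")
  write_cohort(coh, sp, lp)
  back <- read_cohort(sp, lp)
  expect_s3_class(back, "vital_cohort")
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_equal(back$records[[i]]$label, coh$records[[i]]$label)
    expect_named(back$records[[i]]$series, INDICATORS)
    for (ind in INDICATORS) {
      expect_equal(back$records[[i]]$series[[ind]]$values,
                   coh$records[[i]]$series[[ind]]$values, tolerance = 1e-10)
      expect_equal(back$records[[i]]$series[[ind]]$times,
                   coh$records[[i]]$series[[ind]]$times)
    }
  }
})

test_that("read_cohort enforces its contracts", {
  coh <- vital_cohort(list(make_record("a", 1L), make_record("orphan", 0L)),
                      "synthetic")
  sp <- tempfile(fileext = ".csv"); lp <- tempfile(fileext = ".csv")
  write_cohort(coh, sp, lp)
  lab <- read.csv(lp, colClasses = "character")
  write.csv(lab[lab$patient_id != "orphan", ], lp, row.names = FALSE,
            quote = FALSE)
  expect_error(read_cohort(sp, lp), "orphan")

  # unsorted times are sorted with a warning
  write_cohort(coh, sp, lp)
  ser <- read.csv(sp, colClasses = "character")
  ser <- ser[rev(seq_len(nrow(ser))), ]
  write.csv(ser, sp, row.names = FALSE, quote = FALSE)
  w <- capture_warnings(back <- read_cohort(sp, lp))
  expect_true(any(grepl("sort", w)))
  for (r in back$records)
    for (s in r$series) expect_false(is.unsorted(s$times, strictly = TRUE))

  # non-numeric value is a hard error with a row number
  writeLines(c("patient_id,indicator,t_seconds,value",
               "a,hr,0,75", "a,hr,60,oops"), sp)
  writeLines(c("patient_id,label", "a,1"), lp)
  expect_error(read_cohort(sp, lp), "row 3")

  # unknown indicators rejected with a report
  writeLines(c("patient_id,indicator,t_seconds,value",
               "a,hr,0,75", "a,resp,0,16"), sp)
  expect_warning(back <- read_cohort(sp, lp), "resp")
  expect_named(back$records[[1]]$series, "hr")
})

test_that("derive_pp is systolic minus diastolic on the timestamp intersection", {
  t <- c(0, 60)
  rec <- patient_record("p", 0L, list(
    nisysbp = vital_series("nisysbp", t, c(120, 130)),
    nidiasbp = vital_series("nidiasbp", t, c(80, 85))))
  pp <- derive_pp(rec)$series$pp
  expect_equal(pp$values, c(40, 45))

  # equal pressures give all-zero pp
  rec2 <- patient_record("p", 0L, list(
    nisysbp = vital_series("nisysbp", t, c(100, 100)),
    nidiasbp = vital_series("nidiasbp", t, c(100, 100))))
  expect_equal(derive_pp(rec2)$series$pp$values, c(0, 0))

  # partial timestamp overlap keeps only the intersection
  rec3 <- patient_record("p", 0L, list(
    nisysbp = vital_series("nisysbp", c(0, 60), c(120, 125)),
    nidiasbp = vital_series("nidiasbp", c(60, 120), c(70, 72))))
  pp3 <- derive_pp(rec3)$series$pp
  expect_equal(pp3$times, 60)
  expect_equal(pp3$values, 55)

  # no overlap at all is an error
  rec4 <- patient_record("p", 0L, list(
    nisysbp = vital_series("nisysbp", c(0, 30), c(120, 125)),
    nidiasbp = vital_series("nidiasbp", c(45, 90), c(70, 72))))
  expect_error(derive_pp(rec4), "intersection")

  # integer-valued inputs give integer pp exactly
  set.seed(3)
  sysv <- sample(100:140, 20, replace = TRUE)
  diav <- sample(60:80, 20, replace = TRUE)
  rec5 <- patient_record("p", 0L, list(
    nisysbp = make_series(sysv, "nisysbp"),
    nidiasbp = make_series(diav, "nidiasbp")))
  expect_identical(derive_pp(rec5)$series$pp$values, as.numeric(sysv - diav))
})

test_that("z-normalization gives population mean 0 and sd 1", {
  z <- zscore_normalize(make_series(c(2, 4, 6)))
  expect_equal(z$values, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)

  # idempotent on an already standardized series
  z2 <- zscore_normalize(z)
  expect_equal(z2$values, z$values, tolerance = 1e-12)

  expect_error(zscore_normalize(make_series(c(5, 5, 5))), "constant")

  # property: any non-constant series
  set.seed(9)
  for (i in 1:25) {
    n <- sample(3:200, 1)
    v <- rnorm(n, runif(1, -50, 50), runif(1, 0.1, 20))
    zz <- zscore_normalize(make_series(v))$values
    expect_lt(abs(mean(zz)), 1e-9)
    expect_lt(abs(sqrt(mean((zz - mean(zz))^2)) - 1), 1e-9)
  }
})

test_that("completeness is flagged, not silently dropped", {
  rec <- patient_record("p", 1L,
                        list(hr = make_series(c(70, 72, 75))))
  expect_false(is_complete(rec))
  coh <- vital_cohort(list(rec, make_record("q", 0L)), "synthetic")
  expect_message(kept <- complete_records(coh), "1 incomplete")
  expect_length(kept, 1L)
  expect_equal(kept$records[[1]]$patient_id, "q")
})
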