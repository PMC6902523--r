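# The 90-feature statistical representation and its filter.

test_that("base_stats matches hand-evaluated examples", {
  s <- base_stats(c(1, 2, 3))
  expect_equal(s[["mean"]], 2)
  expect_equal(s[["skew"]], 0)

  # percentile at rank (n+1)p: for n = 7, perc25 sits at rank 2
  s7 <- base_stats(as.numeric(1:7))
  expect_equal(s7[["perc25"]], 2)
  expect_equal(s7[["perc50"]], 4)
  expect_equal(s7[["perc75"]], 6)

  # population, non-excess kurtosis: +-1 alternating series has kurt 1
  s4 <- base_stats(c(-1, 1, -1, 1))
  expect_equal(s4[["mean"]], 0)
  expect_equal(s4[["std"]], 1)
  expect_equal(s4[["kurt"]], 1)

  # large standard-normal sample: kurtosis tends to 3 (not 0)
  set.seed(4)
  expect_equal(base_stats(rnorm(1e5))[["kurt"]], 3, tolerance = 0.1)

  expect_error(base_stats(numeric(0)), "empty")
  flat <- base_stats(rep(2, 5))
  expect_equal(flat[["skew"]], 0)
  expect_equal(flat[["kurt"]], 0)
  expect_true(attr(flat, "degenerate"))
})

test_that("base_stats agrees with the direct-summation oracle", {
  set.seed(21)
  for (i in 1:200) {
    x <- rnorm(sample(2:80, 1), runif(1, -10, 10), runif(1, 0.2, 9))
    expect_equal(unclass(base_stats(x))[1:9], bf_stats(x),
                 tolerance = 1e-12)
  }
})

test_that("first_difference is the lag-1 difference, applied once", {
  expect_equal(first_difference(c(1, 3, 6)), c(2, 3))
  expect_equal(first_difference(rep(7, 5)), rep(0, 4))
  expect_equal(first_difference(first_difference(c(1, 2, 4, 8))), c(1, 2))
  expect_error(first_difference(5), "2 points")
})

test_that("extract_features yields exactly 90 named features", {
  rec <- make_record(seed = 8)
  f <- extract_features(rec)
  expect_length(f, 90)
  expect_identical(names(f), stat_feature_names())
  expect_true(all(c("mean_hr", "min_diff_hr", "perc25_nisysbp",
                    "diff-skew_diff_hr", "kurt_nidiasbpe",
                    "diff-kurt_diff_pp") %in% names(f)))
  # recomputation oracle on random records
  for (s in 1:5) {
    r <- make_record(seed = 100 + s)
    ff <- extract_features(r)
    expect_equal(ff[["mean_hr"]], mean(r$series$hr$values))
    expect_equal(ff[["max_spo2"]], max(r$series$spo2$values))
    expect_equal(ff[["std_diff_pp"]],
                 bf_stats(diff(r$series$pp$values))[["std"]])
    expect_equal(ff[["diff-kurt_diff_nisysbp"]],
                 bf_stats(diff(r$series$nisysbp$values))[["kurt"]])
  }

  rec$series$spo2 <- NULL
  expect_error(extract_features(rec), "spo2")
})

test_that("order-free statistics are permutation invariant; diff features are not", {
  rec <- make_record(seed = 12)
  f1 <- extract_features(rec)
  set.seed(33)
  perm <- sample(length(rec$series$hr$values))
  shuf <- rec
  for (ind in INDICATORS) {
    # shuffle values with their timestamps jointly, then re-sort by time
    tt <- shuf$series[[ind]]$times[perm]
    vv <- shuf$series[[ind]]$values[perm]
    o <- order(tt)
    shuf$series[[ind]] <- vital_series(ind, tt[o], vv[o])
  }
  f2 <- extract_features(shuf)
  expect_equal(f2, f1)   # joint shuffle + re-sort is the identity

  # a value-only permutation preserves order-free stats but changes diffs
  vperm <- rec
  vv <- rec$series$hr$values[perm]
  vperm$series$hr <- vital_series("hr", rec$series$hr$times, vv)
  f3 <- extract_features(vperm)
  expect_equal(f3[["mean_hr"]], f1[["mean_hr"]])
  expect_equal(f3[["perc75_hr"]], f1[["perc75_hr"]])
  expect_equal(f3[["kurt_hr"]], f1[["kurt_hr"]])
  expect_false(isTRUE(all.equal(f3[["std_diff_hr"]], f1[["std_diff_hr"]])))
})

test_that("correlation filter removes flat and duplicated columns only", {
  set.seed(6)
  x <- as.data.frame(matrix(rnorm(40 * 6), 40, 6))
  names(x) <- paste0("f", 1:6)
  x$flat <- 1
  x$dup <- x$f1
  out <- correlation_filter(x)
  dropped <- attr(out, "dropped")
  expect_named(dropped, c("flat", "dup"), ignore.order = TRUE)
  expect_match(dropped[["flat"]], "zero variance")
  expect_true("f1" %in% colnames(out))
  expect_false("dup" %in% colnames(out))

  # independent random columns survive the default threshold
  y <- as.data.frame(matrix(rnorm(60 * 8), 60, 8))
  expect_length(attr(correlation_filter(y), "dropped"), 0)
})
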