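# Synthetic-cohort generator: determinism, class design, physiology, and the
# injected class signature.

test_that("default configuration reproduces the 84:168 case-control design", {
  cfg <- generator_config()
  expect_equal(cfg$n_pos, 84L)
  expect_equal(cfg$n_neg, 168L)
  expect_equal(cfg$duration_min * 60 / cfg$dt_s, 180)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- generator_config(n_pos = 3, n_neg = 3, seed = 77, duration_min = 60)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  d <- simulate_cohort(generator_config(n_pos = 3, n_neg = 3, seed = 78,
                                        duration_min = 60))
  expect_false(identical(a$records[[1]]$series$hr$values,
                         d$records[[1]]$series$hr$values))
})

test_that("effect = 0 makes the positive process identical to the negative", {
  cfg <- generator_config(effect = 0, duration_min = 30, seed = 5)
  set.seed(123)
  pos <- simulate_patient(cfg, 1L, "x")
  set.seed(123)
  neg <- simulate_patient(cfg, 0L, "x")
  for (ind in INDICATORS)
    expect_identical(pos$series[[ind]]$values, neg$series[[ind]]$values)
})

test_that("cohort composition and physiological sanity hold", {
  coh <- small_cohort(n_pos = 5, n_neg = 9, effect = 1.5, seed = 3,
                      duration_min = 45)
  lab <- cohort_labels(coh)
  expect_equal(sum(lab == 1), 5)
  expect_equal(sum(lab == 0), 9)
  expect_false(anyDuplicated(names(lab)) > 0)
  for (r in coh$records) {
    expect_true(is_complete(r))
    expect_true(all(r$series$spo2$values > 0 &
                      r$series$spo2$values <= 100))
    expect_true(all(r$series$pp$values > 0))
    expect_equal(r$series$pp$values,
                 r$series$nisysbp$values - r$series$nidiasbp$values)
    expect_length(r$series$hr, 45)
  }

  # all-negative cohort
  coh0 <- simulate_cohort(generator_config(n_pos = 0, n_neg = 4,
                                           duration_min = 30))
  expect_true(all(cohort_labels(coh0) == 0))
})

test_that("the injected heart-rate shift is +8 bpm per unit effect", {
  # Monte-Carlo check of the class signature at effect = 2: expected
  # difference in class means of the per-patient mean HR is 16 bpm
  coh <- simulate_cohort(generator_config(n_pos = 50, n_neg = 50, effect = 2,
                                          duration_min = 60, seed = 11))
  lab <- cohort_labels(coh)
  mhr <- vapply(coh$records, function(r) mean(r$series$hr$values), numeric(1))
  gap <- mean(mhr[lab == 1]) - mean(mhr[lab == 0])
  expect_gt(gap, 16 - 3)   # +-3 bpm sampling band for 50 per class
  expect_lt(gap, 16 + 3)
})
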