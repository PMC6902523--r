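# PAA, SAX, the rule engine, and corpus construction.

test_that("PAA matches hand-evaluated segment means", {
  expect_equal(paa(make_series(c(2, 4, 6, 8)), 2)$segment_means, c(3, 7))
  expect_equal(paa(make_series(as.numeric(1:6)), 3)$segment_means,
               c(1.5, 3.5, 5.5))
  expect_equal(paa(make_series(rep(4, 10)), 3)$segment_means, rep(4, 3))
  expect_error(paa(make_series(c(1, 2)), 5), "exceeds")
})

test_that("PAA preserves the weighted mean and stays inside the input range", {
  set.seed(14)
  for (i in 1:40) {
    n <- sample(5:120, 1)
    w <- sample(1:n, 1)
    v <- rnorm(n)
    pm <- paa(make_series(v), w)$segment_means
    expect_equal(mean(pm), mean(v), tolerance = 1e-12)  # equal segment sizes
    expect_true(all(pm >= min(v) - 1e-12 & pm <= max(v) + 1e-12))
  }
})

test_that("SAX symbols follow the equiprobable Gaussian breakpoints", {
  cfg3 <- sax_config(3)
  expect_equal(cfg3$breakpoints, qnorm(c(1, 2) / 3))
  expect_equal(sax(c(-1, 0, 1), cfg3), "abc")
  expect_equal(sax(c(0, 0, 0), cfg3), "bbb")
  # a value exactly on a breakpoint takes the upper symbol
  expect_equal(sax(qnorm(1 / 3), cfg3), "b")
  expect_equal(sax(qnorm(2 / 3), cfg3), "c")

  # marginal over a large standard-normal sample is near-uniform
  set.seed(2)
  cfg5 <- sax_config(5)
  syms <- strsplit(sax(rnorm(2e4), cfg5), "")[[1]]
  counts <- table(factor(syms, levels = letters[1:5]))
  chi <- sum((counts - 4000)^2 / 4000)
  expect_lt(chi, qchisq(0.999, df = 4))
})

test_that("the rule engine maps shape and level to the phrase vocabulary", {
  expect_equal(textualize("abc", list(mean_z = -0.2, net_z = 2), "hr"),
               "medium hr rapidly increasing")
  expect_equal(textualize("ccc", list(mean_z = 1.0, net_z = 0), "hr"),
               "high hr slowly steady")
  expect_equal(textualize("aca", list(mean_z = -0.8, net_z = 0), "hr"),
               "low hr upward peak")
  expect_equal(textualize("cba", list(mean_z = 0, net_z = -0.4), "spo2"),
               "medium spo2 slowly decreasing")
  expect_equal(textualize("bab", list(mean_z = 0, net_z = -0.1), "pp"),
               "medium pp downward varying")
  expect_error(textualize("abz", list(mean_z = 0, net_z = 0), "hr"),
               "alphabet")
  expect_error(textualize("ab", list(mean_z = 0, net_z = 0), "hr"),
               "3 symbols")
})

test_that("corpus documents have the expected word counts", {
  # 180 one-minute samples -> 60 3-min segments -> 20 words x 5 channels
  coh <- small_cohort(n_pos = 2, n_neg = 2, duration_min = 180, seed = 20)
  corpus <- build_corpus(coh)
  expect_length(corpus, 4L)
  for (d in corpus) expect_length(d$words, 100L)

  # vocabulary stays inside the closed rule vocabulary
  vocab_fields <- strsplit(unlist(lapply(corpus, `[[`, "words")), " ")
  for (w in vocab_fields) {
    expect_length(w, 4L)
    expect_true(w[1] %in% c("low", "medium", "high"))
    expect_true(w[2] %in% INDICATORS)
    expect_true(w[3] %in% c("slowly", "rapidly", "upward", "downward"))
    expect_true(w[4] %in% c("decreasing", "increasing", "steady", "peak",
                            "varying"))
  }

  # an 8-minute series yields no complete word: patient skipped with a log
  tiny <- simulate_cohort(generator_config(n_pos = 0, n_neg = 1,
                                           duration_min = 8, seed = 2))
  expect_message(c0 <- build_corpus(tiny), "skipped")
  expect_length(c0, 0L)

  # determinism
  expect_identical(build_corpus(coh), corpus)

  # per-indicator mode: one document per channel
  ci <- build_corpus(coh, per_indicator = TRUE)
  expect_length(ci, 20L)
  expect_length(ci[[1]]$words, 20L)
})
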