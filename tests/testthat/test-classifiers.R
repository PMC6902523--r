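# The eight reference classifiers: probability contract, learnability on a
# separable problem, seed determinism, and the tree's split oracle.

toy_data <- function(n = 60, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(rnorm(n, ifelse(y == 1, 2, -2), 1),
             rnorm(n, ifelse(y == 1, -1.5, 1.5), 1),
             rnorm(n))
  colnames(x) <- c("f1", "f2", "noise")
  list(x = x, y = y)
}

test_that("every classifier learns a separable problem and outputs probabilities", {
  d <- toy_data()
  for (m in c("adaboost", "dt", "gbdt", "lr", "nb", "rf", "svm", "mlp")) {
    fit <- hf_classifier(d$x, d$y, m, seed = 2)
    p <- predict(fit, d$x)
    expect_true(all(p >= 0 & p <= 1), label = m)
    expect_gt(mean((p >= 0.5) == (d$y == 1)), 0.9)
    cls <- predict(fit, d$x, type = "class")
    expect_true(all(cls %in% c(0L, 1L)), label = m)
  }
})

test_that("classifiers are deterministic under a fixed seed", {
  d <- toy_data(40, seed = 3)
  for (m in c("adaboost", "gbdt", "rf", "svm", "mlp")) {
    p1 <- predict(hf_classifier(d$x, d$y, m, seed = 9), d$x)
    p2 <- predict(hf_classifier(d$x, d$y, m, seed = 9), d$x)
    expect_identical(p1, p2, label = m)
  }
})

test_that("single-class training data is rejected", {
  d <- toy_data(20, seed = 4)
  expect_error(hf_classifier(d$x, rep(1L, 20), "dt"), "both classes")
})

test_that("the CART split matches an exhaustive impurity search", {
  # brute-force best (feature, threshold) by weighted gini on a small sample
  set.seed(5)
  x <- matrix(rnorm(40), 20, 2)
  y <- as.integer(x[, 1] + 0.3 * rnorm(20) > 0)
  gini_at <- function(j, thr) {
    part <- split(y, x[, j] <= thr)
    sum(vapply(part, function(g) {
      p <- mean(g); length(g) * 2 * p * (1 - p)
    }, numeric(1))) / length(y)
  }
  best <- list(score = Inf)
  for (j in 1:2) {
    vs <- sort(unique(x[, j]))
    for (i in seq_len(length(vs) - 1)) {
      thr <- (vs[i] + vs[i + 1]) / 2
      sc <- gini_at(j, thr)
      if (sc < best$score) best <- list(score = sc, j = j, thr = thr)
    }
  }
  tr <- vitalhf:::build_tree(x, y, max_depth = 1L)
  root <- tr$nodes[[tr$root]]
  expect_equal(root$feature, best$j)
  expect_equal(root$threshold, best$thr, tolerance = 1e-12)
  expect_equal(gini_at(root$feature, root$threshold), best$score,
               tolerance = 1e-12)
})

test_that("hf_fit returns a working model object for each representation", {
  coh <- small_cohort(n_pos = 6, n_neg = 10, effect = 2, seed = 22,
                      duration_min = 60)
  m_stat <- hf_fit(coh, "statistical", classifier = "nb", seed = 3)
  expect_s3_class(m_stat, "hf_model")
  p <- predict(m_stat, coh)
  expect_named(p, names(cohort_labels(coh)))
  expect_true(all(p >= 0 & p <= 1))
  expect_output(print(m_stat), "statistical")
  expect_output(summary(m_stat), "in-sample")
  expect_length(residuals(m_stat), 16)

  m_text <- hf_fit(coh, "text", classifier = "lr", seed = 3)
  p2 <- predict(m_text, coh)
  expect_true(all(p2 >= 0 & p2 <= 1))

  m_img <- hf_fit(coh, "image", cnn = cnn_spec(epochs = 3), seed = 3)
  p3 <- predict(m_img, coh)
  expect_true(all(p3 >= 0 & p3 <= 1))
  expect_s3_class(m_img$cnn, "cnn_model")
})
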