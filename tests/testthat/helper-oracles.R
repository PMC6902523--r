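# Independent brute-force oracles and small fixture builders.  These stay
# deliberately naive (direct summation, per-point linear scans, all-pairs
# enumeration) so they check the vectorized implementations from outside.

make_series <- function(values, indicator = "hr", dt = 60) {
  vital_series(indicator, seq(0, by = dt, length.out = length(values)),
               values)
}

make_record <- function(id = "p1", label = 0L, n = 36, seed = 1) {
  set.seed(seed)
  t <- seq(0, by = 60, length.out = n)
  sys <- 120 + rnorm(n, 0, 8)
  dia <- 70 + rnorm(n, 0, 5)
  dia <- pmin(dia, sys - 5)
  rec <- patient_record(id, label, list(
    hr = vital_series("hr", t, 75 + rnorm(n, 0, 6)),
    nisysbp = vital_series("nisysbp", t, sys),
    nidiasbp = vital_series("nidiasbp", t, dia),
    spo2 = vital_series("spo2", t, pmin(98 + rnorm(n, 0, 0.8), 100))))
  derive_pp(rec)
}

small_cohort <- function(n_pos = 6, n_neg = 12, effect = 1, seed = 42,
                         duration_min = 90) {
  simulate_cohort(generator_config(n_pos = n_pos, n_neg = n_neg,
                                   effect = effect, seed = seed,
                                   duration_min = duration_min))
}

# direct-summation statistics (population moments, rank-(n+1)p percentiles)
bf_stats <- function(x) {
  T <- length(x)
  mu <- sum(x) / T
  sigma2 <- sum((x - mu)^2) / T
  sigma <- sqrt(sigma2)
  pctl <- function(p) {
    s <- sort(x)
    h <- (T + 1) * p
    if (h <= 1) return(s[1])
    if (h >= T) return(s[T])
    lo <- floor(h)
    s[lo] + (h - lo) * (s[lo + 1] - s[lo])
  }
  skew <- if (sigma == 0) 0 else sum(((x - mu) / sigma)^3) / T
  kurt <- if (sigma == 0) 0 else sum(((x - mu) / sigma)^4) / T
  c(mean = mu, std = sigma, min = min(x), perc25 = pctl(0.25),
    perc50 = pctl(0.5), perc75 = pctl(0.75), max = max(x),
    skew = skew, kurt = kurt)
}

# per-point linear scan over every rectangle
bf_grid <- function(times, values, m, n) {
  tr <- range(times); vr <- range(values)
  counts <- matrix(0L, m, n)
  for (p in seq_along(times)) {
    placed <- FALSE
    for (i in seq_len(m)) {
      vlo <- vr[1] + (i - 1) * (vr[2] - vr[1]) / m
      vhi <- vr[1] + i * (vr[2] - vr[1]) / m
      in_row <- if (vr[2] == vr[1]) i == 1
      else (values[p] >= vlo && values[p] < vhi) ||
        (i == m && values[p] == vr[2])
      if (!in_row) next
      for (j in seq_len(n)) {
        tlo <- tr[1] + (j - 1) * (tr[2] - tr[1]) / n
        thi <- tr[1] + j * (tr[2] - tr[1]) / n
        in_col <- if (tr[2] == tr[1]) j == 1
        else (times[p] >= tlo && times[p] < thi) ||
          (j == n && times[p] == tr[2])
        if (in_col) {
          counts[i, j] <- counts[i, j] + 1L
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
  }
  counts
}

# all-pairs rank statistic, ties counted one half
bf_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
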