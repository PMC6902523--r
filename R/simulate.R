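#' Configuration for the synthetic intraoperative cohort generator
#'
#' Defaults mirror the motivating study's case-control design: 84 positive
#' (postoperative heart failure) and 168 negative patients, monitored over a
#' 180-minute operation at one sample per minute.  Channel baselines are
#' ordinary adult intraoperative values; noise is AR(1) with a slow
#' random-walk drift plus a shared latent factor that correlates the
#' haemodynamic channels.
#'
#' Positive-class patients additionally receive, scaled by `effect`:
#' * an elevated heart-rate mean (+8*effect bpm),
#' * inflated heart-rate variance (multiplied by `1 + effect`),
#' * a late linear SpO2 decline (-2*effect % over the final third),
#' * a pulse-pressure widening trend (+10*effect mmHg by end of surgery,
#'   injected through the systolic channel so that pp = nisysbp - nidiasbp
#'   still holds exactly).
#'
#' @param n_pos,n_neg class sizes (default 84 / 168).
#' @param duration_min monitored minutes (default 180).
#' @param dt_s sampling interval in seconds (default 60; monitors' true
#'   interval is not standardised, one per minute is typical of charted NIBP).
#' @param baselines named list of `c(mean, sd)` per generated channel.
#' @param ar_coeff AR(1) coefficient in `[0, 1)`.
#' @param drift_sd per-step standard deviation of the random-walk drift.
#' @param shared_sd standard deviation of the shared latent factor coupling
#'   hr/nisysbp/nidiasbp.
#' @param effect effect-size multiplier for the class signature (>= 0).
#' @param seed integer seed used by [simulate_cohort()].
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_pos = 84L, n_neg = 168L, duration_min = 180,
                             dt_s = 60,
                             baselines = list(hr = c(75, 8),
                                              nisysbp = c(120, 12),
                                              nidiasbp = c(70, 8),
                                              spo2 = c(98, 1)),
                             ar_coeff = 0.8, drift_sd = 0.3, shared_sd = 2,
                             effect = 1.0, seed = 1L) {
  stopifnot(n_pos >= 0, n_neg >= 0, duration_min > 0, dt_s > 0,
            ar_coeff >= 0, ar_coeff < 1, drift_sd >= 0, effect >= 0)
  if (!all(c("hr", "nisysbp", "nidiasbp", "spo2") %in% names(baselines)))
    stop("baselines must name hr, nisysbp, nidiasbp, spo2")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 duration_min = duration_min, dt_s = dt_s,
                 baselines = baselines, ar_coeff = ar_coeff,
                 drift_sd = drift_sd, shared_sd = shared_sd,
                 effect = effect, seed = as.integer(seed)),
            class = "generator_config")
}

# AR(1) noise with unit marginal-ish scale plus bounded random-walk drift.
ar1_drift <- function(n, sd, ar, drift_sd) {
  innov_sd <- sd * sqrt(1 - ar^2)       # stationary marginal sd == sd
  e <- stats::rnorm(n, 0, innov_sd)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  for (t in seq_len(n)[-1]) x[t] <- ar * x[t - 1] + e[t]
  x + cumsum(stats::rnorm(n, 0, drift_sd))
}

#' Simulate one labeled patient record
#'
#' Uses the current R random-number stream; [simulate_cohort()] seeds it once
#' per cohort so that a fixed `(config, seed)` pair is exactly reproducible.
#'
#' @param config a [generator_config()].
#' @param label 0 or 1.
#' @param patient_id id string for the record.
#' @return a complete `patient_record` (pp derived via [derive_pp()]).
#' @export
simulate_patient <- function(config, label, patient_id = "p1") {
  stopifnot(inherits(config, "generator_config"), label %in% c(0, 1))
  n <- as.integer(round(config$duration_min * 60 / config$dt_s))
  times <- seq(0, by = config$dt_s, length.out = n)
  eff <- if (label == 1) config$effect else 0
  b <- config$baselines

  shared <- ar1_drift(n, config$shared_sd, config$ar_coeff, 0)

  hr_sd <- b$hr[2] * sqrt(1 + eff)      # variance scales by (1 + effect)
  hr <- b$hr[1] + 8 * eff +
    ar1_drift(n, hr_sd, config$ar_coeff, config$drift_sd) + 0.5 * shared

  pp_trend <- 10 * eff * (seq_len(n) - 1) / (n - 1)  # widening via systolic
  sys <- b$nisysbp[1] + pp_trend +
    ar1_drift(n, b$nisysbp[2], config$ar_coeff, config$drift_sd) + shared
  dia <- b$nidiasbp[1] +
    ar1_drift(n, b$nidiasbp[2], config$ar_coeff, config$drift_sd) +
    0.8 * shared

  # enforce nisysbp > nidiasbp pointwise: resample the offending diastolic
  # points, then clamp any stragglers
  for (k in 1:5) {
    bad <- which(sys <= dia)
    if (!length(bad)) break
    dia[bad] <- b$nidiasbp[1] + stats::rnorm(length(bad), 0, b$nidiasbp[2] / 2)
  }
  dia <- pmin(dia, sys - 1)

  spo2 <- b$spo2[1] + ar1_drift(n, b$spo2[2], config$ar_coeff,
                                config$drift_sd / 3)
  if (eff > 0) {                         # late decline over the final third
    i0 <- floor(2 * n / 3) + 1L
    ramp <- seq(0, 1, length.out = n - i0 + 1L)
    spo2[i0:n] <- spo2[i0:n] - 2 * eff * ramp
  }
  spo2 <- pmin(spo2, 100)
  spo2 <- pmax(spo2, 1)                  # physiological floor

  rec <- patient_record(patient_id, label, list(
    hr = vital_series("hr", times, hr),
    nisysbp = vital_series("nisysbp", times, sys),
    nidiasbp = vital_series("nidiasbp", times, dia),
    spo2 = vital_series("spo2", times, spo2)))
  derive_pp(rec)
}

#' Simulate a labeled synthetic cohort
#'
#' Draws `n_pos + n_neg` patients from a single RNG stream started at
#' `config$seed`; positives first, ids `pos_001...`, `neg_001...`.
#'
#' @param config a [generator_config()].
#' @return a `vital_cohort` with provenance `"synthetic"`.
#' @export
simulate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  recs <- vector("list", config$n_pos + config$n_neg)
  i <- 0L
  for (k in seq_len(config$n_pos)) {
    i <- i + 1L
    recs[[i]] <- simulate_patient(config, 1L, sprintf("pos_%03d", k))
  }
  for (k in seq_len(config$n_neg)) {
    i <- i + 1L
    recs[[i]] <- simulate_patient(config, 0L, sprintf("neg_%03d", k))
  }
  vital_cohort(recs, "synthetic")
}
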