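# Text representation: PAA segmentation, SAX symbolization, the rule engine
# turning 3-symbol windows into clinician-readable phrases, and corpus
# construction for the topic model.

#' Piecewise aggregate approximation of a series
#'
#' Replaces a length-`N` series by `omega` segment means: segment `i` averages
#' the points whose index falls in `((N/omega)(i-1), (N/omega) i]`.  When
#' `omega` does not divide `N`, boundary points are fractionally weighted
#' between the two adjacent segments so that the size-weighted mean of the
#' segments equals the mean of the input exactly.
#'
#' @param series a `vital_series` (normally z-normalized first).
#' @param omega segment count, `1 <= omega <= N`.
#' @return an object of class `paa_series`: `segment_means` (length `omega`),
#'   `segment_span_s`, `indicator`.
#' @export
paa <- function(series, omega) {
  stopifnot(inherits(series, "vital_series"))
  v <- series$values
  n <- length(v)
  omega <- as.integer(omega)
  if (omega < 1L) stop("omega must be >= 1")
  if (omega > n) stop("omega (", omega, ") exceeds series length (", n, ")")
  means <- paa_means(v, omega)
  span <- diff(range(series$times)) / omega
  structure(list(segment_means = means, segment_span_s = span,
                 indicator = series$indicator),
            class = "paa_series")
}

# Fractional-overlap segment means: point j occupies index interval
# (j-1, j]; segment i the interval ((n/w)(i-1), (n/w) i].
paa_means <- function(v, w) {
  n <- length(v)
  seg <- n / w
  means <- numeric(w)
  for (i in seq_len(w)) {
    lo <- seg * (i - 1); hi <- seg * i
    j0 <- floor(lo) + 1L          # first point overlapping the segment
    j1 <- ceiling(hi)             # last point overlapping
    j1 <- min(j1, n)
    idx <- j0:j1
    wts <- pmin(idx, hi) - pmax(idx - 1, lo)
    means[i] <- sum(v[idx] * wts) / seg
  }
  means
}

#' SAX configuration: alphabet size and Gaussian equiprobable breakpoints
#'
#' Breakpoints are the standard-normal quantiles at `i/a`, `i = 1..a-1`, so
#' that a standard-normal value falls in each symbol's band with equal
#' probability.
#'
#' @param alphabet_size `a >= 2` (default 5).
#' @return an object of class `sax_config` with `alphabet_size` and
#'   `breakpoints`.
#' @export
sax_config <- function(alphabet_size = 5L) {
  a <- as.integer(alphabet_size)
  if (a < 2L) stop("alphabet_size must be >= 2")
  structure(list(alphabet_size = a,
                 breakpoints = stats::qnorm(seq_len(a - 1L) / a)),
            class = "sax_config")
}

#' SAX symbolization of PAA segment means
#'
#' Each segment mean maps to the letter whose band contains it: the symbol
#' index is the number of breakpoints at or below the value (a value exactly
#' equal to a breakpoint takes the upper symbol), with `'a'` the lowest band.
#'
#' @param paa a `paa_series` (or bare numeric vector of segment means).
#' @param config a [sax_config()].
#' @return a single character string of `omega` letters.
#' @export
sax <- function(paa, config = sax_config()) {
  v <- if (inherits(paa, "paa_series")) paa$segment_means else as.numeric(paa)
  bp <- config$breakpoints
  idx <- vapply(v, function(x) sum(x >= bp), integer(1))
  paste(letters[idx + 1L], collapse = "")
}

#' Rule-engine textualization of one 3-symbol window
#'
#' Produces a four-field phrase `<level> <feature> <modifier> <movement>`
#' from the window's SAX shape and z-scale statistics:
#' * movement `<pm>`: strictly ascending symbols -> `increasing`; strictly
#'   descending -> `decreasing`; all equal -> `steady`; middle strictly
#'   greatest -> `peak`; anything else -> `varying`.
#' * level `<l>`: window mean z below -0.43 -> `low`, above +0.43 -> `high`,
#'   else `medium` (the tertile breakpoints of a standard normal).
#' * modifier `<mod>`: for increasing/decreasing, `rapidly` when the absolute
#'   net z-change is >= 1 else `slowly`; for peak/varying, `upward` when the
#'   net change is >= 0 else `downward`; `steady` is always `slowly`.
#'
#' @param window_symbols exactly 3 SAX letters.
#' @param window_stats list/vector with `mean_z` and `net_z`.
#' @param indicator channel name, becomes the `<f>` field.
#' @param config the [sax_config()] whose alphabet the symbols come from.
#' @return the phrase as a single space-separated string.
#' @export
textualize <- function(window_symbols, window_stats, indicator,
                       config = sax_config()) {
  syms <- strsplit(window_symbols, "")[[1]]
  if (length(syms) != 3L) stop("textualize needs exactly 3 symbols")
  ok <- letters[seq_len(config$alphabet_size)]
  if (!all(syms %in% ok))
    stop("symbol outside alphabet: ", window_symbols)
  r <- match(syms, letters)
  pm <- if (r[1] < r[2] && r[2] < r[3]) "increasing"
  else if (r[1] > r[2] && r[2] > r[3]) "decreasing"
  else if (r[1] == r[2] && r[2] == r[3]) "steady"
  else if (r[2] > r[1] && r[2] > r[3]) "peak"
  else "varying"
  mz <- window_stats[["mean_z"]]
  nz <- window_stats[["net_z"]]
  l <- if (mz < -0.43) "low" else if (mz > 0.43) "high" else "medium"
  mod <- switch(pm,
                increasing = , decreasing = if (abs(nz) >= 1) "rapidly"
                else "slowly",
                steady = "slowly",
                if (nz >= 0) "upward" else "downward")
  paste(l, indicator, mod, pm)
}

#' Build the per-patient text corpus for a cohort
#'
#' For each complete patient and each channel: z-normalize, aggregate into
#' `window_min`-minute PAA segments (segment mean = mean of the points whose
#' timestamp falls in the window), SAX-symbolize, then turn every
#' non-overlapping run of `symbols_per_word` symbols into one phrase via
#' [textualize()] (window mean z and net z-change computed from the segment
#' means).  A patient's document concatenates the words of all five channels
#' in canonical order; patients too short for a single complete word are
#' skipped with a message.
#'
#' @param cohort a `vital_cohort`.
#' @param window_min minutes per PAA segment (default 3).
#' @param symbols_per_word symbols per phrase (default 3).
#' @param config a [sax_config()].
#' @param per_indicator if `TRUE`, emit one document per (patient, channel)
#'   instead of one concatenated document per patient.
#' @return a list of `text_document`s: `patient_id`, `words` (character
#'   vector of phrases), and for per-indicator mode an `indicator` field.
#' @export
build_corpus <- function(cohort, window_min = 3, symbols_per_word = 3L,
                         config = sax_config(), per_indicator = FALSE) {
  coh <- complete_records(cohort, quiet = TRUE)
  docs <- list()
  skipped <- character(0)
  for (rec in coh$records) {
    by_ind <- list()
    ok <- TRUE
    for (ind in INDICATORS) {
      s <- rec$series[[ind]]
      if (stats::sd(s$values) == 0) { ok <- FALSE; break }
      z <- zscore_normalize(s)
      segs <- window_segment_means(z$times, z$values, window_min * 60)
      nw <- floor(length(segs) / symbols_per_word)
      if (nw < 1L) { ok <- FALSE; break }
      words <- character(nw)
      for (k in seq_len(nw)) {
        sl <- segs[((k - 1L) * symbols_per_word + 1L):(k * symbols_per_word)]
        words[k] <- textualize(sax(sl, config),
                               list(mean_z = mean(sl),
                                    net_z = sl[length(sl)] - sl[1]),
                               ind, config)
      }
      by_ind[[ind]] <- words
    }
    if (!ok) { skipped <- c(skipped, rec$patient_id); next }
    if (per_indicator) {
      for (ind in INDICATORS)
        docs[[length(docs) + 1L]] <- structure(
          list(patient_id = rec$patient_id, indicator = ind,
               words = by_ind[[ind]]), class = "text_document")
    } else {
      docs[[length(docs) + 1L]] <- structure(
        list(patient_id = rec$patient_id,
             words = unlist(by_ind, use.names = FALSE)),
        class = "text_document")
    }
  }
  if (length(skipped))
    message(length(skipped), " patient(s) skipped (series too short or flat): ",
            paste(utils::head(skipped, 5), collapse = ", "))
  attr(docs, "skipped") <- skipped
  docs
}

# Mean of the points falling in each consecutive time window of width
# window_s, starting at the first timestamp.  Each sample is taken to cover
# one (median) sampling interval, so a series of 180 one-minute samples spans
# 180 minutes and yields exactly 60 complete 3-minute windows; trailing
# partial windows are discarded and empty windows (gaps) are dropped.
window_segment_means <- function(times, values, window_s) {
  t0 <- times[1]
  dt <- if (length(times) > 1L) stats::median(diff(times)) else 0
  nwin <- floor((times[length(times)] - t0 + dt) / window_s)
  if (nwin < 1L) return(numeric(0))
  idx <- floor((times - t0) / window_s)
  keep_pts <- idx < nwin
  sums <- tabulate_sum(idx[keep_pts] + 1L, values[keep_pts], nwin)
  cnts <- tabulate(idx[keep_pts] + 1L, nwin)
  keep <- cnts > 0
  sums[keep] / cnts[keep]
}

tabulate_sum <- function(bin, v, nbins) {
  as.numeric(rowsum(v, factor(bin, levels = seq_len(nbins)))[, 1]) |>
    (\(x) { x[is.na(x)] <- 0; x })()
}

#' Write a corpus to a tab-separated text file
#'
#' One line per document: `patient_id<TAB>word1 TAB-free phrases joined by
#' " | "`.  Human-readable export of the rule-engine output.
#'
#' @param corpus result of [build_corpus()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(corpus, function(d)
    paste0(d$patient_id, "\t", paste(d$words, collapse = " | ")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
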