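# Statistical representation: 9 moments/quantiles per series, on the raw and
# first-differenced version of each of the five channels = 90 named features.

#' Nine summary statistics of a value sequence
#'
#' Population-moment conventions throughout: mean and variance use 1/T (no
#' Bessel correction); skewness and kurtosis are the standardized third and
#' fourth central moments (kurtosis is NOT excess — a normal series gives 3).
#' Percentiles locate rank `(n+1)p` on the sorted sample with linear
#' interpolation between order statistics (the `(n+1)/4`, `(n+1)/2`,
#' `3(n+1)/4` positions), clamped to the extremes when the rank falls outside
#' `[1, n]`.
#'
#' A zero-variance series has undefined skewness/kurtosis; both are reported
#' as 0 and the result carries a `degenerate` attribute, so callers can
#' distinguish a flat channel from a symmetric one.
#'
#' @param x numeric vector, length >= 1 (>= 2 for std/skew/kurt to be
#'   meaningful).
#' @return named numeric vector
#'   `c(mean, std, min, perc25, perc50, perc75, max, skew, kurt)` with a
#'   logical `degenerate` attribute.
#' @export
base_stats <- function(x) {
  if (length(x) == 0L) stop("empty input")
  if (anyNA(x)) stop("NA in input")
  n <- length(x)
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  q <- quantile_rank_np1(x, c(0.25, 0.50, 0.75))
  degenerate <- sigma == 0
  if (degenerate) {
    skew <- 0; kurt <- 0
  } else {
    z <- (x - mu) / sigma
    skew <- mean(z^3)
    kurt <- mean(z^4)
  }
  out <- c(mean = mu, std = sigma, min = min(x),
           perc25 = q[[1]], perc50 = q[[2]], perc75 = q[[3]],
           max = max(x), skew = skew, kurt = kurt)
  attr(out, "degenerate") <- degenerate
  out
}

# Quantile at rank (n+1)p with linear interpolation (R's type-6 definition).
quantile_rank_np1 <- function(x, probs) {
  unname(stats::quantile(x, probs = probs, type = 6, names = FALSE))
}

#' First-order difference of a sequence
#'
#' @param x numeric vector of length >= 2.
#' @return `x[-1] - x[-length(x)]`, length `length(x) - 1`.
#' @export
first_difference <- function(x) {
  if (length(x) < 2L) stop("need at least 2 points to difference")
  diff(x)
}

# The 18 feature names for one indicator, in the canonical table order.
feature_names_for <- function(ind) {
  f <- FEATURE_INDICATOR_NAMES[[ind]]
  c(paste0(c("mean_", "std_", "min_", "perc25_", "perc50_", "perc75_",
             "max_"), f),
    paste0(c("mean_diff_", "std_diff_", "min_diff_", "perc25_diff_",
             "perc50_diff_", "perc75_diff_", "max_diff_"), f),
    paste0(c("skew_", "kurt_"), f),
    paste0(c("diff-skew_diff_", "diff-kurt_diff_"), f))
}

#' All 90 statistical feature names
#' @return character vector of length 90.
#' @export
stat_feature_names <- function() {
  unlist(lapply(INDICATORS, feature_names_for), use.names = FALSE)
}

#' Extract the 90 statistical derivative variables from one patient
#'
#' For each of the five channels, [base_stats()] of the raw series and of its
#' first difference: 5 x (9 + 9) = 90 named features.  Names follow the
#' underscore-joined convention, e.g. `mean_hr`, `min_diff_hr`,
#' `perc25_nisysbp`, `diff-skew_diff_hr`.
#'
#' @param record a complete `patient_record`.
#' @return named numeric vector of length 90 with a `degenerate` attribute
#'   naming any flat series encountered.
#' @export
extract_features <- function(record) {
  stopifnot(inherits(record, "patient_record"))
  missing <- setdiff(INDICATORS, names(record$series))
  if (length(missing))
    stop("record ", record$patient_id, " missing indicator(s): ",
         paste(missing, collapse = ", "))
  out <- numeric(0)
  degen <- character(0)
  for (ind in INDICATORS) {
    v <- record$series[[ind]]$values
    raw <- base_stats(v)
    d <- base_stats(first_difference(v))
    if (isTRUE(attr(raw, "degenerate"))) degen <- c(degen, ind)
    if (isTRUE(attr(d, "degenerate"))) degen <- c(degen, paste0("diff_", ind))
    vals <- c(raw[c("mean", "std", "min", "perc25", "perc50", "perc75",
                    "max")],
              d[c("mean", "std", "min", "perc25", "perc50", "perc75", "max")],
              raw[c("skew", "kurt")], d[c("skew", "kurt")])
    names(vals) <- feature_names_for(ind)
    out <- c(out, vals)
  }
  attr(out, "degenerate") <- degen
  out
}

#' Statistical feature matrix for a cohort
#'
#' One row per complete patient (id order preserved), 90 named columns.
#'
#' @param cohort a `vital_cohort`.
#' @return a data.frame with rownames = patient ids, plus a `labels`
#'   attribute (named integer vector).
#' @export
stat_feature_matrix <- function(cohort) {
  coh <- complete_records(cohort, quiet = TRUE)
  feats <- t(vapply(coh$records, function(r) as.numeric(extract_features(r)),
                    numeric(90)))
  df <- as.data.frame(feats)
  colnames(df) <- stat_feature_names()
  rownames(df) <- vapply(coh$records, function(r) r$patient_id, character(1))
  attr(df, "labels") <- cohort_labels(coh)
  df
}

#' Correlation-based feature filter
#'
#' Drops (a) zero-variance columns, for which a Pearson correlation is
#' undefined, and (b) for every pair of remaining columns with
#' `|r| >= dedupe_threshold`, the later column of the pair.  The dropped
#' names and reasons are returned as attributes for the provenance sidecar.
#'
#' @param matrix a numeric data.frame (rows = patients).
#' @param dedupe_threshold absolute-correlation cut for near-duplicates
#'   (default 0.99).
#' @param keep_cor also return the full correlation matrix?
#' @return the filtered data.frame with attributes `dropped` (named character
#'   vector of reasons) and, optionally, `correlation`.
#' @export
correlation_filter <- function(matrix, dedupe_threshold = 0.99,
                               keep_cor = FALSE) {
  stopifnot(nrow(matrix) >= 2)
  x <- as.matrix(matrix)
  dropped <- character(0)
  sds <- apply(x, 2, stats::sd)
  zv <- sds == 0
  if (any(zv))
    dropped[colnames(x)[zv]] <- "zero variance"
  keep <- which(!zv)
  cm <- if (length(keep) >= 2) stats::cor(x[, keep, drop = FALSE]) else NULL
  if (!is.null(cm)) {
    drop_idx <- logical(length(keep))
    for (j in seq_along(keep)[-1]) {
      if (drop_idx[j]) next
      earlier <- which(!drop_idx[seq_len(j - 1)])
      if (any(abs(cm[earlier, j]) >= dedupe_threshold)) {
        drop_idx[j] <- TRUE
        dropped[colnames(cm)[j]] <-
          paste0("|r| >= ", dedupe_threshold, " with ",
                 colnames(cm)[earlier[which(abs(cm[earlier, j]) >=
                                              dedupe_threshold)[1]]])
      }
    }
    keep <- keep[!drop_idx]
  }
  out <- matrix[, keep, drop = FALSE]
  attr(out, "dropped") <- dropped
  attr(out, "labels") <- attr(matrix, "labels")
  if (keep_cor) attr(out, "correlation") <- cm
  out
}
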