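# Grid representation for time series (GRTS): partition a series'
# time-value plane into m x n rectangles and count the points per rectangle.

#' Grid representation of a single series
#'
#' The time axis is split into `n` equal-width columns over
#' `[t_min, t_max]` and the value axis into `m` equal-height rows over
#' `[v_min, v_max]` (per-series bounds by default).  Intervals are half-open
#' `[lo, hi)` except the last of each axis, which is closed so that
#' max-valued points are counted; row 1 holds the lowest values and column 1
#' the earliest times, so every point lands in exactly one rectangle and the
#' counts sum to the series length.  A constant series degenerates to a
#' single occupied row (row 1), not an error.
#'
#' @param series a `vital_series`.
#' @param m,n row (value) and column (time) counts, both >= 1.
#' @param value_range optional fixed `c(lo, hi)` value bounds for
#'   cross-patient comparability; default per-series.
#' @return object of class `grid_matrix`: integer `counts` (m x n),
#'   `value_range`, `time_range`, `indicator`.
#' @export
grid_represent <- function(series, m, n, value_range = NULL) {
  stopifnot(inherits(series, "vital_series"), m >= 1, n >= 1)
  t <- series$times; v <- series$values
  if (length(t) == 0L) stop("empty series")
  tr <- range(t)
  vr <- if (is.null(value_range)) range(v) else as.numeric(value_range)
  col <- axis_bin(t, tr[1], tr[2], n)
  row <- axis_bin(v, vr[1], vr[2], m)
  counts <- matrix(0L, m, n)
  for (i in seq_along(row)) counts[row[i], col[i]] <- counts[row[i], col[i]] + 1L
  structure(list(counts = counts, value_range = vr, time_range = tr,
                 indicator = series$indicator),
            class = "grid_matrix")
}

# Bin index in 1..k over [lo, hi): half-open cells, last cell closed.
# Degenerate axis (lo == hi) puts everything in cell 1.
axis_bin <- function(x, lo, hi, k) {
  if (hi == lo) return(rep(1L, length(x)))
  idx <- floor((x - lo) * k / (hi - lo)) + 1L
  idx[idx > k] <- k                       # x == hi falls in the closed last cell
  idx[idx < 1L] <- 1L                     # guard for fixed ranges narrower than data
  as.integer(idx)
}

#' @export
print.grid_matrix <- function(x, ...) {
  cat(sprintf("<grid_matrix> %s %dx%d, %d points\n", x$indicator,
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Fuse the five channel grids of one patient into a (5, m, n) tensor
#'
#' Channels are stacked in the canonical order [INDICATORS] regardless of the
#' record's internal ordering.  With `normalize = TRUE` (default, for
#' training stability) each channel is divided by its maximum cell count so
#' all entries lie in `[0, 1]`; unnormalized tensors keep raw integer counts
#' whose per-channel sums equal the channel lengths.
#'
#' @param record a complete `patient_record`.
#' @param m,n grid dimensions (default 16 x 16: power-of-two for clean 2x2
#'   pooling in the downstream network).
#' @param normalize divide each channel by its max cell count?
#' @return numeric array of shape `(5, m, n)` with attribute `indicators`.
#' @export
fuse_channels <- function(record, m = 16L, n = 16L, normalize = TRUE) {
  stopifnot(inherits(record, "patient_record"))
  missing <- setdiff(INDICATORS, names(record$series))
  if (length(missing))
    stop("record ", record$patient_id, " missing indicator(s): ",
         paste(missing, collapse = ", "))
  out <- array(0, dim = c(5L, m, n))
  for (ci in seq_along(INDICATORS)) {
    g <- grid_represent(record$series[[INDICATORS[ci]]], m, n)$counts
    if (normalize) {
      mx <- max(g)
      if (mx > 0) g <- g / mx
    }
    out[ci, , ] <- g
  }
  attr(out, "indicators") <- INDICATORS
  out
}

#' Grid tensors for a whole cohort
#'
#' @param cohort a `vital_cohort`.
#' @inheritParams fuse_channels
#' @return array of shape `(N, 5, m, n)` with `dimnames` patient ids on the
#'   first axis and a `labels` attribute.
#' @export
grid_tensor_cohort <- function(cohort, m = 16L, n = 16L, normalize = TRUE) {
  coh <- complete_records(cohort, quiet = TRUE)
  N <- length(coh$records)
  out <- array(0, dim = c(N, 5L, m, n))
  for (i in seq_len(N)) out[i, , , ] <- fuse_channels(coh$records[[i]], m, n,
                                                      normalize)
  dimnames(out) <- list(vapply(coh$records, function(r) r$patient_id,
                               character(1)), NULL, NULL, NULL)
  attr(out, "labels") <- cohort_labels(coh)
  out
}
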