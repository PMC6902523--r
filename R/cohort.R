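#' @useDynLib vitalhf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats qnorm quantile rnorm runif sd var cor predict glm binomial
#'   plogis aggregate rbinom setNames coef
#' @importFrom utils read.csv write.csv head tail
NULL

#' Canonical vital-sign indicator names, in fixed channel order
#'
#' Heart rate, non-invasive systolic and diastolic blood pressure, SpO2 and
#' pulse pressure.  All multi-channel containers (documents, grid tensors,
#' feature vectors) use this ordering.
#' @export
INDICATORS <- c("hr", "nisysbp", "nidiasbp", "spo2", "pp")

# Historical spelling used in feature names for the diastolic channel.
FEATURE_INDICATOR_NAMES <- c(hr = "hr", nisysbp = "nisysbp",
                             nidiasbp = "nidiasbpe", spo2 = "spo2", pp = "pp")

#' Construct a single-indicator vital-sign series
#'
#' A `vital_series` is one indicator's timestamped measurement sequence for
#' one patient: times in seconds since series start (strictly increasing) and
#' real-valued measurements (bpm, mmHg or %).
#'
#' @param indicator one of [INDICATORS].
#' @param times numeric vector of seconds, strictly increasing.
#' @param values numeric vector, same length as `times`.
#' @return an object of class `vital_series`.
#' @export
vital_series <- function(indicator, times, values) {
  indicator <- match.arg(indicator, INDICATORS)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) < 1L)
    stop("a vital_series needs at least one point")
  if (any(is.na(times)) || any(is.na(values)))
    stop("NA in times or values")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (indicator == "spo2" && (any(values < 0) || any(values > 100)))
    stop("spo2 values must lie in [0, 100]")
  structure(list(indicator = indicator, times = times, values = values),
            class = "vital_series")
}

#' @export
length.vital_series <- function(x) length(x$times)

#' @export
print.vital_series <- function(x, ...) {
  cat(sprintf("<vital_series> %s: %d points over %.1f min\n",
              x$indicator, length(x$times), diff(range(x$times)) / 60))
  invisible(x)
}

#' Construct a labeled patient record
#'
#' Bundles up to five indicator series for one patient with a heart-failure
#' label (`1` = postoperative heart failure, `0` = none).  Records missing any
#' of the five indicators are flagged as incomplete rather than rejected;
#' modelling pipelines exclude incomplete records with a logged count, the
#' policy applied to the 15 incompletely monitored cases in the motivating
#' cohort.
#'
#' @param patient_id opaque string id.
#' @param label 0 or 1.
#' @param series named list of `vital_series`, names from [INDICATORS].
#' @return an object of class `patient_record`.
#' @export
patient_record <- function(patient_id, label, series) {
  stopifnot(length(patient_id) == 1L, label %in% c(0L, 1L))
  if (is.null(names(series)) || !all(names(series) %in% INDICATORS))
    stop("series must be a named list with names among: ",
         paste(INDICATORS, collapse = ", "))
  for (nm in names(series)) {
    s <- series[[nm]]
    if (!inherits(s, "vital_series") || s$indicator != nm)
      stop("series element '", nm, "' is not a vital_series of that indicator")
  }
  series <- series[intersect(INDICATORS, names(series))]  # canonical order
  structure(list(patient_id = as.character(patient_id),
                 label = as.integer(label), series = series),
            class = "patient_record")
}

#' Is a patient record complete (all five indicators present)?
#' @param record a `patient_record`.
#' @return logical.
#' @export
is_complete <- function(record) {
  stopifnot(inherits(record, "patient_record"))
  all(INDICATORS %in% names(record$series))
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s label=%d [%s]%s\n", x$patient_id, x$label,
              paste(names(x$series), collapse = ","),
              if (is_complete(x)) "" else " (incomplete)"))
  invisible(x)
}

#' Construct a cohort dataset
#'
#' @param records list of `patient_record`s with unique ids.
#' @param provenance `"synthetic"` or `"file"`.
#' @return an object of class `vital_cohort`.
#' @export
vital_cohort <- function(records, provenance = c("synthetic", "file")) {
  provenance <- match.arg(provenance)
  ids <- vapply(records, function(r) r$patient_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate patient_ids in cohort")
  structure(list(records = records, provenance = provenance),
            class = "vital_cohort")
}

#' @export
length.vital_cohort <- function(x) length(x$records)

#' Cohort labels, named by patient id
#' @param cohort a `vital_cohort`.
#' @return named integer vector.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$records, function(r) r$label, integer(1),
         USE.NAMES = FALSE) |>
    stats::setNames(vapply(cohort$records, function(r) r$patient_id,
                           character(1)))
}

#' @export
print.vital_cohort <- function(x, ...) {
  lab <- cohort_labels(x)
  cat(sprintf("<vital_cohort> %d records (%d positive, %d negative), %s\n",
              length(lab), sum(lab == 1), sum(lab == 0), x$provenance))
  ninc <- sum(!vapply(x$records, is_complete, logical(1)))
  if (ninc > 0) cat(sprintf("  %d incomplete record(s)\n", ninc))
  invisible(x)
}

#' Keep only complete records
#'
#' @param cohort a `vital_cohort`.
#' @param quiet suppress the exclusion message.
#' @return a `vital_cohort` of complete records only.
#' @export
complete_records <- function(cohort, quiet = FALSE) {
  keep <- vapply(cohort$records, is_complete, logical(1))
  if (!all(keep) && !quiet)
    message(sum(!keep), " incomplete record(s) excluded")
  vital_cohort(cohort$records[keep], cohort$provenance)
}

#' Read a cohort from long-format series and label CSV files
#'
#' The series file has header `patient_id,indicator,t_seconds,value` (one row
#' per measurement); the labels file has header `patient_id,label` with label
#' in \{0,1\}.  Rows with an unknown indicator are rejected with a report;
#' unsorted times are sorted with a warning; a series patient missing from the
#' labels file is a hard error.
#'
#' @param series_path,labels_path CSV paths.
#' @return a `vital_cohort` with provenance `"file"`.
#' @export
read_cohort <- function(series_path, labels_path) {
  if (!file.exists(series_path)) stop("series file not found: ", series_path)
  if (!file.exists(labels_path)) stop("labels file not found: ", labels_path)
  ser <- utils::read.csv(series_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("patient_id", "indicator", "t_seconds", "value")
  if (!all(need %in% names(ser)))
    stop("series file must have columns: ", paste(need, collapse = ", "))
  lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("patient_id", "label") %in% names(lab)))
    stop("labels file must have columns: patient_id, label")

  bad_ind <- !(ser$indicator %in% INDICATORS)
  if (any(bad_ind)) {
    warning(sum(bad_ind), " row(s) with unknown indicator rejected: ",
            paste(unique(ser$indicator[bad_ind]), collapse = ", "))
    ser <- ser[!bad_ind, , drop = FALSE]
  }
  tnum <- suppressWarnings(as.numeric(ser$t_seconds))
  vnum <- suppressWarnings(as.numeric(ser$value))
  if (anyNA(tnum) || anyNA(vnum)) {
    row <- which(is.na(tnum) | is.na(vnum))[1L]
    stop("non-numeric t_seconds/value at series row ", row + 1L,
         " (counting the header)")
  }
  labs <- lab$label
  if (!all(labs %in% c("0", "1")))
    stop("labels must be 0 or 1")
  label_map <- stats::setNames(as.integer(labs), lab$patient_id)
  if (anyDuplicated(lab$patient_id)) stop("duplicate patient_id in labels file")

  missing_lab <- setdiff(unique(ser$patient_id), names(label_map))
  if (length(missing_lab))
    stop("no label for patient(s): ", paste(missing_lab, collapse = ", "))

  records <- lapply(names(label_map), function(pid) {
    rows <- ser$patient_id == pid
    slist <- list()
    for (ind in unique(ser$indicator[rows])) {
      sel <- rows & ser$indicator == ind
      tt <- tnum[sel]; vv <- vnum[sel]
      o <- order(tt)
      if (is.unsorted(tt, strictly = TRUE)) {
        warning("series for patient ", pid, " indicator ", ind,
                " not sorted by time; sorting")
        tt <- tt[o]; vv <- vv[o]
      }
      slist[[ind]] <- vital_series(ind, tt, vv)
    }
    patient_record(pid, label_map[[pid]], slist)
  })
  vital_cohort(records, "file")
}

#' Write a cohort to the series/labels CSV dialects
#'
#' Inverse of [read_cohort()] up to float formatting.
#'
#' @param cohort a `vital_cohort`.
#' @param series_path,labels_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, series_path, labels_path) {
  rows <- lapply(cohort$records, function(r) {
    do.call(rbind, lapply(r$series, function(s) {
      data.frame(patient_id = r$patient_id, indicator = s$indicator,
                 t_seconds = s$times, value = s$values,
                 stringsAsFactors = FALSE)
    }))
  })
  ser <- do.call(rbind, rows)
  lab <- data.frame(patient_id = vapply(cohort$records,
                                        function(r) r$patient_id, character(1)),
                    label = vapply(cohort$records, function(r) r$label,
                                   integer(1)))
  utils::write.csv(ser, series_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(lab, labels_path, row.names = FALSE, quote = FALSE)
  invisible(c(series = series_path, labels = labels_path))
}

#' Derive the pulse-pressure series from systolic and diastolic pressure
#'
#' Pulse pressure is systolic minus diastolic blood pressure, computed
#' pointwise at exactly matching timestamps (the timestamp intersection of the
#' two pressure series).
#'
#' @param record a `patient_record` containing `nisysbp` and `nidiasbp`.
#' @param overwrite replace an existing `pp` series? Default `FALSE` keeps it.
#' @return the record with a `pp` series added.
#' @export
derive_pp <- function(record, overwrite = FALSE) {
  stopifnot(inherits(record, "patient_record"))
  if ("pp" %in% names(record$series) && !overwrite) return(record)
  sys <- record$series[["nisysbp"]]
  dia <- record$series[["nidiasbp"]]
  if (is.null(sys) || is.null(dia))
    stop("record needs both nisysbp and nidiasbp to derive pp")
  common <- intersect(sys$times, dia$times)
  if (length(common) == 0L)
    stop("empty timestamp intersection between nisysbp and nidiasbp")
  common <- sort(common)
  pv <- sys$values[match(common, sys$times)] -
    dia$values[match(common, dia$times)]
  record$series[["pp"]] <- vital_series("pp", common, pv)
  record$series <- record$series[intersect(INDICATORS, names(record$series))]
  record
}

#' Z-normalize a series to mean 0 and (population) standard deviation 1
#'
#' Uses the population (1/N) standard deviation, the convention under which
#' discretization breakpoints for SAX assume standard-normal segment values.
#'
#' @param series a `vital_series` with at least 2 points.
#' @return a `vital_series` with the same times and standardized values.
#' @export
zscore_normalize <- function(series) {
  stopifnot(inherits(series, "vital_series"))
  v <- series$values
  if (length(v) < 2L) stop("need at least 2 points to z-normalize")
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  if (sigma == 0) stop("constant series cannot be z-normalized")
  series$values <- (v - mu) / sigma
  series
}
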