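# Provenance sidecars: every exported artifact (cohort CSVs, feature
# matrices, topic matrices, reports) can carry a JSON sidecar recording the
# configuration and seed that produced it, so a run can be reproduced
# exactly from the sidecar alone.

#' Write a provenance sidecar next to an artifact
#'
#' @param artifact_path the artifact the sidecar describes; the sidecar is
#'   written at `<artifact_path>.json`.
#' @param config named list of configuration (coerced to JSON; classed
#'   config objects are unclassed).
#' @return invisibly, the sidecar path.
#' @export
write_provenance <- function(artifact_path, config) {
  path <- paste0(artifact_path, ".json")
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  jsonlite::write_json(strip(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a provenance sidecar
#'
#' @param artifact_path artifact whose `<path>.json` sidecar to read.
#' @return named list.
#' @export
read_provenance <- function(artifact_path) {
  jsonlite::read_json(paste0(artifact_path, ".json"), simplifyVector = TRUE)
}

#' Export a feature matrix as CSV plus provenance sidecar
#'
#' First column `patient_id`, then the named feature columns.
#'
#' @param features data.frame with patient ids as rownames.
#' @param path output CSV path.
#' @param config configuration list recorded in the sidecar.
#' @return invisibly, `path`.
#' @export
export_features <- function(features, path, config = list()) {
  df <- cbind(patient_id = rownames(features), as.data.frame(features))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  write_provenance(path, config)
  invisible(path)
}
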