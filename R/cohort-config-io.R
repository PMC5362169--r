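#' Read a simulator configuration from a YAML or JSON file
#'
#' Loads named fields for [cohort_config()] from a config file; fields not
#' present fall back to the package defaults. `feature_prevalences` and
#' `effect_coefficients` must be named maps. Files ending in `.json` are
#' parsed as JSON, anything else as YAML.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `cohort_config`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines(c("n_patients: 50", "seed: 7", "trajectory_coefficient: 0.3"), f)
#' read_cohort_config(f)$n_patients
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop_data(paste0("config file not found: ", path))
  fields <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(fields)) stop_schema("config file must contain a mapping")
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(fields), known)
  if (length(unknown) > 0) {
    stop_schema(paste0("unknown config field(s): ",
                       paste(unknown, collapse = ", ")))
  }
  for (nm in c("feature_prevalences", "effect_coefficients")) {
    if (!is.null(fields[[nm]])) fields[[nm]] <- unlist(fields[[nm]])
  }
  if (!is.null(fields$followup_months)) {
    fields$followup_months <- as.numeric(unlist(fields$followup_months))
  }
  do.call(cohort_config, fields)
}
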