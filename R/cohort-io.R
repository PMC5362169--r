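#' Read a long-format visit table
#'
#' Reads the CSV interchange format (one row per patient-visit), infers
#' the feature codebook from the header, sorts rows by patient and visit
#' month, and validates the cohort invariants (binary flags, strictly
#' increasing visit times, non-decreasing SDI, constant sex). Any
#' violation aborts with a message locating the offending patient/row.
#'
#' @param path CSV file path.
#' @return An `sle_cohort` tibble (see [generate_cohort()]).
#' @export
read_visits_csv <- function(path) {
  if (!file.exists(path)) stop_data(paste0("file not found: ", path))
  tbl <- readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(patient_id = readr::col_character(),
                            sex = readr::col_character(),
                            .default = readr::col_double())
  )
  required <- c(visit_id_cols(), visit_tail_cols())
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    stop_schema(paste0("missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  codebook <- setdiff(names(tbl), required)
  for (col in c(codebook, "activity")) {
    bad <- which(!tbl[[col]] %in% c(0, 1))
    if (length(bad) > 0) {
      stop_data(paste0("non-binary value in flag column `", col,
                       "` at row ", bad[1]))
    }
  }
  tbl <- dplyr::arrange(tbl, .data$patient_id, .data$month)
  cohort <- as_sle_cohort(tbl, codebook = codebook)
  viol <- validate_cohort(cohort)
  if (nrow(viol) > 0) {
    stop_data(paste0(
      "invalid cohort file: ",
      paste(utils::head(viol$message, 5), collapse = "; ")
    ))
  }
  cohort
}

#' Write a cohort to the long-format visit CSV
#'
#' Emits one row per visit with a stable column order (id, month,
#' demographics, codebook features, activity, SDI) and deterministic row
#' order (patient, then month), so equal cohorts serialize byte-identically.
#'
#' @param cohort An `sle_cohort` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_visits_csv <- function(cohort, path) {
  codebook <- cohort_codebook(cohort)
  tbl <- dplyr::arrange(tibble::as_tibble(cohort), .data$patient_id, .data$month)
  tbl <- tbl[, c(visit_id_cols(), codebook, visit_tail_cols())]
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Check the cohort invariants, returning violations as data
#'
#' Unlike [read_visits_csv()] this never throws: every violation of the
#' longitudinal invariants is returned as a row with a locator, and a valid
#' cohort yields a zero-row tibble.
#'
#' @param cohort A cohort tibble.
#' @return Tibble with columns `type`, `patient_id`, `row`, `message`.
#'   Violation types: `sdi_decrease`, `unsorted_visits`, `negative_sdi`,
#'   `nonbinary_flag`, `sex_change`, `duplicate_id`, `too_few_visits`,
#'   `bad_first_month`.
#' @export
#' @examples
#' validate_cohort(generate_cohort(cohort_config(n_patients = 5)))
validate_cohort <- function(cohort) {
  codebook <- cohort_codebook(cohort)
  tbl <- tibble::as_tibble(cohort)
  tbl$.row <- seq_len(nrow(tbl))
  out <- list()
  note <- function(type, pid, row, msg) {
    out[[length(out) + 1]] <<- tibble::tibble(
      type = type, patient_id = pid, row = as.integer(row), message = msg
    )
  }

  for (col in c(codebook, "activity")) {
    bad <- which(!tbl[[col]] %in% c(0, 1))
    for (r in bad) {
      note("nonbinary_flag", tbl$patient_id[r], r,
           paste0("non-binary value in `", col, "` at row ", r))
    }
  }

  # duplicate ids: a patient's rows must be contiguous in the table
  runs <- rle(as.character(tbl$patient_id))
  dup <- unique(runs$values[duplicated(runs$values)])
  for (pid in dup) {
    note("duplicate_id", pid, NA,
         paste0("patient `", pid, "` appears in non-contiguous blocks"))
  }

  by_patient <- split(tbl, factor(tbl$patient_id, levels = unique(tbl$patient_id)))
  for (series in by_patient) {
    pid <- series$patient_id[1]
    if (nrow(series) < 2) {
      note("too_few_visits", pid, series$.row[1],
           paste0("patient `", pid, "` has fewer than 2 visits"))
    }
    if (series$month[1] != 0) {
      note("bad_first_month", pid, series$.row[1],
           paste0("patient `", pid, "` first visit month is ",
                  series$month[1], ", expected 0"))
    }
    if (nrow(series) >= 2) {
      noninc <- which(diff(series$month) <= 0)
      for (k in noninc) {
        note("unsorted_visits", pid, series$.row[k + 1],
             paste0("visit months not strictly increasing for `", pid,
                    "` at row ", series$.row[k + 1]))
      }
      dec <- which(diff(series$sdi) < 0)
      for (k in dec) {
        note("sdi_decrease", pid, series$.row[k + 1],
             paste0("SDI decreases for `", pid, "` at row ",
                    series$.row[k + 1]))
      }
    }
    if (any(series$sdi < 0)) {
      note("negative_sdi", pid, series$.row[which(series$sdi < 0)[1]],
           paste0("negative SDI for `", pid, "`"))
    }
    if (length(unique(series$sex)) > 1) {
      note("sex_change", pid, series$.row[1],
           paste0("sex not constant for `", pid, "`"))
    }
  }
  if (length(out) == 0) {
    tibble::tibble(type = character(), patient_id = character(),
                   row = integer(), message = character())
  } else {
    dplyr::bind_rows(out)
  }
}
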