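#' Select case patients and their pre-damage visit prefixes
#'
#' A case is a patient with SDI = 0 at the first visit who develops
#' SDI >= 1 during follow-up. For each case the returned rows are the
#' visits strictly before the first visit with a positive SDI, labelled 1.
#' Patients already damaged at baseline are excluded entirely (from cases
#' and, downstream, from controls).
#'
#' @param cohort A cohort tibble.
#' @return Tibble of visit rows (cohort columns) plus a `label` column
#'   (all 1), restricted to case prefixes.
#' @export
select_cases <- function(cohort) {
  tbl <- tibble::as_tibble(cohort)
  codebook <- cohort_codebook(cohort)
  out <- tbl |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::filter(dplyr::first(.data$sdi) == 0, any(.data$sdi >= 1)) |>
    dplyr::filter(dplyr::row_number() < which(.data$sdi >= 1)[1]) |>
    dplyr::ungroup() |>
    dplyr::mutate(label = 1L)
  attr(out, "codebook") <- codebook
  out
}

#' Select control patients and their usable visit prefixes
#'
#' A control never shows damage (SDI = 0 at every visit), has at least
#' `min_visits` visits, and enough follow-up that some visits remain after
#' reserving the final `min_horizon_months` as the damage-free
#' confirmation window. The returned prefix excludes that window, making
#' the control label semantically parallel to "no damage in the next two
#' years"; rows are labelled 0. Never-damaged patients with too short or
#' too sparse a follow-up are excluded from both groups.
#'
#' @param cohort A cohort tibble.
#' @param min_visits Minimum total visits (default 5).
#' @param min_horizon_months Damage-free confirmation window reserved at
#'   the end of follow-up (default 24 months).
#' @return Tibble of visit rows plus `label` (all 0).
#' @export
select_controls <- function(cohort, min_visits = 5, min_horizon_months = 24) {
  tbl <- tibble::as_tibble(cohort)
  codebook <- cohort_codebook(cohort)
  out <- tbl |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::filter(all(.data$sdi == 0), dplyr::n() >= min_visits) |>
    dplyr::filter(.data$month <= max(.data$month) - min_horizon_months) |>
    dplyr::ungroup() |>
    dplyr::mutate(label = 0L)
  attr(out, "codebook") <- codebook
  out
}

#' Build the labelled analysis set (cases + controls)
#'
#' Convenience wrapper binding [select_cases()] and [select_controls()];
#' the two groups are disjoint by construction.
#'
#' @inheritParams select_controls
#' @return Tibble of labelled visit rows.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 60, seed = 2))
#' sel <- select_analysis_set(cohort)
#' dplyr::count(dplyr::distinct(sel, patient_id, label), label)
select_analysis_set <- function(cohort, min_visits = 5, min_horizon_months = 24) {
  codebook <- cohort_codebook(cohort)
  out <- dplyr::bind_rows(
    select_cases(cohort),
    select_controls(cohort, min_visits = min_visits,
                    min_horizon_months = min_horizon_months)
  )
  attr(out, "codebook") <- codebook
  out
}

#' Encode labelled visit prefixes into model-ready sequences
#'
#' Turns the output of [select_analysis_set()] (or of the individual
#' selectors) into a `damage_dataset`: one feature matrix per patient with
#' columns `sex` (0 = F, 1 = M), standardized `age`, the binary codebook
#' flags, and the binarized `activity` flag. Age is centred and scaled to
#' zero mean / unit variance over all visits in the given data (tanh units
#' saturate on raw ages); the parameters are stored in the dataset so
#' held-out data can be re-encoded with training-set statistics.
#'
#' @param selection Labelled visit rows (must contain a `label` column).
#' @param codebook Feature columns to encode; defaults to the selection's
#'   codebook attribute or every non-reserved column.
#' @param age_center,age_scale Optional fixed standardization parameters
#'   (used when encoding held-out data with training statistics).
#' @return A `damage_dataset`: list with `sequences` (each a list with
#'   `patient_id`, matrix `x` of T visits x p features, and `label`),
#'   `features`, `binary` (which columns the rare-feature filter may
#'   drop), `age_col`, `age_center`, `age_scale`.
#' @export
encode_features <- function(selection, codebook = NULL,
                            age_center = NULL, age_scale = NULL) {
  if (nrow(selection) == 0) stop_data("empty selection: nothing to encode")
  if (!"label" %in% names(selection)) {
    stop_schema("`selection` must carry a `label` column")
  }
  if (is.null(codebook)) codebook <- cohort_codebook(selection)
  missing_cols <- setdiff(codebook, names(selection))
  if (length(missing_cols) > 0) {
    stop_schema(paste0("codebook features absent from data: ",
                       paste(missing_cols, collapse = ", ")))
  }
  tbl <- dplyr::arrange(tibble::as_tibble(selection),
                        .data$patient_id, .data$month)
  if (is.null(age_center)) age_center <- mean(tbl$age)
  if (is.null(age_scale)) {
    age_scale <- stats::sd(tbl$age)
    if (!is.finite(age_scale) || age_scale == 0) age_scale <- 1
  }
  features <- c("sex", "age", codebook, "activity")
  sex01 <- as.integer(tbl$sex == "M")
  age_std <- (tbl$age - age_center) / age_scale
  mat_all <- cbind(sex = sex01, age = age_std,
                   as.matrix(tbl[, codebook, drop = FALSE]),
                   activity = tbl$activity)
  colnames(mat_all) <- features
  idx <- split(seq_len(nrow(tbl)),
               factor(tbl$patient_id, levels = unique(tbl$patient_id)))
  sequences <- purrr::map2(idx, names(idx), function(rows, pid) {
    list(patient_id = pid,
         x = mat_all[rows, , drop = FALSE],
         label = as.integer(tbl$label[rows[1]]))
  })
  names(sequences) <- NULL
  new_damage_dataset(
    sequences = sequences,
    features = features,
    binary = features != "age",
    age_center = age_center,
    age_scale = age_scale
  )
}

new_damage_dataset <- function(sequences, features, binary,
                               age_center, age_scale) {
  structure(
    list(
      sequences = sequences,
      features = features,
      binary = binary,
      age_col = match("age", features),
      age_center = age_center,
      age_scale = age_scale
    ),
    class = "damage_dataset"
  )
}

dataset_labels <- function(dataset) {
  vapply(dataset$sequences, function(s) s$label, integer(1))
}

dataset_ids <- function(dataset) {
  vapply(dataset$sequences, function(s) s$patient_id, character(1))
}

#' Drop rarely observed binary features
#'
#' Removes every binary feature positive in fewer than `min_positive`
#' patients (a patient counts as positive if the flag is 1 at any visit),
#' preserving the order of the surviving features. A feature positive in
#' exactly `min_positive` patients is retained. Idempotent.
#'
#' @param dataset A `damage_dataset`.
#' @param min_positive Minimum number of ever-positive patients (default 4).
#' @param per_visit If `TRUE`, count positive visits instead of
#'   ever-positive patients.
#' @return The filtered `damage_dataset`; dropped names are recorded in
#'   `attr(, "dropped_features")`.
#' @export
filter_rare_binary_features <- function(dataset, min_positive = 4,
                                        per_visit = FALSE) {
  counts <- vapply(seq_along(dataset$features), function(j) {
    if (!dataset$binary[j]) return(Inf)
    if (per_visit) {
      sum(vapply(dataset$sequences, function(s) sum(s$x[, j] == 1), double(1)))
    } else {
      sum(vapply(dataset$sequences, function(s) any(s$x[, j] == 1), logical(1)))
    }
  }, double(1))
  keep <- counts >= min_positive
  if (any(dataset$binary) && !any(keep & dataset$binary)) {
    stop_data("all binary features removed by the rare-feature filter")
  }
  dropped <- dataset$features[!keep]
  dataset$sequences <- purrr::map(dataset$sequences, function(s) {
    s$x <- s$x[, keep, drop = FALSE]
    s
  })
  dataset$features <- dataset$features[keep]
  dataset$binary <- dataset$binary[keep]
  dataset$age_col <- match("age", dataset$features)
  attr(dataset, "dropped_features") <- dropped
  dataset
}

# Re-standardize the age column with new (center, scale), e.g. fitted on a
# training fold only. Recovers raw ages exactly from the stored parameters.
rescale_age <- function(dataset, center, scale) {
  j <- dataset$age_col
  if (is.na(j)) return(dataset)
  c0 <- dataset$age_center
  s0 <- dataset$age_scale
  dataset$sequences <- purrr::map(dataset$sequences, function(s) {
    raw <- s$x[, j] * s0 + c0
    s$x[, j] <- (raw - center) / scale
    s
  })
  dataset$age_center <- center
  dataset$age_scale <- scale
  dataset
}

# Age standardization parameters over all visits of a subset of sequences.
age_stats <- function(dataset, which = seq_along(dataset$sequences)) {
  j <- dataset$age_col
  if (is.na(j)) return(list(center = 0, scale = 1))
  raw <- unlist(purrr::map(dataset$sequences[which], function(s) {
    s$x[, j] * dataset$age_scale + dataset$age_center
  }))
  sc <- stats::sd(raw)
  list(center = mean(raw), scale = if (is.finite(sc) && sc > 0) sc else 1)
}

subset_dataset <- function(dataset, which) {
  dataset$sequences <- dataset$sequences[which]
  dataset
}

#' @export
print.damage_dataset <- function(x, ...) {
  lab <- dataset_labels(x)
  lens <- vapply(x$sequences, function(s) nrow(s$x), integer(1))
  cat("<damage_dataset>\n")
  cat("  sequences: ", length(x$sequences), " (", sum(lab == 1), " cases / ",
      sum(lab == 0), " controls)\n", sep = "")
  cat("  features:  ", length(x$features), "\n", sep = "")
  cat("  visits per sequence: ", min(lens), "-", max(lens),
      " (median ", stats::median(lens), ")\n", sep = "")
  invisible(x)
}

#' @describeIn encode_features One row per sequence: id, label, length.
#' @param x A `damage_dataset`.
#' @param ... Unused.
#' @export
tidy.damage_dataset <- function(x, ...) {
  tibble::tibble(
    patient_id = dataset_ids(x),
    label = dataset_labels(x),
    n_visits = vapply(x$sequences, function(s) nrow(s$x), integer(1))
  )
}
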