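#' Per-visit hazard of a first damage event
#'
#' Discrete-time logistic hazard: the probability that a patient with the
#' given feature flags and activity history develops a first irreversible
#' damage item over the coming visit interval. Effects are log-odds, so the
#' hazard is strictly increasing in every positive-coefficient feature and
#' in the cumulative activity count.
#'
#' @param features Named numeric (0/1) vector of per-visit feature values;
#'   must cover every name in `config$effect_coefficients`.
#' @param cumulative_activity Number of active (SLEDAI-2K >= 1) visits
#'   observed before the current one; may be a vector.
#' @param config A [cohort_config()].
#' @return Hazard probability (vectorized over `cumulative_activity`).
#' @export
#' @examples
#' cfg <- cohort_config(effect_coefficients = c(renal = 1),
#'                      baseline_log_odds = -2, trajectory_coefficient = 0.5)
#' damage_hazard(c(renal = 1), cumulative_activity = 2, config = cfg)
damage_hazard <- function(features, cumulative_activity, config) {
  coefs <- config$effect_coefficients
  missing_feats <- setdiff(names(coefs), names(features))
  if (length(missing_feats) > 0) {
    stop_data(paste0(
      "features required by `effect_coefficients` are missing: ",
      paste(missing_feats, collapse = ", ")
    ))
  }
  eta <- config$baseline_log_odds +
    sum(coefs * as.numeric(features[names(coefs)])) +
    config$trajectory_coefficient * cumulative_activity
  plogis(eta)
}

#' Simulate one patient's visit history
#'
#' Draws a single patient from the current RNG stream: a quarterly-ish
#' visit schedule with uniform jitter over a uniformly drawn follow-up,
#' static disease-history flags, a two-state Markov activity flag, age
#' advancing deterministically with time, and a first-damage event drawn
#' per visit from [damage_hazard()]. Once damage occurs the SDI stays at 1
#' for every later visit (irreversible damage); further accrual is not
#' modelled because the analysis only uses SDI = 0 versus SDI > 0.
#'
#' @param config A [cohort_config()].
#' @param patient_id Identifier for the generated series.
#' @return Tibble of visit rows for one patient (see [generate_cohort()]).
#' @export
sample_patient <- function(config, patient_id = "P1") {
  followup <- runif(1, config$followup_months[1], config$followup_months[2])
  gaps <- config$visit_interval_months +
    runif(200, -config$visit_jitter_months, config$visit_jitter_months)
  months <- c(0, cumsum(gaps))
  months <- months[months <= followup]
  if (length(months) < 2) months <- c(0, max(followup, config$visit_interval_months))
  t_n <- length(months)

  flags <- stats::setNames(
    rbinom(length(config$feature_prevalences), 1, config$feature_prevalences),
    names(config$feature_prevalences)
  )
  sex <- if (runif(1) < config$male_probability) "M" else "F"
  age0 <- rnorm(1, config$age_mean, config$age_sd)

  # binarized SLEDAI-2K as a symmetric two-state Markov chain
  persist <- config$activity_persistence
  activity <- integer(t_n)
  activity[1] <- rbinom(1, 1, 0.5)
  if (t_n > 1) {
    for (t in 2:t_n) {
      stay <- runif(1) < persist
      activity[t] <- if (stay) activity[t - 1] else 1L - activity[t - 1]
    }
  }

  sdi <- integer(t_n)
  cum_act <- cumsum(activity)
  for (t in 2:t_n) {
    if (sdi[t - 1] >= 1L) {
      sdi[t] <- sdi[t - 1]
      next
    }
    h <- damage_hazard(flags, cumulative_activity = cum_act[t - 1], config = config)
    sdi[t] <- if (runif(1) < h) 1L else 0L
  }

  out <- tibble::tibble(
    patient_id = patient_id,
    month = months,
    sex = sex,
    age = age0 + months / 12
  )
  out <- dplyr::bind_cols(
    out,
    tibble::as_tibble(as.list(flags))[rep(1, t_n), ]
  )
  out$activity <- activity
  out$sdi <- sdi
  out
}

#' Generate a synthetic longitudinal SLE cohort
#'
#' Produces a long-format visit table with the structure the analysis
#' assumes: one row per patient-visit, strictly increasing visit times
#' starting at month 0, static disease-history flags, a persistent
#' binarized activity flag, and a non-decreasing SDI starting at 0 whose
#' first-event probability follows the configured discrete-time hazard.
#' The result is a pure function of the config (including its seed).
#'
#' @param config A [cohort_config()].
#' @return A tibble of class `sle_cohort` with columns `patient_id`,
#'   `month`, `sex`, `age`, one 0/1 column per configured feature,
#'   `activity` and `sdi`, carrying the feature codebook in
#'   `attr(, "codebook")`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 20, seed = 7))
#' dplyr::count(cohort, patient_id)
generate_cohort <- function(config) {
  validate_cohort_config(config)
  with_seed(config$seed, {
    ids <- sprintf("P%04d", seq_len(config$n_patients))
    cohort <- purrr::map_dfr(ids, function(id) sample_patient(config, id))
    as_sle_cohort(cohort, codebook = names(config$feature_prevalences))
  })
}

as_sle_cohort <- function(tbl, codebook = NULL) {
  if (is.null(codebook)) {
    codebook <- setdiff(names(tbl), c(visit_id_cols(), visit_tail_cols()))
  }
  tbl <- tbl[, c(visit_id_cols(), codebook, visit_tail_cols())]
  structure(tbl, codebook = codebook,
            class = c("sle_cohort", class(tibble::tibble())))
}

#' Feature codebook of a cohort table
#'
#' @param cohort A cohort tibble.
#' @return Character vector of binary feature column names, in file order.
#' @export
cohort_codebook <- function(cohort) {
  cb <- attr(cohort, "codebook")
  if (is.null(cb)) {
    cb <- setdiff(names(cohort), c(visit_id_cols(), visit_tail_cols()))
  }
  cb
}
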