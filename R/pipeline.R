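#' Simulate a model-ready analysis dataset in one call
#'
#' Convenience pipeline for experiments: generates a synthetic cohort,
#' applies the case/control selection rules, encodes features and drops
#' rare binary flags. Equivalent to
#' `generate_cohort() |> select_analysis_set() |> encode_features() |>
#' filter_rare_binary_features()`.
#'
#' @param seed Cohort seed (ignored if `config` is supplied).
#' @param config Optional [cohort_config()]; defaults to the package
#'   defaults at `seed`.
#' @param min_visits,min_horizon_months Control eligibility, as in
#'   [select_controls()].
#' @param min_positive Rare-feature cutoff, as in
#'   [filter_rare_binary_features()].
#' @return A `damage_dataset`.
#' @export
#' @examples
#' ds <- simulate_analysis_dataset(seed = 1,
#'                                 config = cohort_config(n_patients = 60))
#' tidy(ds)
simulate_analysis_dataset <- function(seed = 1L, config = NULL,
                                      min_visits = 5,
                                      min_horizon_months = 24,
                                      min_positive = 4) {
  if (is.null(config)) config <- cohort_config(seed = seed)
  cohort <- generate_cohort(config)
  sel <- select_analysis_set(cohort, min_visits = min_visits,
                             min_horizon_months = min_horizon_months)
  filter_rare_binary_features(encode_features(sel),
                              min_positive = min_positive)
}

#' Subsample a dataset to fixed case/control counts
#'
#' Draws (without replacement) the requested number of cases and controls
#' from a `damage_dataset` — used to reproduce experiments at a study's
#' exact group sizes.
#'
#' @param dataset A `damage_dataset`.
#' @param n_cases,n_controls Group sizes to draw.
#' @param seed Sampling seed.
#' @return A `damage_dataset` with `n_cases + n_controls` sequences.
#' @export
sample_case_control <- function(dataset, n_cases, n_controls, seed = 1L) {
  labels <- dataset_labels(dataset)
  if (sum(labels == 1) < n_cases || sum(labels == 0) < n_controls) {
    stop_data(paste0("dataset has ", sum(labels == 1), " cases and ",
                     sum(labels == 0), " controls; cannot draw ",
                     n_cases, "/", n_controls))
  }
  with_seed(seed, {
    idx <- c(sample(which(labels == 1), n_cases),
             sample(which(labels == 0), n_controls))
    subset_dataset(dataset, sort(idx))
  })
}

#' Permute sequence labels (null-calibration experiments)
#'
#' Randomly reassigns the existing labels across sequences, destroying any
#' feature-outcome association while preserving the label balance; the
#' cross-validated AUC of any correct pipeline then has expectation 0.5.
#'
#' @param dataset A `damage_dataset`.
#' @param seed Permutation seed.
#' @return The dataset with permuted labels.
#' @export
permute_labels <- function(dataset, seed = 1L) {
  labels <- dataset_labels(dataset)
  with_seed(seed, {
    perm <- sample(labels)
    dataset$sequences <- purrr::map2(dataset$sequences, perm, function(s, l) {
      s$label <- as.integer(l)
      s
    })
  })
  dataset
}
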