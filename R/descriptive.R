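#' Summary statistics of an SDI score distribution
#'
#' Takes a damage-score histogram (score -> patient count) and returns the
#' statistics a cohort description reports: weighted mean, sample standard
#' deviation (n - 1 divisor; 0 by convention for a single patient), median
#' by cumulative counts with the midpoint convention, and the range of
#' scores with positive counts. Rounded (half-up, 1 decimal) mean and SD
#' are included alongside the exact values.
#'
#' @param dist Named numeric vector (`c("1" = 88, ...)`) or a two-column
#'   data frame (score, count).
#' @return One-row tibble: `n`, `mean`, `sd`, `median`, `min`, `max`,
#'   `mean_1dp`, `sd_1dp`.
#' @export
#' @examples
#' sdi_summary(c("1" = 88, "2" = 38, "3" = 10, "4" = 10, "7" = 1, "8" = 1))
sdi_summary <- function(dist) {
  if (is.data.frame(dist)) {
    scores <- as.numeric(dist[[1]])
    counts <- as.numeric(dist[[2]])
  } else {
    scores <- as.numeric(names(dist))
    counts <- as.numeric(dist)
  }
  if (length(scores) == 0 || any(is.na(scores)) || any(counts < 0) ||
      sum(counts) == 0) {
    stop_domain("`dist` must map scores to non-negative counts, not all zero")
  }
  keep <- counts > 0
  scores <- scores[keep]
  counts <- counts[keep]
  n <- sum(counts)
  m <- sum(scores * counts) / n
  s <- if (n > 1) sqrt(sum(counts * (scores - m)^2) / (n - 1)) else 0
  # median via cumulative counts (midpoint of the two central values)
  ord <- order(scores)
  scores <- scores[ord]
  counts <- counts[ord]
  cum <- cumsum(counts)
  at <- function(pos) scores[which(cum >= pos)[1]]
  med <- if (n %% 2 == 1) at((n + 1) / 2) else (at(n / 2) + at(n / 2 + 1)) / 2
  tibble::tibble(
    n = n, mean = m, sd = s, median = med,
    min = min(scores), max = max(scores),
    mean_1dp = round_half_up(m, 1), sd_1dp = round_half_up(s, 1)
  )
}

#' Percentage with half-up rounding to one decimal
#'
#' @param numerator,denominator Non-negative counts, `numerator <=
#'   denominator`, `denominator > 0`.
#' @return `100 * numerator / denominator` rounded half-up to 1 decimal.
#' @export
#' @examples
#' proportion_pct(148, 413)  # 35.8
proportion_pct <- function(numerator, denominator) {
  if (!is_count(numerator) || !is_count(denominator) || denominator == 0 ||
      numerator > denominator) {
    stop_domain("need counts with 0 <= numerator <= denominator, denominator > 0")
  }
  round_half_up(100 * numerator / denominator, 1)
}

#' Association test for a 2x2 case/control table
#'
#' Chi-square (1 df, no continuity correction unless `correct = TRUE`) or
#' Fisher's exact test (two-sided, by hypergeometric enumeration of tables
#' as or more extreme) for a feature-by-group contingency table.
#'
#' @param a,b Cases positive / cases negative.
#' @param c,d Controls positive / controls negative.
#' @param method `"chi_square"` or `"fisher_exact"`.
#' @param correct Apply the Yates continuity correction (chi-square only).
#' @return One-row tibble: `method`, `statistic` (NA for Fisher),
#'   `p_value`.
#' @export
#' @examples
#' two_by_two_test(12, 26, 14, 80, method = "fisher_exact")
two_by_two_test <- function(a, b, c, d,
                            method = c("chi_square", "fisher_exact"),
                            correct = FALSE) {
  method <- match.arg(method)
  cells <- c(a, b, c, d)
  if (!all(vapply(cells, is_count, logical(1)))) {
    stop_domain("all four cells must be non-negative integers")
  }
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_domain("both rows and both columns need positive totals")
  }
  if (method == "chi_square") {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    tibble::tibble(method = method,
                   statistic = unname(ht$statistic),
                   p_value = unname(ht$p.value))
  } else {
    ht <- stats::fisher.test(tab)
    tibble::tibble(method = method, statistic = NA_real_,
                   p_value = unname(ht$p.value))
  }
}

#' Mann-Whitney U test for two continuous samples
#'
#' Tie-corrected U statistic with a two-sided p-value: exact by
#' enumeration of all group assignments when the combined sample size is
#' at most `exact_limit` (handling ties, which the classical exact tables
#' do not), otherwise the normal approximation with the tie-corrected
#' variance (no continuity correction).
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @param exact_limit Combined-size cutoff for exact enumeration
#'   (default 12).
#' @return One-row tibble: `u` (number of (a, b) pairs with a > b, ties
#'   counting one half), `p_value`, `method`.
#' @export
mann_whitney <- function(sample_a, sample_b, exact_limit = 12) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    stop_domain("both samples must be non-empty")
  }
  n1 <- length(sample_a)
  n2 <- length(sample_b)
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= exact_limit) {
    # exact two-sided p over all assignments of ranks to group A
    combos <- utils::combn(n1 + n2, n1)
    u_all <- apply(combos, 2, function(idx) {
      sum(r[idx]) - n1 * (n1 + 1) / 2
    })
    mu <- n1 * n2 / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
    tibble::tibble(u = u, p_value = p, method = "exact")
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(sample_a, sample_b, exact = FALSE, correct = FALSE)
    )
    tibble::tibble(u = u, p_value = ht$p.value, method = "normal_approx")
  }
}

#' Case/control comparison table for a labelled selection
#'
#' Builds a cohort-description table from labelled visit rows: for each
#' binary feature, the number and percentage of ever-positive patients in
#' cases and controls with a chi-square test (Fisher's exact where any
#' expected cell count falls below 5); for age at first visit, group means
#' with a Mann-Whitney test.
#'
#' @param selection Labelled visit rows from [select_analysis_set()].
#' @param codebook Feature columns to compare (defaults to the selection's
#'   codebook).
#' @return Tibble with one row per feature: counts, percentages, test and
#'   p-value.
#' @export
compare_groups <- function(selection, codebook = NULL) {
  if (is.null(codebook)) codebook <- cohort_codebook(selection)
  per_patient <- selection |>
    dplyr::group_by(.data$patient_id, .data$label) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(codebook), ~ as.integer(any(.x == 1))),
      age_baseline = dplyr::first(.data$age),
      .groups = "drop"
    )
  n_case <- sum(per_patient$label == 1)
  n_ctrl <- sum(per_patient$label == 0)
  rows <- purrr::map_dfr(codebook, function(feat) {
    a <- sum(per_patient[[feat]][per_patient$label == 1])
    c_ <- sum(per_patient[[feat]][per_patient$label == 0])
    b <- n_case - a
    d <- n_ctrl - c_
    res <- tryCatch({
      expected_ok <- all(outer(c(a + b, c_ + d), c(a + c_, b + d)) /
                           (n_case + n_ctrl) >= 5)
      method <- if (expected_ok) "chi_square" else "fisher_exact"
      two_by_two_test(a, b, c_, d, method = method)
    }, error = function(e) {
      tibble::tibble(method = NA_character_, statistic = NA_real_,
                     p_value = NA_real_)
    })
    tibble::tibble(
      feature = feat,
      case_positive = a, case_pct = proportion_pct(a, n_case),
      control_positive = c_, control_pct = proportion_pct(c_, n_ctrl),
      method = res$method, p_value = res$p_value
    )
  })
  age_case <- per_patient$age_baseline[per_patient$label == 1]
  age_ctrl <- per_patient$age_baseline[per_patient$label == 0]
  mw <- mann_whitney(age_case, age_ctrl)
  dplyr::bind_rows(
    rows,
    tibble::tibble(
      feature = "age_baseline",
      case_positive = NA_integer_, case_pct = round_half_up(mean(age_case), 1),
      control_positive = NA_integer_,
      control_pct = round_half_up(mean(age_ctrl), 1),
      method = "mann_whitney", p_value = mw$p_value
    )
  )
}
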