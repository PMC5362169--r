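#' Stratified k-fold assignment
#'
#' Splits positives and negatives separately into k parts, so per-fold
#' case counts differ by at most one and likewise for controls.
#'
#' @param dataset A `damage_dataset` (or anything with labels retrievable
#'   via an integer vector passed as `labels`).
#' @param k Number of folds (default 8).
#' @param seed Seed for the shuffles.
#' @param labels Optional explicit 0/1 label vector (used internally for
#'   static baselines so recurrent and static evaluation share folds).
#' @return Tibble with `seq_id`, `label`, `fold`.
#' @export
kfold_split <- function(dataset = NULL, k = 8, seed = 1L, labels = NULL) {
  if (is.null(labels)) labels <- dataset_labels(dataset)
  if (!is_count(k) || k < 2) {
    stop_config("`k` must be an integer >= 2 (k = 1 leaves nothing held out)")
  }
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab < k)) {
    stop_config(paste0("each class needs >= k members (have ", tab[["1"]],
                       " cases, ", tab[["0"]], " controls, k = ", k, ")"))
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  tibble::tibble(seq_id = seq_along(labels), label = as.integer(labels),
                 fold = fold)
}

#' Empirical ROC curve and trapezoidal AUC
#'
#' Sweeps decreasing thresholds over the observed distinct scores (a score
#' greater than or equal to the threshold classifies positive), recording
#' the true- and false-positive rate at each. The first point is the
#' all-negative corner (0, 0) at threshold `Inf`; the last, at the lowest
#' observed score, is (1, 1). The AUC is the trapezoidal area, identical
#' to the tie-aware concordance probability of positives over negatives.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 outcomes (both classes required).
#' @return A `damage_roc` tibble with columns `threshold`, `tpr`, `fpr`
#'   and the AUC in `attr(, "auc")`.
#' @export
#' @examples
#' roc <- roc_curve(c(0.9, 0.8, 0.3), c(1, 0, 1))
#' attr(roc, "auc")
roc_curve <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop_domain("`scores` and `labels` lengths differ")
  }
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2) {
    stop_domain("ROC needs 0/1 labels with both classes present")
  }
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / npos,
                double(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / nneg,
                double(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    tibble::tibble(threshold = thr, tpr = tpr, fpr = fpr),
    auc = auc,
    class = c("damage_roc", class(tibble::tibble()))
  )
}

#' @describeIn roc_curve One-row summary with the AUC.
#' @param x A `damage_roc`.
#' @param ... Unused.
#' @export
glance.damage_roc <- function(x, ...) {
  tibble::tibble(auc = attr(x, "auc"), n_thresholds = nrow(x))
}

#' @describeIn roc_curve Plot the curve with the chance diagonal.
#' @param object A `damage_roc`.
#' @export
autoplot.damage_roc <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false-positive rate (1 - specificity)",
      y = "true-positive rate (sensitivity)",
      title = sprintf("Pooled ROC, AUC = %.3f", attr(object, "auc"))
    )
}

#' Operating thresholds meeting sensitivity and specificity floors
#'
#' Reduces a ROC curve to the rows whose sensitivity (TPR) and specificity
#' (1 - FPR) both meet the given floors, sorted by decreasing threshold —
#' the form in which candidate clinical cut-offs are reported. May be
#' empty (a chance-level curve has no qualifying operating point).
#'
#' @param roc A `damage_roc`.
#' @param min_sensitivity,min_specificity Floors, both default 0.7.
#' @return Tibble with `threshold`, `sensitivity`, `specificity`.
#' @export
threshold_table <- function(roc, min_sensitivity = 0.7,
                            min_specificity = 0.7) {
  tibble::as_tibble(roc) |>
    dplyr::mutate(sensitivity = .data$tpr,
                  specificity = 1 - .data$fpr) |>
    dplyr::filter(is.finite(.data$threshold),
                  .data$sensitivity >= min_sensitivity,
                  .data$specificity >= min_specificity) |>
    dplyr::arrange(dplyr::desc(.data$threshold)) |>
    dplyr::select("threshold", "sensitivity", "specificity")
}

# Internal: pooled out-of-fold cross-validation of the recurrent model on
# pre-computed folds. Age scaling is re-fitted on each fold's training part
# only, so held-out visits never leak into the encoding.
cv_rnn_folds <- function(dataset, folds, config, master_seed) {
  k <- max(folds$fold)
  scores <- rep(NA_real_, length(dataset$sequences))
  histories <- vector("list", k)
  fold_age <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- folds$seq_id[folds$fold == f]
    train_idx <- folds$seq_id[folds$fold != f]
    train_ds <- subset_dataset(dataset, train_idx)
    st <- age_stats(train_ds)
    train_ds <- rescale_age(train_ds, st$center, st$scale)
    test_ds <- rescale_age(subset_dataset(dataset, test_idx),
                           st$center, st$scale)
    cfg <- config
    cfg$seed <- as.integer(master_seed + 1000L + f)
    fit <- sgd_train(train_ds, cfg)
    scores[test_idx] <- predict(fit, test_ds)$score
    histories[[f]] <- fit$history
    fold_age[[f]] <- tibble::tibble(fold = f, center = st$center,
                                    scale = st$scale)
  }
  list(scores = scores, histories = histories,
       fold_age_stats = dplyr::bind_rows(fold_age))
}

#' Pooled k-fold cross-validation of the recurrent model
#'
#' For each of k stratified folds, trains the network on the other k - 1
#' parts (re-fitting the age standardization on that training part only)
#' and scores the held-out part; all held-out scores are then pooled into
#' a single ROC curve, rather than averaging per-fold AUCs. The fold
#' assignment uses `seed`; fold f trains with seed `seed + 1000 + f`.
#'
#' @param dataset A `damage_dataset`.
#' @param config An [rnn_config()].
#' @param k Number of folds (default 8).
#' @param seed Master seed for the split and the per-fold training seeds.
#' @return A `damage_cv`: `scores` tibble (one pooled out-of-fold score
#'   per sequence), `roc`, `auc`, `folds`, per-fold `histories` and
#'   `fold_age_stats`.
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(n_patients = 120, seed = 5))
#' ds <- encode_features(select_analysis_set(cohort))
#' cv <- cross_validate_rnn(ds, rnn_config(n_hidden = 10, max_epochs = 10),
#'                          k = 4, seed = 1)
#' glance(cv)
#' }
cross_validate_rnn <- function(dataset, config = rnn_config(), k = 8,
                               seed = 1L) {
  folds <- kfold_split(dataset, k = k, seed = seed)
  res <- cv_rnn_folds(dataset, folds, config, master_seed = seed)
  labels <- dataset_labels(dataset)
  roc <- roc_curve(res$scores, labels)
  structure(
    list(
      scores = tibble::tibble(
        patient_id = dataset_ids(dataset),
        label = as.integer(labels),
        fold = folds$fold,
        score = res$scores
      ),
      roc = roc,
      auc = attr(roc, "auc"),
      folds = folds,
      histories = res$histories,
      fold_age_stats = res$fold_age_stats,
      model = "rnn",
      config = config
    ),
    class = "damage_cv"
  )
}

#' @export
print.damage_cv <- function(x, ...) {
  cat("<damage_cv> pooled ", max(x$folds$fold), "-fold validation (",
      x$model, ")\n", sep = "")
  cat("  sequences:", nrow(x$scores), " pooled AUC:", signif(x$auc, 4), "\n")
  invisible(x)
}

#' @describeIn cross_validate_rnn Pooled out-of-fold scores, one row per
#'   sequence.
#' @param x A `damage_cv`.
#' @param ... Unused.
#' @export
tidy.damage_cv <- function(x, ...) x$scores

#' @describeIn cross_validate_rnn One-row summary (pooled AUC, sizes).
#' @export
glance.damage_cv <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    k = max(x$folds$fold),
    n = nrow(x$scores),
    n_case = sum(x$scores$label == 1),
    n_control = sum(x$scores$label == 0),
    auc = x$auc
  )
}

#' @describeIn cross_validate_rnn Pooled ROC plot.
#' @param object A `damage_cv`.
#' @export
autoplot.damage_cv <- function(object, ...) autoplot(object$roc, ...)

#' Robustness of the pooled AUC to the hidden-layer size
#'
#' Re-runs the pooled cross-validation for each hidden size on a shared
#' fold assignment, so the sizes are compared on identical held-out data.
#'
#' @param dataset A `damage_dataset`.
#' @param sizes Hidden sizes to compare (default `c(50, 100)`).
#' @param config An [rnn_config()]; its `n_hidden` is overridden per size.
#' @param k,seed As in [cross_validate_rnn()].
#' @return Tibble with `n_hidden` and pooled `auc`.
#' @export
hidden_sweep <- function(dataset, sizes = c(50, 100),
                         config = rnn_config(), k = 8, seed = 1L) {
  if (length(sizes) == 0) stop_config("`sizes` must be non-empty")
  purrr::map_dfr(sizes, function(n) {
    cfg <- config
    cfg$n_hidden <- n
    cv <- cross_validate_rnn(dataset, cfg, k = k, seed = seed)
    tibble::tibble(n_hidden = n, auc = cv$auc)
  })
}
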