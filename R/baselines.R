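#' Concatenated last-L-visit feature vectors for static models
#'
#' Builds the fixed-length input of the static comparison models: for each
#' sequence, the features of its last `L` usable visits concatenated in
#' chronological order (length `L * p`). When a sequence is shorter than
#' `L` the window is left-padded by repeating its earliest visit (or with
#' zeros, via `pad`). With `drop_last = TRUE` the usable window ends one
#' visit before the sequence's final visit — the alternative reading of
#' "up to the second to last available visit"; by default the windows
#' produced by the selection rules are used as-is.
#'
#' @param dataset A `damage_dataset`.
#' @param L Number of trailing visits (>= 1).
#' @param pad `"repeat_first"` (default) or `"zero"`.
#' @param drop_last Drop each sequence's final visit before windowing.
#' @return A `static_dataset`: list with matrix `x` (n x L*p), `labels`,
#'   `patient_id`, `L`, `p`, `features`, `age_cols`, `age_center`,
#'   `age_scale`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 40, seed = 4))
#' ds <- encode_features(select_analysis_set(cohort))
#' st <- build_static_features(ds, L = 2)
#' dim(st$x)
build_static_features <- function(dataset, L,
                                  pad = c("repeat_first", "zero"),
                                  drop_last = FALSE) {
  if (!is_count(L) || L < 1) stop_config("`L` must be an integer >= 1")
  pad <- match.arg(pad)
  p <- length(dataset$features)
  rows <- purrr::map(dataset$sequences, function(s) {
    x <- s$x
    if (drop_last && nrow(x) > 1) x <- x[-nrow(x), , drop = FALSE]
    t_n <- nrow(x)
    take <- seq(max(1L, t_n - L + 1L), t_n)
    if (length(take) < L) {
      pad_rows <- L - length(take)
      padding <- if (pad == "repeat_first") {
        x[rep(take[1], pad_rows), , drop = FALSE]
      } else {
        matrix(0, pad_rows, p)
      }
      win <- rbind(padding, x[take, , drop = FALSE])
    } else {
      win <- x[take, , drop = FALSE]
    }
    as.numeric(t(win))  # visit-major, chronological
  })
  x <- do.call(rbind, rows)
  colnames(x) <- paste0(rep(dataset$features, times = L), "_v",
                        rep(seq_len(L), each = p))
  structure(
    list(
      x = x,
      labels = dataset_labels(dataset),
      patient_id = dataset_ids(dataset),
      L = L,
      p = p,
      features = dataset$features,
      age_cols = if (is.na(dataset$age_col)) integer(0) else
        dataset$age_col + p * (seq_len(L) - 1),
      age_center = dataset$age_center,
      age_scale = dataset$age_scale
    ),
    class = "static_dataset"
  )
}

#' Logistic-regression baseline on static feature vectors
#'
#' Unpenalized maximum-likelihood fit (binomial GLM with intercept) of the
#' damage label on the concatenated visit window. The fit is
#' deterministic; `seed` is accepted for interface parity with the other
#' learners and ignored.
#'
#' @param static A `static_dataset`.
#' @param seed Ignored (the MLE has no random component).
#' @param maxit IRLS iteration cap (default 5000).
#' @return A `static_logistic` scorer; use [predict()] for probabilities.
#' @export
fit_logistic <- function(static, seed = NULL, maxit = 5000) {
  if (length(unique(static$labels)) < 2) {
    stop_data("logistic fit requires both labels")
  }
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, static$x), static$labels,
                   family = stats::binomial(),
                   control = list(maxit = maxit))
  )
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  structure(list(coefficients = coefs, converged = fit$converged),
            class = "static_logistic")
}

#' @export
predict.static_logistic <- function(object, static, ...) {
  eta <- drop(cbind(1, static$x) %*% object$coefficients)
  tibble::tibble(patient_id = static$patient_id,
                 label = static$labels,
                 score = plogis(eta))
}

#' @describeIn fit_logistic Coefficients as a tibble.
#' @param x A `static_logistic`.
#' @param ... Unused.
#' @export
tidy.static_logistic <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = as.numeric(x$coefficients))
}

#' Feedforward baseline on static feature vectors
#'
#' One hidden tanh layer and a logistic output — exactly the recurrent
#' model evaluated on a single time step (with `h_0 = 0` the recurrence
#' contributes nothing at T = 1) — trained by the same per-example SGD and
#' training-AUC early-stopping protocol as the sequence model.
#'
#' @param static A `static_dataset`.
#' @param n_hidden Hidden units (default 100).
#' @param config An [rnn_config()]; `n_hidden` is overridden.
#' @return An `rnn_fit` over length-1 sequences; score with
#'   [predict_static_ffnn()] or via [evaluate_static()].
#' @export
fit_ffnn <- function(static, n_hidden = 100, config = rnn_config()) {
  config$n_hidden <- n_hidden
  sgd_train(static_as_dataset(static), config)
}

# View a static dataset as length-1 sequences so the recurrent machinery
# (shared SGD loop and stopping rule) can train and score it.
static_as_dataset <- function(static) {
  sequences <- purrr::map(seq_along(static$labels), function(i) {
    list(patient_id = static$patient_id[i],
         x = matrix(static$x[i, ], nrow = 1,
                    dimnames = list(NULL, colnames(static$x))),
         label = static$labels[i])
  })
  new_damage_dataset(
    sequences = sequences,
    features = colnames(static$x),
    binary = !seq_along(colnames(static$x)) %in% static$age_cols,
    age_center = static$age_center,
    age_scale = static$age_scale
  )
}

#' Score a static dataset with a fitted feedforward baseline
#'
#' @param object An `rnn_fit` from [fit_ffnn()].
#' @param static A `static_dataset`.
#' @return Tibble with `patient_id`, `label`, `score`.
#' @export
predict_static_ffnn <- function(object, static) {
  predict(object, static_as_dataset(static))
}

#' Pooled k-fold validation of a static baseline
#'
#' Applies the same pooled cross-validation protocol as
#' [cross_validate_rnn()] — identical stratified folds for the same
#' master seed, age scaling re-fitted per training part, held-out scores
#' pooled into one ROC — to a logistic regression or feedforward network
#' on the concatenated last-L-visit vectors.
#'
#' @param static A `static_dataset`.
#' @param model `"logistic"` or `"ffnn"`.
#' @param k Number of folds (default 8).
#' @param seed Master seed (matching [cross_validate_rnn()]'s gives paired
#'   folds when the underlying sequences are in the same order).
#' @param config An [rnn_config()] for the feedforward model.
#' @param n_hidden Hidden units of the feedforward model (default 100).
#' @return A `damage_cv` with pooled scores, ROC and AUC.
#' @export
evaluate_static <- function(static, model = c("logistic", "ffnn"), k = 8,
                            seed = 1L, config = rnn_config(),
                            n_hidden = 100) {
  model <- match.arg(model)
  folds <- kfold_split(k = k, seed = seed, labels = static$labels)
  n <- length(static$labels)
  scores <- rep(NA_real_, n)
  for (f in seq_len(max(folds$fold))) {
    test_idx <- folds$seq_id[folds$fold == f]
    train_idx <- folds$seq_id[folds$fold != f]
    tr <- static_subset(static, train_idx)
    te <- static_subset(static, test_idx)
    if (length(tr$age_cols) > 0) {
      raw <- tr$x[, tr$age_cols, drop = FALSE] * tr$age_scale + tr$age_center
      ctr <- mean(raw)
      scl <- stats::sd(as.numeric(raw))
      if (!is.finite(scl) || scl == 0) scl <- 1
      tr <- static_rescale_age(tr, ctr, scl)
      te <- static_rescale_age(te, ctr, scl)
    }
    if (model == "logistic") {
      fit <- fit_logistic(tr)
      scores[test_idx] <- predict(fit, te)$score
    } else {
      cfg <- config
      cfg$seed <- as.integer(seed + 1000L + f)
      fit <- fit_ffnn(tr, n_hidden = n_hidden, config = cfg)
      scores[test_idx] <- predict_static_ffnn(fit, te)$score
    }
  }
  roc <- roc_curve(scores, static$labels)
  structure(
    list(
      scores = tibble::tibble(patient_id = static$patient_id,
                              label = as.integer(static$labels),
                              fold = folds$fold, score = scores),
      roc = roc,
      auc = attr(roc, "auc"),
      folds = folds,
      histories = NULL,
      model = paste0(model, "_L", static$L)
    ),
    class = "damage_cv"
  )
}

static_subset <- function(static, idx) {
  static$x <- static$x[idx, , drop = FALSE]
  static$labels <- static$labels[idx]
  static$patient_id <- static$patient_id[idx]
  static
}

static_rescale_age <- function(static, center, scale) {
  j <- static$age_cols
  raw <- static$x[, j, drop = FALSE] * static$age_scale + static$age_center
  static$x[, j] <- (raw - center) / scale
  static$age_center <- center
  static$age_scale <- scale
  static
}
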