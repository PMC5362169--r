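#' Training configuration for the recurrent model
#'
#' Defaults follow the reference protocol where one is stated: 100 hidden
#' units and early stopping once the training-pool AUC exceeds 0.95.
#' Learning rate, epoch cap and initialization scale are this package's
#' own choices (the protocol leaves them open): plain per-example SGD with
#' a constant rate, no momentum, no bias terms.
#'
#' @param n_hidden Number of hidden tanh units (default 100).
#' @param learning_rate Constant SGD step size (default 0.005; larger rates
#'   make the training AUC oscillate without converging on cohort-sized
#'   problems).
#' @param max_epochs Epoch cap guarding non-convergence (default 500).
#' @param early_stop_auc Stop once training AUC exceeds this (default 0.95).
#' @param init_scale Weights drawn i.i.d. uniform on
#'   `[-init_scale, init_scale]` (default 0.17, which puts the spectral
#'   radius of the recurrent matrix near 1 for 100 hidden units, the
#'   longest-memory regime of a random recurrence).
#' @param seed Seed for initialization and epoch shuffling.
#' @return An `rnn_config` list.
#' @export
rnn_config <- function(n_hidden = 100, learning_rate = 0.005,
                       max_epochs = 500, early_stop_auc = 0.95,
                       init_scale = 0.17, seed = 1L) {
  if (!is_count(n_hidden) || n_hidden < 1) {
    stop_config("`n_hidden` must be a positive integer")
  }
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    stop_config("`learning_rate` must be positive")
  }
  if (!is_count(max_epochs)) stop_config("`max_epochs` must be a count")
  if (!is.numeric(early_stop_auc) || early_stop_auc <= 0.5 ||
      early_stop_auc > 1) {
    stop_config("`early_stop_auc` must lie in (0.5, 1]")
  }
  if (!is.numeric(init_scale) || init_scale < 0) {
    stop_config("`init_scale` must be non-negative")
  }
  structure(
    list(n_hidden = n_hidden, learning_rate = learning_rate,
         max_epochs = max_epochs, early_stop_auc = early_stop_auc,
         init_scale = init_scale, seed = as.integer(seed)),
    class = "rnn_config"
  )
}

#' Initialize recurrent-network weights
#'
#' Draws the three weight matrices of the Elman model — recurrent
#' `Wr` (n x n), input `Wi` (n x p) and output `Wo` (length n) — i.i.d.
#' uniform on `[-init_scale, init_scale]` from the seeded generator.
#' There are no bias terms: the model equations contain none.
#'
#' @param p Input width (number of features).
#' @param n Hidden size.
#' @param config An [rnn_config()].
#' @return An `rnn_weights` list with elements `Wr`, `Wi`, `Wo`.
#' @export
init_weights <- function(p, n = config$n_hidden, config = rnn_config()) {
  if (!is_count(p) || p < 1 || !is_count(n) || n < 1) {
    stop_config("`p` and `n` must be positive integers")
  }
  with_seed(config$seed, {
    s <- config$init_scale
    structure(
      list(
        Wr = matrix(runif(n * n, -s, s), n, n),
        Wi = matrix(runif(n * p, -s, s), n, p),
        Wo = runif(n, -s, s)
      ),
      class = "rnn_weights"
    )
  })
}

#' Forward pass of the recurrent model over one visit sequence
#'
#' Computes `h_t = tanh(Wr h_{t-1} + Wi x_t)` from `h_0 = 0` and
#' `y_t = plogis(Wo . h_t)` for every visit; only the final output is the
#' sequence score, interpreted as the probability of developing organ
#' damage within the next two years. Sequences of any length are handled
#' natively — there is no padding anywhere in the pipeline.
#'
#' @param weights An `rnn_weights` object.
#' @param x Numeric matrix, T visits x p features (or an encoded sequence
#'   from a `damage_dataset`).
#' @return List with `h` (T x n hidden trajectory), `y` (per-step
#'   outputs) and `score` (`y[T]`).
#' @export
#' @examples
#' w <- init_weights(p = 3, n = 2, config = rnn_config(seed = 1))
#' rnn_forward(w, matrix(rbinom(12, 1, 0.5), 4, 3))$score
rnn_forward <- function(weights, x) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(weights$Wi)) {
    stop_data(paste0("sequence width ", ncol(x), " does not match input size ",
                     ncol(weights$Wi)))
  }
  res <- rnn_forward_cpp(weights$Wr, weights$Wi, weights$Wo, x)
  res$y <- as.numeric(res$y)
  res
}

#' Binary cross-entropy of a sequence score
#'
#' @param score Predicted probability, strictly inside (0, 1).
#' @param label 0/1 outcome.
#' @return `-(label * log(score) + (1 - label) * log(1 - score))`.
#' @export
bce_loss <- function(score, label) {
  if (!is.numeric(score) || any(score <= 0) || any(score >= 1)) {
    stop_domain("`score` must lie strictly inside (0, 1)")
  }
  if (!all(label %in% c(0, 1))) stop_domain("`label` must be 0 or 1")
  -(label * log(score) + (1 - label) * log(1 - score))
}

#' Exact loss gradients by backpropagation through time
#'
#' Differentiates the final-step binary cross-entropy through the fully
#' unrolled recurrence (no truncation), returning the gradients with
#' respect to `Wr`, `Wi` and `Wo`.
#'
#' @param weights An `rnn_weights` object.
#' @param x T x p sequence matrix.
#' @param label 0/1 outcome.
#' @return List with matrices `Wr`, `Wi`, vector `Wo`, and the forward
#'   `score`.
#' @export
rnn_gradients <- function(weights, x, label) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(weights$Wi)) {
    stop_data("sequence width does not match input size")
  }
  if (!label %in% c(0, 1)) stop_domain("`label` must be 0 or 1")
  res <- rnn_bptt_cpp(weights$Wr, weights$Wi, weights$Wo, x, label)
  res$Wo <- as.numeric(res$Wo)
  res
}

#' Train the recurrent model by stochastic gradient descent
#'
#' Per-example SGD over epoch-wise shuffles of the training pool. After
#' each full epoch the training AUC is computed on the whole pool and
#' training halts once it exceeds `config$early_stop_auc` (early
#' stopping), or at `config$max_epochs`. Deterministic given the dataset
#' order and the config seed.
#'
#' @param dataset A `damage_dataset` containing both labels.
#' @param config An [rnn_config()].
#' @return An `rnn_fit`: weights, per-epoch `history` tibble
#'   (epoch, loss, auc), `stop_reason` (`"early_stop"` or
#'   `"max_epochs"`), and the configs used.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 80, seed = 3))
#' ds <- encode_features(select_analysis_set(cohort))
#' fit <- sgd_train(ds, rnn_config(n_hidden = 10, max_epochs = 5))
#' glance(fit)
sgd_train <- function(dataset, config = rnn_config()) {
  labels <- dataset_labels(dataset)
  if (length(unique(labels)) < 2) {
    stop_data("training requires both labels (AUC is undefined otherwise)")
  }
  p <- length(dataset$features)
  n <- config$n_hidden
  seqs <- purrr::map(dataset$sequences, function(s) unname(s$x))
  res <- with_seed(config$seed, {
    w <- list(
      Wr = matrix(runif(n * n, -config$init_scale, config$init_scale), n, n),
      Wi = matrix(runif(n * p, -config$init_scale, config$init_scale), n, p),
      Wo = runif(n, -config$init_scale, config$init_scale)
    )
    if (config$max_epochs == 0) {
      list(Wr = w$Wr, Wi = w$Wi, Wo = w$Wo, loss = numeric(0),
           auc = numeric(0), stop_reason = "max_epochs")
    } else {
      orders <- t(replicate(config$max_epochs, sample.int(length(seqs))))
      if (length(seqs) == 1) orders <- matrix(orders, ncol = 1)
      rnn_sgd_cpp(seqs, as.integer(labels), w$Wr, w$Wi, w$Wo,
                  config$learning_rate, config$max_epochs,
                  config$early_stop_auc, orders)
    }
  })
  structure(
    list(
      weights = structure(list(Wr = res$Wr, Wi = res$Wi, Wo = as.numeric(res$Wo)),
                          class = "rnn_weights"),
      history = tibble::tibble(
        epoch = seq_along(res$loss),
        loss = as.numeric(res$loss),
        auc = as.numeric(res$auc)
      ),
      stop_reason = res$stop_reason,
      features = dataset$features,
      config = config
    ),
    class = "rnn_fit"
  )
}

#' Score sequences with a trained model
#'
#' @param object An `rnn_fit`.
#' @param dataset A `damage_dataset` encoded with the same feature set.
#' @param ... Unused.
#' @return Tibble with `patient_id`, `label`, `score`.
#' @export
predict.rnn_fit <- function(object, dataset, ...) {
  if (length(dataset$features) != ncol(object$weights$Wi)) {
    stop_data("dataset feature width does not match the fitted model")
  }
  seqs <- purrr::map(dataset$sequences, function(s) unname(s$x))
  tibble::tibble(
    patient_id = dataset_ids(dataset),
    label = dataset_labels(dataset),
    score = as.numeric(rnn_score_cpp(seqs, object$weights$Wr,
                                     object$weights$Wi, object$weights$Wo))
  )
}

#' @export
print.rnn_fit <- function(x, ...) {
  cat("<rnn_fit> Elman recurrent network\n")
  cat("  hidden units:", x$config$n_hidden, " features:",
      length(x$features), "\n")
  cat("  epochs run:  ", nrow(x$history), " (", x$stop_reason, ")\n", sep = "")
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat("  final train loss ", signif(last$loss, 4), ", train AUC ",
        signif(last$auc, 4), "\n", sep = "")
  }
  invisible(x)
}

#' @describeIn sgd_train Per-epoch training history as a tibble.
#' @param x An `rnn_fit`.
#' @param ... Unused.
#' @export
tidy.rnn_fit <- function(x, ...) x$history

#' @describeIn sgd_train One-row fit summary.
#' @export
glance.rnn_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_hidden = x$config$n_hidden,
    epochs = nrow(h),
    stop_reason = x$stop_reason,
    final_loss = if (nrow(h)) h$loss[nrow(h)] else NA_real_,
    final_train_auc = if (nrow(h)) h$auc[nrow(h)] else NA_real_
  )
}

#' @describeIn sgd_train Training loss and AUC per epoch.
#' @param object An `rnn_fit`.
#' @export
autoplot.rnn_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("loss", "auc"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Training history (per-example SGD)")
}
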