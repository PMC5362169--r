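test_that("weight initialization is seeded, bounded and shaped", {
  cfg <- rnn_config(init_scale = 0.2, seed = 31)
  w1 <- init_weights(p = 4, n = 3, config = cfg)
  w2 <- init_weights(p = 4, n = 3, config = cfg)
  expect_identical(w1, w2)
  expect_equal(dim(w1$Wr), c(3, 3))
  expect_equal(dim(w1$Wi), c(3, 4))
  expect_length(w1$Wo, 3)
  expect_true(all(abs(unlist(w1[c("Wr", "Wi")])) <= 0.2))

  wz <- init_weights(2, 2, rnn_config(init_scale = 0))
  expect_true(all(unlist(wz[c("Wr", "Wi")]) == 0) && all(wz$Wo == 0))

  w_min <- init_weights(1, 1, cfg)
  expect_equal(dim(w_min$Wr), c(1, 1))

  expect_error(init_weights(0, 3), class = "lupusrnn_config_error")
})

test_that("forward pass matches hand computation and the R oracle", {
  # all-zero weights: logistic(0) everywhere
  wz <- init_weights(3, 4, rnn_config(init_scale = 0))
  fz <- rnn_forward(wz, matrix(rbinom(9, 1, 0.5), 3, 3))
  expect_equal(fz$y, rep(0.5, 3))

  # n = 1 closed form: h1 = tanh(1), y1 = logistic(tanh(1))
  w <- structure(list(Wr = matrix(0, 1, 1), Wi = matrix(c(1, 0, 0), 1, 3),
                      Wo = 1), class = "rnn_weights")
  f <- rnn_forward(w, matrix(c(1, 0, 0), 1, 3))
  expect_equal(f$score, plogis(tanh(1)), tolerance = 1e-12)
  expect_equal(f$score, 0.68165, tolerance = 1e-4)

  # random shapes against the independent R implementation
  set.seed(5)
  for (i in 1:10) {
    n <- sample(1:5, 1); p <- sample(1:4, 1); t_len <- sample(1:6, 1)
    w <- list(Wr = matrix(rnorm(n * n, sd = 0.5), n, n),
              Wi = matrix(rnorm(n * p, sd = 0.5), n, p),
              Wo = rnorm(n, sd = 0.5))
    class(w) <- "rnn_weights"
    X <- matrix(rnorm(t_len * p), t_len, p)
    expect_equal(rnn_forward(w, X)$score, oracle_forward(w$Wr, w$Wi, w$Wo, X),
                 tolerance = 1e-12)
  }
  expect_error(rnn_forward(w, matrix(0, 2, 17)),
               class = "lupusrnn_data_error")
})

test_that("with Wr = 0 the final score is a static net on the last visit", {
  set.seed(8)
  n <- 6; p <- 5
  w <- structure(list(Wr = matrix(0, n, n),
                      Wi = matrix(rnorm(n * p), n, p),
                      Wo = rnorm(n)), class = "rnn_weights")
  for (i in 1:5) {
    X <- matrix(rnorm(4 * p), 4, p)
    expect_equal(rnn_forward(w, X)$score,
                 oracle_static_net(w$Wi, w$Wo, X[4, ]), tolerance = 1e-12)
  }
})

test_that("binary cross-entropy has the stated values and monotonicity", {
  expect_equal(bce_loss(0.5, 1), log(2))
  expect_equal(bce_loss(0.5, 0), log(2))
  s <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(bce_loss(s, 1)) < 0))
  expect_true(all(diff(bce_loss(s, 0)) > 0))
  expect_error(bce_loss(1, 1), class = "lupusrnn_domain_error")
  expect_error(bce_loss(0, 0), class = "lupusrnn_domain_error")
})

test_that("BPTT matches central finite differences on random instances", {
  set.seed(17)
  worst <- 0
  for (i in 1:25) {
    n <- sample(1:5, 1); p <- sample(1:4, 1); t_len <- sample(1:6, 1)
    w <- structure(list(Wr = matrix(rnorm(n * n, sd = 0.6), n, n),
                        Wi = matrix(rnorm(n * p, sd = 0.6), n, p),
                        Wo = rnorm(n, sd = 0.6)), class = "rnn_weights")
    X <- matrix(rnorm(t_len * p), t_len, p)
    label <- rbinom(1, 1, 0.5)
    g <- rnn_gradients(w, X, label)
    fd <- oracle_fd_gradients(w$Wr, w$Wi, w$Wo, X, label)
    for (nm in c("Wr", "Wi", "Wo")) {
      denom <- pmax(abs(fd[[nm]]), 1e-6)
      worst <- max(worst, max(abs(g[[nm]] - fd[[nm]]) / denom))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("structural zeros of the gradient are exact", {
  set.seed(3)
  w <- init_weights(3, 4, rnn_config(init_scale = 0.3, seed = 2))
  # length-1 sequence: h0 = 0 enters Wr once, so its gradient vanishes
  g1 <- rnn_gradients(w, matrix(rnorm(3), 1, 3), 1)
  expect_true(all(g1$Wr == 0))
  # all-zero weights: h_T = 0 forces the output gradient to zero
  wz <- init_weights(3, 4, rnn_config(init_scale = 0))
  gz <- rnn_gradients(wz, matrix(rnorm(6), 2, 3), 0)
  expect_true(all(gz$Wo == 0))
})

test_that("SGD reaches early stop on a separable fixture, deterministically", {
  ds <- make_separable_dataset(n_per_class = 10)
  cfg <- rnn_config(n_hidden = 8, learning_rate = 0.05, max_epochs = 200,
                    seed = 5)
  fit <- sgd_train(ds, cfg)
  expect_equal(fit$stop_reason, "early_stop")
  expect_gt(dplyr::last(fit$history$auc), 0.95)

  refit <- sgd_train(ds, cfg)
  expect_identical(fit$weights, refit$weights)
  expect_identical(fit$history, refit$history)

  # at stopping, the fit separates the classes far better than at init
  scores <- predict(fit, ds)
  init_fit <- sgd_train(ds, rnn_config(n_hidden = 8, max_epochs = 0, seed = 5))
  expect_lt(mean(bce_loss(scores$score, scores$label)),
            mean(bce_loss(predict(init_fit, ds)$score, scores$label)))
})

test_that("degenerate training configurations behave as specified", {
  ds <- make_separable_dataset(n_per_class = 4)
  fit0 <- sgd_train(ds, rnn_config(n_hidden = 3, max_epochs = 0, seed = 1))
  expect_equal(nrow(fit0$history), 0)
  expect_equal(fit0$stop_reason, "max_epochs")
  expect_identical(fit0$weights,
                   init_weights(length(ds$features), 3,
                                rnn_config(n_hidden = 3, max_epochs = 0, seed = 1)))

  single <- ds
  single$sequences <- purrr::keep(single$sequences, function(s) s$label == 1)
  expect_error(sgd_train(single, rnn_config(n_hidden = 3)),
               class = "lupusrnn_data_error")
})

test_that("variable-length sequences are scored natively, without padding", {
  w <- init_weights(3, 4, rnn_config(init_scale = 0.3, seed = 9))
  x_short <- matrix(rbinom(3, 1, 0.5), 1, 3)
  x_long <- rbind(matrix(rbinom(6, 1, 0.5), 2, 3), x_short)
  s_short <- rnn_forward(w, x_short)$score
  s_long <- rnn_forward(w, x_long)$score
  # the short sequence's score equals the oracle on exactly its own visits
  expect_equal(s_short, oracle_forward(w$Wr, w$Wi, w$Wo, x_short))
  expect_equal(s_long, oracle_forward(w$Wr, w$Wi, w$Wo, x_long))
})
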