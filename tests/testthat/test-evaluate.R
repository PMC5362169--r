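test_that("stratified folds balance both classes at the study group sizes", {
  labels <- rep(c(1L, 0L), c(38, 94))
  folds <- kfold_split(k = 8, seed = 3, labels = labels)
  expect_equal(sort(unique(folds$fold)), 1:8)
  per_fold <- dplyr::count(folds, fold, label)
  cases <- per_fold$n[per_fold$label == 1]
  controls <- per_fold$n[per_fold$label == 0]
  expect_true(all(cases %in% c(4L, 5L)))
  expect_true(all(controls %in% c(11L, 12L)))
  expect_equal(sum(cases), 38L)
  expect_equal(sum(controls), 94L)

  expect_identical(folds, kfold_split(k = 8, seed = 3, labels = labels))
  expect_error(kfold_split(k = 1, seed = 1, labels = labels),
               class = "lupusrnn_config_error")
  expect_error(kfold_split(k = 8, seed = 1, labels = rep(c(1, 0), c(5, 94))),
               class = "lupusrnn_config_error")
})

test_that("roc_curve reproduces worked examples and the type invariants", {
  roc <- roc_curve(c(0.9, 0.8, 0.3), c(1, 0, 1))
  expect_equal(attr(roc, "auc"), 0.5)

  expect_equal(attr(roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), "auc"), 1)
  expect_equal(attr(roc_curve(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), "auc"), 0.5)

  # endpoints and monotonicity as threshold decreases
  expect_equal(unlist(roc[1, c("tpr", "fpr")], use.names = FALSE), c(0, 0))
  expect_equal(unlist(roc[nrow(roc), c("tpr", "fpr")], use.names = FALSE),
               c(1, 1))
  expect_true(all(diff(roc$tpr) >= 0) && all(diff(roc$fpr) >= 0))

  expect_error(roc_curve(c(0.1, 0.2), c(1, 1)),
               class = "lupusrnn_domain_error")
})

test_that("trapezoidal AUC equals pairwise concordance on random instances", {
  set.seed(41)
  for (i in 1:60) {
    n <- sample(4:40, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force ties sometimes
    roc <- roc_curve(scores, labels)
    expect_equal(attr(roc, "auc"), oracle_concordance_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (i in 1:5) {
    labels <- c(0, 1, rbinom(30, 1, 0.4))
    scores <- round(runif(32), 2)
    ours <- attr(roc_curve(scores, labels), "auc")
    theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                             direction = "<")))
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("threshold_table filters and orders reported operating points", {
  # a curve containing the six published-style operating points plus
  # points that fail one or both floors
  pts <- tibble::tibble(
    threshold = c(0.9, 0.486, 0.383, 0.365, 0.358, 0.290, 0.271, 0.1),
    tpr = c(0.2, 0.819, 0.755, 0.745, 0.745, 0.702, 0.702, 0.99),
    fpr = 1 - c(0.99, 0.711, 0.711, 0.737, 0.763, 0.763, 0.789, 0.2)
  )
  roc <- structure(pts, auc = NA_real_,
                   class = c("damage_roc", class(tibble::tibble())))
  tab <- threshold_table(roc)
  expect_equal(tab$threshold, c(0.486, 0.383, 0.365, 0.358, 0.290, 0.271))
  expect_true(all(tab$sensitivity >= 0.7 & tab$specificity >= 0.7))

  # a chance-level curve has no qualifying operating point
  diag <- roc_curve(seq(0, 1, length.out = 20), rep(c(1, 0), 10))
  expect_equal(nrow(threshold_table(diag)), 0)

  # zero floors return every finite-threshold point
  expect_equal(nrow(threshold_table(diag, 0, 0)),
               sum(is.finite(diag$threshold)))
})

test_that("pooled cross-validation scores every sequence exactly once", {
  ds <- make_small_dataset(n_patients = 60, seed = 11)
  cfg <- rnn_config(n_hidden = 6, max_epochs = 10, seed = 1)
  cv <- cross_validate_rnn(ds, cfg, k = 3, seed = 2)
  expect_equal(nrow(cv$scores), length(ds$sequences))
  expect_false(any(is.na(cv$scores$score)))
  expect_equal(sort(unique(cv$scores$fold)), 1:3)
  expect_equal(cv$auc, attr(roc_curve(cv$scores$score, cv$scores$label), "auc"))

  # determinism under the master seed
  cv2 <- cross_validate_rnn(ds, cfg, k = 3, seed = 2)
  expect_identical(cv$scores, cv2$scores)
})

test_that("age scaling is fitted on each fold's training part only", {
  ds <- make_small_dataset(n_patients = 60, seed = 11)
  cv <- cross_validate_rnn(ds, rnn_config(n_hidden = 4, max_epochs = 2),
                           k = 3, seed = 5)
  j <- ds$age_col
  for (f in 1:3) {
    train_idx <- cv$folds$seq_id[cv$folds$fold != f]
    raw_train_ages <- unlist(purrr::map(ds$sequences[train_idx], function(s) {
      s$x[, j] * ds$age_scale + ds$age_center
    }))
    st <- cv$fold_age_stats[cv$fold_age_stats$fold == f, ]
    expect_equal(st$center, mean(raw_train_ages), tolerance = 1e-12)
    expect_equal(st$scale, sd(raw_train_ages), tolerance = 1e-12)
  }
})

test_that("hidden_sweep shares folds across sizes and returns one AUC each", {
  ds <- make_small_dataset(n_patients = 60, seed = 11)
  cfg <- rnn_config(max_epochs = 5, seed = 1)
  sweep <- hidden_sweep(ds, sizes = c(4, 8), config = cfg, k = 3, seed = 9)
  expect_equal(sweep$n_hidden, c(4, 8))
  expect_true(all(sweep$auc >= 0 & sweep$auc <= 1))

  single <- hidden_sweep(ds, sizes = 5, config = cfg, k = 3, seed = 9)
  expect_equal(nrow(single), 1)
  expect_error(hidden_sweep(ds, sizes = integer(0)),
               class = "lupusrnn_config_error")
})
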