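# Independent oracles used to check the package's numerics. These are
# deliberately naive re-derivations (loops, enumeration, finite
# differences) kept free of any code path they verify.

# Elman forward pass in plain R, element by element.
oracle_forward <- function(Wr, Wi, Wo, X) {
  n <- nrow(Wr)
  h <- rep(0, n)
  for (t in seq_len(nrow(X))) {
    h <- tanh(as.numeric(Wr %*% h) + as.numeric(Wi %*% X[t, ]))
  }
  1 / (1 + exp(-sum(Wo * h)))
}

oracle_bce <- function(score, label) {
  -(label * log(score) + (1 - label) * log(1 - score))
}

# Central finite differences of the final-step BCE wrt all weights.
oracle_fd_gradients <- function(Wr, Wi, Wo, X, label, eps = 1e-5) {
  f <- function(Wr, Wi, Wo) oracle_bce(oracle_forward(Wr, Wi, Wo, X), label)
  g <- list(Wr = Wr * 0, Wi = Wi * 0, Wo = Wo * 0)
  for (i in seq_along(Wr)) {
    up <- Wr; up[i] <- up[i] + eps
    dn <- Wr; dn[i] <- dn[i] - eps
    g$Wr[i] <- (f(up, Wi, Wo) - f(dn, Wi, Wo)) / (2 * eps)
  }
  for (i in seq_along(Wi)) {
    up <- Wi; up[i] <- up[i] + eps
    dn <- Wi; dn[i] <- dn[i] - eps
    g$Wi[i] <- (f(Wr, up, Wo) - f(Wr, dn, Wo)) / (2 * eps)
  }
  for (i in seq_along(Wo)) {
    up <- Wo; up[i] <- up[i] + eps
    dn <- Wo; dn[i] <- dn[i] - eps
    g$Wo[i] <- (f(Wr, Wi, up) - f(Wr, Wi, dn)) / (2 * eps)
  }
  g
}

# Tie-aware concordance probability by explicit pair enumeration.
oracle_concordance_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (sp in pos) {
    for (sn in neg) {
      total <- total + (sp > sn) + 0.5 * (sp == sn)
    }
  }
  total / (length(pos) * length(neg))
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  amin <- max(0, k - n)
  amax <- min(k, m)
  probs <- vapply(amin:amax, function(x) {
    dhyper(x, m, n, k)
  }, double(1))
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact Mann-Whitney two-sided p over all ways to label the pooled values.
oracle_mw_exact <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(b) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# One-hidden-layer tanh network (no recurrence) on a single input vector.
oracle_static_net <- function(Wi, Wo, x) {
  1 / (1 + exp(-sum(Wo * tanh(as.numeric(Wi %*% x)))))
}

# Tiny hand-built cohort tables ------------------------------------------

# One patient as a visit tibble; flags recycled across visits.
make_series <- function(pid, months, sdi, activity = rep(0L, length(months)),
                        flag_a = 0L, flag_b = 0L, sex = "F", age0 = 40) {
  tibble::tibble(
    patient_id = pid, month = months, sex = sex,
    age = age0 + months / 12,
    flag_a = as.integer(flag_a), flag_b = as.integer(flag_b),
    activity = as.integer(activity), sdi = as.integer(sdi)
  )
}

# A linearly separable toy dataset: one feature equals the label.
make_separable_dataset <- function(n_per_class = 10, t_len = 3, p_extra = 2,
                                   seed = 42) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    seqs <- list()
    for (lab in c(0L, 1L)) {
      for (i in seq_len(n_per_class)) {
        x <- cbind(signal = rep(lab, t_len),
                   matrix(rbinom(t_len * p_extra, 1, 0.5), t_len, p_extra))
        colnames(x) <- c("signal", paste0("noise", seq_len(p_extra)))
        seqs[[length(seqs) + 1]] <- list(
          patient_id = paste0("S", lab, "_", i), x = x, label = lab
        )
      }
    }
    lupusrnn:::new_damage_dataset(
      sequences = seqs,
      features = c("signal", paste0("noise", seq_len(p_extra))),
      binary = rep(TRUE, 1 + p_extra),
      age_center = 0, age_scale = 1
    )
  })
}

# Small encoded dataset from a generated cohort (shared across tests).
make_small_dataset <- function(n_patients = 60, seed = 11) {
  cohort <- generate_cohort(cohort_config(n_patients = n_patients, seed = seed))
  encode_features(select_analysis_set(cohort))
}
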