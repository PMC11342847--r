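test_that("parameter specifications carry the documented counts and bounds", {
  expect_equal(n_free_params("rw1"), 2)
  expect_equal(n_free_params("rw2"), 3)
  expect_equal(n_free_params("peirs"), 5)
  expect_equal(n_free_params("cvar"), 2)
  sp <- model_param_specs("cvar")
  expect_equal(sp$transform[sp$name == "eta"], "eta_logit")
  # transforms are invertible on their ranges
  for (m in c("rw1", "rw2", "peirs", "cvar")) {
    sp <- model_param_specs(m)
    for (i in seq_len(nrow(sp))) {
      x <- runif(1, sp$lower[i], sp$upper[i])
      nat <- cvarlearn:::to_natural(x, sp$transform[i])
      expect_equal(cvarlearn:::to_transformed(nat, sp$transform[i]), x,
                   tolerance = 1e-9)
    }
  }
})

test_that("a fully random decision stage gives exactly n log 2 deviance", {
  data <- make_subject("rw1", list(alpha = 0.3, beta = 5), seed = 8)
  for (m in c("rw1", "cvar")) {
    p <- if (m == "rw1") list(alpha = 0.3, beta = 0) else list(eta = 0.2, beta = 0)
    expect_equal(negative_log_likelihood(m, p, data), 120 * log(2))
  }
})

test_that("likelihoods equal a stepwise-replay oracle over random parameters", {
  set.seed(19)
  for (model in c("rw1", "rw2", "peirs", "cvar")) {
    data <- make_subject(model, random_test_params(model), seed = 55)
    for (i in 1:10) {
      params <- random_test_params(model)
      expect_equal(negative_log_likelihood(model, params, data),
                   oracle_nll(model, params, data), tolerance = 1e-10)
    }
  }
})

test_that("a spread-blind PEIRS likelihood collapses onto the one-rate model", {
  data <- make_subject("rw2", list(alpha_pos = 0.5, alpha_neg = 0.2, beta = 4),
                       seed = 14)
  for (alpha in c(0.2, 0.6)) {
    for (beta in c(1, 6)) {
      expect_identical(
        negative_log_likelihood("peirs",
                                list(alpha_q = alpha, alpha_s = 0.4, omega = 0,
                                     s0 = 0.3, beta = beta), data),
        negative_log_likelihood("rw1", list(alpha = alpha, beta = beta), data))
    }
  }
})

test_that("likelihood requires the four same-mean blocks", {
  data <- make_subject("rw1", list(alpha = 0.3, beta = 5), seed = 8)
  partial <- data[data$block_type != "BLNL", ]
  expect_error(negative_log_likelihood("rw1", list(alpha = 0.3, beta = 5), partial),
               "missing same-mean block")
})

test_that("BIC identities hold to machine precision", {
  expect_equal(bic(list(k = 2, n = 120, loglik = -80)), 2 * log(120) + 160)
  expect_equal(bic(list(k = 0, n = 5, loglik = 0)), 0)
  expect_equal(random_model_bic(120), 240 * log(2))
  data <- make_subject("cvar", list(eta = 0.4, beta = 6), seed = 23)
  fit <- fit_subject("rw1", data, restarts = 3, seed = 1)
  expect_identical(fit$bic, fit$k * log(fit$n) - 2 * fit$loglik)
  expect_equal(fit$n, 120)
})

test_that("fitting is deterministic under a seed and respects the bounds", {
  data <- make_subject("rw2", list(alpha_pos = 0.6, alpha_neg = 0.2, beta = 5),
                       seed = 33)
  f1 <- fit_subject("rw2", data, restarts = 4, seed = 2)
  f2 <- fit_subject("rw2", data, restarts = 4, seed = 2)
  expect_identical(f1, f2)
  sp <- model_param_specs("rw2")
  expect_true(all(f1$transformed >= sp$lower & f1$transformed <= sp$upper))
  expect_true(f1$converged)
})

test_that("a choice-random agent is fitted with beta at its floor", {
  data <- make_subject("rw1", list(alpha = 0.5, beta = 0), seed = 41)
  fit <- fit_subject("rw1", data, restarts = 4, seed = 3)
  expect_lt(fit$params$beta, 0.3)  # transformed floor is exp(-3) ~ 0.05
  expect_equal(fit$loglik, -120 * log(2), tolerance = 0.02)
})

test_that("asymmetric refits of symmetric-learner data recover a 0.5 bias", {
  set.seed(61)
  bias <- replicate(12, {
    params <- list(alpha = runif(1, 0.2, 0.7), beta = runif(1, 3, 9))
    data <- make_subject("rw1", params, seed = sample.int(1e6, 1))
    fit <- fit_subject("rw2", data, restarts = 4, seed = 5)
    positive_learning_bias(fit$params$alpha_pos, fit$params$alpha_neg)
  })
  expect_lt(abs(mean(bias) - 0.5), 0.1)
})

test_that("model comparison sums BIC and anchors the best model at zero", {
  fits <- rbind(
    data.frame(subject_id = "S1", model = "rw1", bic = 150, n = 120),
    data.frame(subject_id = "S1", model = "rw2", bic = 140, n = 120),
    data.frame(subject_id = "S2", model = "rw1", bic = 160, n = 120),
    data.frame(subject_id = "S2", model = "rw2", bic = 175, n = 120))
  cmp <- compare_models(fits, include_random = FALSE)
  expect_equal(cmp$delta_bic[cmp$model == "rw1"], 0)
  expect_equal(cmp$sum_bic[cmp$model == "rw2"], 315)
  cmp_r <- compare_models(fits)
  expect_equal(cmp_r$sum_bic[cmp_r$model == "random"], 2 * 240 * log(2))
  expect_error(compare_models(fits[-1, ]), "ragged")
  # equal likelihoods: the smaller model wins by exactly the penalty difference
  ll <- -80
  b2 <- bic(list(k = 2, n = 120, loglik = ll))
  b3 <- bic(list(k = 3, n = 120, loglik = ll))
  expect_equal(b3 - b2, log(120))
})

test_that("an empty recovery study returns empty tables without error", {
  rec <- parameter_recovery("rw1", n_agents = 0, seed = 1)
  expect_equal(nrow(rec$results), 0)
  expect_equal(nrow(rec$summary), 0)
})
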