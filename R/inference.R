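# Per-subject maximum-likelihood fitting on the four same-mean blocks,
# BIC model comparison, and parameter-recovery studies.
#
# Parameters are optimized on transformed scales whose finite ranges act as
# hard bounds: logit for learning rates, log for beta and s0, identity for
# omega, and logit((eta + 1) / 2) for the CVaR level. Optimization is
# multi-start Nelder-Mead with an out-of-bounds penalty; the CVaR likelihood
# is piecewise-constant in eta at grid resolution, which rules out
# gradient-based methods.

#' Parameter specifications for a model
#'
#' One row per free parameter: name, transform (`logit`, `log`, `identity`,
#' `eta_logit` for `logit((eta + 1) / 2)`) and the finite bounds on the
#' transformed scale within which fitting is constrained.
#'
#' @param model One of `"rw1"`, `"rw2"`, `"peirs"`, `"cvar"`.
#' @return Data frame with columns `name`, `transform`, `lower`, `upper`.
#' @export
model_param_specs <- function(model) {
  check_model(model)
  spec <- function(name, transform, lower, upper) {
    data.frame(name = name, transform = transform, lower = lower, upper = upper)
  }
  switch(model,
    rw1 = rbind(spec("alpha", "logit", -4.6, 4.6),
                spec("beta", "log", -3, 3)),
    rw2 = rbind(spec("alpha_pos", "logit", -4.6, 4.6),
                spec("alpha_neg", "logit", -4.6, 4.6),
                spec("beta", "log", -3, 3)),
    peirs = rbind(spec("alpha_q", "logit", -4.6, 4.6),
                  spec("alpha_s", "logit", -4.6, 4.6),
                  spec("omega", "identity", -10, 10),
                  spec("s0", "log", -4.6, 0),
                  spec("beta", "log", -3, 3)),
    cvar = rbind(spec("eta", "eta_logit", -7, 7),
                 spec("beta", "log", -3, 3))
  )
}

to_transformed <- function(value, transform) {
  switch(transform,
    logit = stats::qlogis(value),
    log = log(value),
    identity = value,
    eta_logit = stats::qlogis((value + 1) / 2)
  )
}

to_natural <- function(value, transform) {
  switch(transform,
    logit = stats::plogis(value),
    log = exp(value),
    identity = value,
    eta_logit = 2 * stats::plogis(value) - 1
  )
}

natural_params <- function(x, specs) {
  out <- lapply(seq_len(nrow(specs)), function(i) to_natural(x[i], specs$transform[i]))
  stats::setNames(out, specs$name)
}

#' Number of free parameters per model
#' @param model One of `"rw1"`, `"rw2"`, `"peirs"`, `"cvar"`.
#' @return Integer (rw1: 2, rw2: 3, peirs: 5, cvar: 2).
#' @export
n_free_params <- function(model) nrow(model_param_specs(model))

subject_same_mean_blocks <- function(data) {
  validate_choice_data(data)
  if (length(unique(data$subject_id)) > 1) {
    stop("expected data for a single subject", call. = FALSE)
  }
  present <- intersect(SAME_MEAN_BLOCKS, unique(data$block_type))
  missing <- setdiff(SAME_MEAN_BLOCKS, present)
  if (length(missing)) {
    stop("subject is missing same-mean block(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lapply(SAME_MEAN_BLOCKS, function(b) {
    d <- data[data$block_type == b, , drop = FALSE]
    d[order(d$trial), , drop = FALSE]
  })
}

# Builds a fast per-subject NLL closure over the same-mean blocks. Learning
# state resets at each block start (V = 0.5, flat belief, S = s0). For the
# CVaR model the belief trajectories (which depend only on the outcomes and
# updatevar) are precomputed once; each evaluation only re-reads the tails.
build_nll <- function(model, data, n_grid = 481, updatevar = 0.009,
                      clamp = 1e-12) {
  blocks <- subject_same_mean_blocks(data)
  chose_a <- lapply(blocks, function(b) b$choice == "a")
  n_obs <- sum(lengths(chose_a))

  nll_from_probs <- function(p_a_list) {
    total <- 0
    for (j in seq_along(p_a_list)) {
      p <- ifelse(chose_a[[j]], p_a_list[[j]], 1 - p_a_list[[j]])
      total <- total - sum(log(pmax(p, clamp)))
    }
    total
  }

  if (model == "cvar") {
    grid <- seq(0.01, 0.99, length.out = n_grid)
    E <- card_evidence_matrix(grid, updatevar)
    pre <- lapply(blocks, function(b) {
      n_t <- nrow(b)
      wa <- matrix(1 / n_grid, n_grid, 1); wb <- wa
      cfa <- matrix(NA_real_, n_grid, n_t); cza <- cfa; cfb <- cfa; czb <- cfa
      for (t in seq_len(n_t)) {
        cfa[, t] <- cumsum(wa); cza[, t] <- cumsum(grid * wa)
        cfb[, t] <- cumsum(wb); czb[, t] <- cumsum(grid * wb)
        wa <- normalize_cols(wa * E[, b$outcome_a[t], drop = FALSE])
        wb <- normalize_cols(wb * E[, b$outcome_b[t], drop = FALSE])
      }
      list(cfa = cfa, cza = cza, cfb = cfb, czb = czb)
    })
    function(params) {
      p_a <- lapply(pre, function(m) {
        va <- cvar_readout_batch(m$cfa, m$cza, params$eta)
        vb <- cvar_readout_batch(m$cfb, m$czb, params$eta)
        stats::plogis(params$beta * (va - vb))
      })
      nll_from_probs(p_a)
    }
  } else {
    Ra <- lapply(blocks, function(b) matrix(rescale_card(b$outcome_a)))
    Rb <- lapply(blocks, function(b) matrix(rescale_card(b$outcome_b)))
    function(params) {
      p_a <- lapply(seq_along(Ra), function(j) {
        drop(probs_rw_family(model, params, Ra[[j]], Rb[[j]]))
      })
      nll_from_probs(p_a)
    }
  }
}

#' Negative log-likelihood of a subject's same-mean-block choices
#'
#' Sums `-log P(choice_t)` over all trials of the four same-mean blocks
#' (BHNH, BLNL, BiHNH, BiLNL), with per-trial probabilities from the model's
#' decision values passed through the softmax rule. Learning state resets at
#' each block start. Probabilities are clamped below at `clamp` (with a
#' warning when the clamp is hit).
#'
#' @param model One of `"rw1"`, `"rw2"`, `"peirs"`, `"cvar"`.
#' @param params Named list of model parameters (natural scale).
#' @param data Trial table for one subject containing the same-mean blocks.
#' @param n_grid,updatevar Belief-grid resolution and evidence variance
#'   (`"cvar"` only; `updatevar` is a fixed hyperparameter, not fitted).
#' @param clamp Lower probability floor (default 1e-12).
#' @return Scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(model, params, data,
                                    n_grid = 481, updatevar = 0.009,
                                    clamp = 1e-12) {
  check_model(model)
  check_params(model, params)
  nll <- build_nll(model, data, n_grid = n_grid, updatevar = updatevar,
                   clamp = clamp)
  # an unclamped evaluation reveals whether the floor was hit
  raw <- build_nll(model, data, n_grid = n_grid, updatevar = updatevar, clamp = 0)
  v <- nll(params)
  v_raw <- raw(params)
  if (!is.finite(v_raw) || v_raw > v + 1e-12 * abs(v)) {
    warning("some choice probabilities underflowed and were clamped at ", clamp,
            call. = FALSE)
  }
  v
}

#' Fit one subject by multi-start maximum likelihood
#'
#' Minimizes the same-mean-block negative log-likelihood over the bounded
#' transformed parameter space with `restarts` Nelder-Mead runs (first start
#' at the box midpoint, the rest drawn uniformly in the box). Deterministic
#' given `seed`.
#'
#' @inheritParams negative_log_likelihood
#' @param data Trial table for one subject.
#' @param restarts Number of optimizer starts (default 10).
#' @param seed Optional integer seed for the start draws.
#' @param maxit Nelder-Mead iteration cap per start.
#' @return Object of class `fit_result`: `model`, `params` (natural scale),
#'   `loglik`, `k`, `n`, `bic`, `converged`, `restarts`.
#' @export
fit_subject <- function(model, data, restarts = 10, seed = NULL,
                        n_grid = 481, updatevar = 0.009, maxit = 500) {
  check_model(model)
  specs <- model_param_specs(model)
  nll <- build_nll(model, data, n_grid = n_grid, updatevar = updatevar)
  n_obs <- sum(data$block_type %in% SAME_MEAN_BLOCKS)

  objective <- function(x) {
    over <- pmax(x - specs$upper, 0) + pmax(specs$lower - x, 0)
    if (any(over > 0)) return(1e10 + sum(over) * 1e6)
    v <- nll(natural_params(x, specs))
    if (!is.finite(v)) 1e10 else v
  }

  k <- nrow(specs)
  draw_starts <- function() {
    mid <- (specs$lower + specs$upper) / 2
    more <- if (restarts > 1) {
      lapply(seq_len(restarts - 1), function(i) {
        stats::runif(k, specs$lower, specs$upper)
      })
    } else list()
    c(list(mid), more)
  }
  starts <- if (is.null(seed)) draw_starts() else withr::with_seed(seed, draw_starts())

  best <- NULL
  any_converged <- FALSE
  for (x0 in starts) {
    res <- tryCatch(
      stats::optim(x0, objective, method = "Nelder-Mead",
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) any_converged <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimizer restarts failed", call. = FALSE)

  x <- pmin(pmax(best$par, specs$lower), specs$upper)
  loglik <- -nll(natural_params(x, specs))
  structure(list(
    model = model,
    params = natural_params(x, specs),
    transformed = stats::setNames(x, specs$name),
    loglik = loglik,
    k = k,
    n = n_obs,
    bic = k * log(n_obs) - 2 * loglik,
    converged = any_converged,
    restarts = length(starts)
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result %s: logLik %.3f, k %d, n %d, BIC %.3f%s>\n",
              x$model, x$loglik, x$k, x$n, x$bic,
              if (x$converged) "" else " [not converged]"))
  p <- unlist(x$params)
  cat("  ", paste(sprintf("%s = %.4f", names(p), p), collapse = ", "), "\n")
  invisible(x)
}

#' Bayesian information criterion
#'
#' `BIC = k * ln(n) - 2 * ln(L)`. The random-model baseline sets every
#' decision probability to 0.5 with no free parameters, so its BIC is
#' `-2 * n * ln(0.5)`.
#'
#' @param fit A `fit_result` (or any list with `k`, `n`, `loglik`).
#' @return Scalar BIC.
#' @export
bic <- function(fit) {
  fit$k * log(fit$n) - 2 * fit$loglik
}

#' @rdname bic
#' @param n Number of observations.
#' @export
random_model_bic <- function(n) {
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  -2 * n * log(0.5)
}

#' Fit all subjects with one or more models
#'
#' Convenience wrapper around [fit_subject()] producing a long table of fits,
#' one row per subject x model, with the fitted parameters spread into
#' columns (NA where a parameter does not belong to the model).
#'
#' @param data Trial table covering one or more subjects.
#' @param models Character vector of models to fit.
#' @inheritParams fit_subject
#' @return Data frame with columns `subject_id`, `model`, parameter columns,
#'   `loglik`, `k`, `n`, `bic`, `converged`.
#' @export
fit_cohort <- function(data, models = MODELS, restarts = 10, seed = NULL,
                       n_grid = 481, updatevar = 0.009, maxit = 500) {
  validate_choice_data(data)
  ids <- unique(data$subject_id)
  all_params <- unique(unlist(lapply(models, function(m) model_param_specs(m)$name)))
  seeds <- if (is.null(seed)) rep(list(NULL), length(ids)) else
    withr::with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, length(ids))))
  rows <- list()
  for (i in seq_along(ids)) {
    sub <- data[data$subject_id == ids[i], , drop = FALSE]
    for (m in models) {
      fit <- fit_subject(m, sub, restarts = restarts, seed = seeds[[i]],
                         n_grid = n_grid, updatevar = updatevar, maxit = maxit)
      row <- data.frame(subject_id = ids[i], model = m,
                        loglik = fit$loglik, k = fit$k, n = fit$n,
                        bic = fit$bic, converged = fit$converged)
      for (p in all_params) row[[p]] <- fit$params[[p]] %||% NA_real_
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("subject_id", "model", all_params, "loglik", "k", "n", "bic", "converged")]
}

#' Compare models by summed BIC
#'
#' Sums per-subject BIC scores within each model and reports the difference
#' from the best (lowest) model. Every subject must have a fit for every
#' model. A `random` baseline row (probability 0.5 for every choice, k = 0)
#' is appended.
#'
#' @param fits Data frame as produced by [fit_cohort()] (needs `subject_id`,
#'   `model`, `bic`, `n`).
#' @param include_random Append the random-model baseline (default TRUE).
#' @return Data frame with `model`, `sum_bic`, `delta_bic`, `n_subjects`,
#'   ordered by `sum_bic`.
#' @export
compare_models <- function(fits, include_random = TRUE) {
  tab <- table(fits$subject_id, fits$model)
  if (any(tab != 1)) {
    stop("ragged fit set: every subject needs exactly one fit per model",
         call. = FALSE)
  }
  sums <- stats::aggregate(bic ~ model, data = fits, FUN = sum)
  names(sums)[names(sums) == "bic"] <- "sum_bic"
  sums$n_subjects <- length(unique(fits$subject_id))
  if (include_random) {
    n_per <- fits$n[!duplicated(fits$subject_id)]
    sums <- rbind(sums, data.frame(model = "random",
                                   sum_bic = sum(random_model_bic(n_per)),
                                   n_subjects = sums$n_subjects[1]))
  }
  sums$delta_bic <- sums$sum_bic - min(sums$sum_bic)
  sums[order(sums$sum_bic), c("model", "sum_bic", "delta_bic", "n_subjects")]
}

#' Parameter recovery study
#'
#' Simulates a cohort from known generating parameters, refits every agent,
#' and reports per-parameter Pearson correlation and mean signed error
#' between generating and recovered values.
#'
#' @param model Generating (and fitted) model.
#' @param n_agents Cohort size.
#' @param seed Integer seed driving both generation and fitting.
#' @param param_sampler Optional sampler override (see [cohort_spec()]).
#' @inheritParams fit_subject
#' @return List with `results` (per-agent generating and recovered values)
#'   and `summary` (per-parameter `r` and `mean_signed_error`). Empty cohorts
#'   yield empty tables.
#' @export
parameter_recovery <- function(model, n_agents = 50, seed = 1,
                               param_sampler = NULL, restarts = 10,
                               n_grid = 481, updatevar = 0.009, maxit = 500) {
  check_model(model)
  pnames <- model_param_specs(model)$name
  if (n_agents == 0) {
    empty <- data.frame(subject_id = character(0))
    return(list(results = empty,
                summary = data.frame(param = character(0), r = numeric(0),
                                     mean_signed_error = numeric(0))))
  }
  cohort <- cohort_spec(n_agents, model, param_sampler = param_sampler,
                        seed = seed)
  gen <- generate_cohort(cohort, n_grid = n_grid, updatevar = updatevar)
  fits <- fit_cohort(gen$choices, models = model, restarts = restarts,
                     seed = seed + 1L, n_grid = n_grid, updatevar = updatevar,
                     maxit = maxit)
  results <- merge(gen$params, fits[, c("subject_id", pnames, "loglik", "bic",
                                        "converged")],
                   by = "subject_id", suffixes = c("_gen", "_fit"))
  summary <- do.call(rbind, lapply(pnames, function(p) {
    g <- results[[paste0(p, "_gen")]]
    f <- results[[paste0(p, "_fit")]]
    data.frame(param = p,
               r = if (stats::sd(g) > 0 && stats::sd(f) > 0) stats::cor(g, f) else NA_real_,
               mean_signed_error = mean(f - g))
  }))
  list(results = results, summary = summary)
}
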