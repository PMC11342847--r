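# Block simulation and the four-condition parameter-sweep study.
#
# With full feedback both decks are updated every trial regardless of choice,
# so the learning trajectories of every model depend only on the outcome
# streams. The engines below exploit this: they compute per-trial choice
# probabilities for a whole batch of blocks at once (trials x blocks
# matrices), and choices are then sampled from those probabilities.

MODELS <- c("rw1", "rw2", "peirs", "cvar")

CONDITION_BLOCKS <- c(
  "both-narrow" = "NHNL",
  "both-broad"  = "BHBL",
  "both-high"   = "BHNH",
  "both-low"    = "BLNL"
)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_model <- function(model) {
  if (!is.character(model) || length(model) != 1 || !model %in% MODELS) {
    stop("unknown model; expected one of ", paste(MODELS, collapse = ", "),
         call. = FALSE)
  }
  model
}

required_params <- function(model) {
  switch(model,
    rw1   = c("alpha", "beta"),
    rw2   = c("alpha_pos", "alpha_neg", "beta"),
    peirs = c("alpha_q", "alpha_s", "omega", "s0", "beta"),
    cvar  = c("eta", "beta")
  )
}

check_params <- function(model, params) {
  missing <- setdiff(required_params(model), names(params))
  if (length(missing)) {
    stop("model '", model, "' is missing parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  params
}

# Choice probabilities for the RW-family models on rescaled outcome matrices
# Ra, Rb (trials x blocks). Values reset to 0.5 (and spread to s0) at t = 1.
probs_rw_family <- function(model, params, Ra, Rb) {
  n_t <- nrow(Ra); n_b <- ncol(Ra)
  va <- rep(0.5, n_b); vb <- rep(0.5, n_b)
  if (model == "peirs") {
    sa <- rep(params$s0, n_b); sb <- rep(params$s0, n_b)
  }
  P <- matrix(NA_real_, n_t, n_b)
  for (t in seq_len(n_t)) {
    if (model == "peirs") {
      adj <- tanh(params$omega * ((va + vb) / 2 - 0.5))
      P[t, ] <- stats::plogis(params$beta * ((va + adj * sa) - (vb + adj * sb)))
    } else {
      P[t, ] <- stats::plogis(params$beta * (va - vb))
    }
    da <- Ra[t, ] - va
    db <- Rb[t, ] - vb
    if (model == "rw1") {
      va <- va + params$alpha * da
      vb <- vb + params$alpha * db
    } else if (model == "rw2") {
      va <- va + ifelse(da >= 0, params$alpha_pos, params$alpha_neg) * da
      vb <- vb + ifelse(db >= 0, params$alpha_pos, params$alpha_neg) * db
    } else {
      va <- va + params$alpha_q * da
      vb <- vb + params$alpha_q * db
      sa <- sa + params$alpha_s * (abs(da) - sa)
      sb <- sb + params$alpha_s * (abs(db) - sb)
    }
  }
  P
}

col_cumsum <- function(m) apply(m, 2, cumsum)

normalize_cols <- function(w) {
  tot <- colSums(w)
  if (any(!is.finite(tot)) || any(tot <= 0)) {
    stop("belief update underflowed to an all-zero density", call. = FALSE)
  }
  w / rep(tot, each = nrow(w))
}

# CVaR decision-value trajectories for card-index outcome matrices Oa, Ob
# (trials x blocks), for every eta in `etas` at once. Belief evolution does
# not depend on eta or beta, so it is computed a single time per batch.
# Returns list(va = list per eta of trials x blocks, vb = likewise).
cvar_value_trajectories <- function(Oa, Ob, etas, n_grid = 481, updatevar = 0.009) {
  n_t <- nrow(Oa); n_b <- ncol(Oa)
  grid <- seq(0.01, 0.99, length.out = n_grid)
  E <- card_evidence_matrix(grid, updatevar)
  wa <- matrix(1 / n_grid, n_grid, n_b)
  wb <- matrix(1 / n_grid, n_grid, n_b)
  va <- lapply(etas, function(e) matrix(NA_real_, n_t, n_b))
  vb <- lapply(etas, function(e) matrix(NA_real_, n_t, n_b))
  for (t in seq_len(n_t)) {
    cfa <- col_cumsum(wa); cza <- col_cumsum(grid * wa)
    cfb <- col_cumsum(wb); czb <- col_cumsum(grid * wb)
    for (k in seq_along(etas)) {
      va[[k]][t, ] <- cvar_readout_batch(cfa, cza, etas[k])
      vb[[k]][t, ] <- cvar_readout_batch(cfb, czb, etas[k])
    }
    wa <- normalize_cols(wa * E[, Oa[t, ], drop = FALSE])
    wb <- normalize_cols(wb * E[, Ob[t, ], drop = FALSE])
  }
  list(va = va, vb = vb)
}

# Per-trial probability of choosing deck a for one block's card outcomes.
trial_choice_probs <- function(model, params, outcome_a, outcome_b,
                               n_grid = 481, updatevar = 0.009) {
  if (model == "cvar") {
    traj <- cvar_value_trajectories(matrix(outcome_a), matrix(outcome_b),
                                    etas = params$eta, n_grid = n_grid,
                                    updatevar = updatevar)
    drop(stats::plogis(params$beta * (traj$va[[1]] - traj$vb[[1]])))
  } else {
    drop(probs_rw_family(model, params,
                         matrix(rescale_card(outcome_a)),
                         matrix(rescale_card(outcome_b))))
  }
}

#' Simulate one agent playing one block
#'
#' Per trial the model's decision values are computed from the learning state,
#' a choice is drawn through the softmax rule, both outcomes are revealed, and
#' both decks are updated (full feedback).
#'
#' @param model One of `"rw1"` (single learning rate), `"rw2"` (asymmetric
#'   learning rates), `"peirs"` (value plus spread), `"cvar"` (Bayesian
#'   learner with CVaR readout).
#' @param params Named list of model parameters, e.g. `list(alpha = 0.3,
#'   beta = 5)` for `"rw1"` or `list(eta = -0.3, beta = 5)` for `"cvar"`.
#' @param spec A [make_block_spec()].
#' @param seed Optional integer seed (outcomes and choices reproducible).
#' @param n_grid,updatevar Belief-grid resolution and evidence variance for
#'   the `"cvar"` model.
#' @return List with `choice` (character, "a"/"b"), `p_a` (per-trial
#'   probability of choosing a), `outcome_a`, `outcome_b` (card scale) and
#'   `points` (chosen minus unchosen card value).
#' @export
simulate_block <- function(model, params, spec, seed = NULL,
                           n_grid = 481, updatevar = 0.009) {
  check_model(model)
  check_params(model, params)
  stopifnot(inherits(spec, "block_spec"))
  run <- function() {
    out <- sample_trial_outcomes(spec)
    p_a <- trial_choice_probs(model, params, out$outcome_a, out$outcome_b,
                              n_grid = n_grid, updatevar = updatevar)
    choice <- ifelse(stats::runif(spec$n_trials) < p_a, "a", "b")
    points <- ifelse(choice == "a",
                     out$outcome_a - out$outcome_b,
                     out$outcome_b - out$outcome_a)
    list(choice = choice, p_a = p_a,
         outcome_a = out$outcome_a, outcome_b = out$outcome_b,
         points = as.integer(points))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# nuisance-parameter lattices: `n` evenly spaced values across each free
# parameter's transformed prior range (beta and s0 on the log scale, learning
# rates on the logit scale, eta through logit((eta + 1) / 2), omega on its
# natural range). The swept parameter is excluded; sweeping the positive
# learning bias marginalizes the total learning rate instead of the two
# rates, so the bias stays exact at each swept value (alpha_pos = p * total,
# alpha_neg = (1 - p) * total).
nuisance_lattice <- function(model, sweep_name, n) {
  grid_for <- function(name) {
    switch(name,
      beta = exp(seq(-3, 3, length.out = n)),
      alpha = ,
      alpha_pos = ,
      alpha_neg = ,
      alpha_q = ,
      alpha_s = stats::plogis(seq(-4.6, 4.6, length.out = n)),
      s0 = exp(seq(-4.6, 0, length.out = n)),
      omega = seq(-10, 10, length.out = n),
      eta = 2 * stats::plogis(seq(-7, 7, length.out = n)) - 1)
  }
  lat <- list()
  if (model == "rw2" && sweep_name == "lr_pos_bias") {
    lat$beta <- grid_for("beta")
    lat$alpha_total <- seq(0.2, 1.0, length.out = n)
  } else {
    for (nm in setdiff(required_params(model), sweep_name)) {
      lat[[nm]] <- grid_for(nm)
    }
  }
  expand.grid(lat, KEEP.OUT.ATTRS = FALSE)
}

default_sweep <- function(model) {
  switch(model,
    rw1   = list(name = "alpha",       values = stats::plogis(seq(-4.6, 4.6, length.out = 9))),
    rw2   = list(name = "lr_pos_bias", values = seq(0.1, 0.9, length.out = 9)),
    peirs = list(name = "omega",       values = seq(-10, 10, length.out = 9)),
    cvar  = list(name = "eta",         values = seq(-0.95, 0.95, length.out = 9))
  )
}

sweep_params <- function(model, sweep_name, value, nuis) {
  p <- as.list(nuis)
  if (sweep_name == "lr_pos_bias") {
    p$alpha_pos <- value * p$alpha_total
    p$alpha_neg <- (1 - value) * p$alpha_total
    p$alpha_total <- NULL
  } else {
    p[[sweep_name]] <- value
  }
  p
}

#' Parameter-sweep simulation study
#'
#' Reproduces the four-condition simulation design: for each condition
#' (both-narrow = NHNL, both-broad = BHBL, both-high = BHNH, both-low = BLNL)
#' `n_blocks` blocks of `n_trials` trials are generated, agents of the given
#' model play them across a sweep of one parameter, and the percentage of
#' choices of option a (the higher-mean option in different-mean conditions,
#' the broader option in same-mean conditions) is averaged over blocks and
#' over an even lattice of the model's other free parameters. The outcome
#' streams depend only on `seed`, `conditions`, `n_blocks` and `n_trials`, so
#' the same events are reused when different models are swept under one seed.
#'
#' @param model One of `"rw1"`, `"rw2"`, `"peirs"`, `"cvar"`.
#' @param conditions Subset of `c("both-narrow", "both-broad", "both-high",
#'   "both-low")`.
#' @param sweep List with `name` and `values`; default sweeps the model's
#'   signature parameter (alpha, lr_pos_bias, omega or eta).
#' @param n_blocks Blocks per condition per swept value (default 500).
#' @param n_trials Trials per block (default 30).
#' @param n_lattice Lattice points per marginalized parameter (default 9).
#' @param n_grid,updatevar Belief-grid resolution and evidence variance
#'   (`"cvar"` only).
#' @param seed Optional integer seed.
#' @param config Optional [task_config()] overriding deck distributions.
#' @return Data frame with columns `model`, `condition`, `param_name`,
#'   `param_value`, `pct_choose_a`, `n_blocks`.
#' @export
run_parameter_sweep <- function(model,
                                conditions = names(CONDITION_BLOCKS),
                                sweep = NULL,
                                n_blocks = 500, n_trials = 30, n_lattice = 9,
                                n_grid = 481, updatevar = 0.009,
                                seed = NULL, config = NULL) {
  check_model(model)
  bad <- setdiff(conditions, names(CONDITION_BLOCKS))
  if (length(bad)) stop("unknown condition(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  sweep <- sweep %||% default_sweep(model)
  if (!length(sweep$values)) stop("sweep grid is empty", call. = FALSE)
  config <- config %||% task_config(n_trials = n_trials)

  run <- function() {
    # outcome streams first, in fixed condition order: identical events for
    # every model swept under the same seed
    streams <- lapply(names(CONDITION_BLOCKS), function(cond) {
      spec <- make_block_spec(CONDITION_BLOCKS[[cond]], config)
      list(
        Oa = matrix(sample(CARD_VALUES, n_trials * n_blocks, replace = TRUE,
                           prob = spec$deck_a), n_trials, n_blocks),
        Ob = matrix(sample(CARD_VALUES, n_trials * n_blocks, replace = TRUE,
                           prob = spec$deck_b), n_trials, n_blocks)
      )
    })
    names(streams) <- names(CONDITION_BLOCKS)

    nuis <- nuisance_lattice(model, sweep$name, n_lattice)
    if (nrow(nuis) == 0) nuis <- data.frame(.dummy = 1)

    rows <- list()
    for (cond in conditions) {
      st <- streams[[cond]]
      if (model == "cvar" && sweep$name == "eta") {
        traj <- cvar_value_trajectories(st$Oa, st$Ob, etas = sweep$values,
                                        n_grid = n_grid, updatevar = updatevar)
        for (k in seq_along(sweep$values)) {
          pcts <- vapply(seq_len(nrow(nuis)), function(i) {
            beta <- nuis$beta[i]
            P <- stats::plogis(beta * (traj$va[[k]] - traj$vb[[k]]))
            100 * mean(stats::runif(length(P)) < P)
          }, numeric(1))
          rows[[length(rows) + 1L]] <- data.frame(
            model = model, condition = cond, param_name = sweep$name,
            param_value = sweep$values[k], pct_choose_a = mean(pcts),
            n_blocks = n_blocks)
        }
      } else {
        Ra <- rescale_card(st$Oa); Rb <- rescale_card(st$Ob)
        for (k in seq_along(sweep$values)) {
          pcts <- vapply(seq_len(nrow(nuis)), function(i) {
            p <- sweep_params(model, sweep$name, sweep$values[k],
                              nuis[i, setdiff(names(nuis), ".dummy"), drop = FALSE])
            P <- if (model == "cvar") {
              tr <- cvar_value_trajectories(st$Oa, st$Ob, etas = p$eta,
                                            n_grid = n_grid, updatevar = updatevar)
              stats::plogis(p$beta * (tr$va[[1]] - tr$vb[[1]]))
            } else {
              probs_rw_family(model, check_params(model, p), Ra, Rb)
            }
            100 * mean(stats::runif(length(P)) < P)
          }, numeric(1))
          rows[[length(rows) + 1L]] <- data.frame(
            model = model, condition = cond, param_name = sweep$name,
            param_value = sweep$values[k], pct_choose_a = mean(pcts),
            n_blocks = n_blocks)
        }
      }
    }
    do.call(rbind, rows)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
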