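# Trial-by-trial learning rules shared by the simulator and the likelihoods.
# All models operate on outcomes rescaled to [0.01, 0.99] and start each block
# from an expected value of 0.5 (the rescaled global card mean of 7).

#' Softmax choice probability
#'
#' Probability of choosing option a given the two decision values and the
#' inverse temperature: `P_a = 1 / (1 + exp(-beta * (value_a - value_b)))`.
#' `beta = 0` gives fully random choice (P = 0.5); large `beta` approaches
#' deterministic maximization.
#'
#' @param value_a,value_b Decision values (finite numerics, vectorized).
#' @param beta Inverse temperature, `>= 0`.
#' @return Probability of choosing a, in (0, 1).
#' @examples
#' softmax_prob(0.6, 0.5, 10)  # 1 / (1 + exp(-1))
#' @export
softmax_prob <- function(value_a, value_b, beta) {
  if (!all(is.finite(value_a)) || !all(is.finite(value_b)) || !all(is.finite(beta))) {
    stop("softmax_prob: inputs must be finite", call. = FALSE)
  }
  if (any(beta < 0)) stop("softmax_prob: beta must be >= 0", call. = FALSE)
  stats::plogis(beta * (value_a - value_b))
}

#' Initial Rescorla-Wagner state
#'
#' Expected values start at 0.5 for both decks; for the PEIRS model the
#' expected spread starts at `s0`.
#'
#' @param s0 Initial spread (PEIRS only); `NULL` for plain RW states.
#' @return List with named numeric `v` (and `s` when `s0` is given).
#' @export
rw_state <- function(s0 = NULL) {
  st <- list(v = c(a = 0.5, b = 0.5))
  if (!is.null(s0)) {
    if (s0 < 0) stop("initial spread must be >= 0", call. = FALSE)
    st$s <- c(a = s0, b = s0)
  }
  st
}

check_outcome <- function(outcome) {
  if (!is.numeric(outcome) || anyNA(outcome) ||
      any(outcome < 0.01 - 1e-12 | outcome > 0.99 + 1e-12)) {
    stop("outcome must be on the rescaled [0.01, 0.99] scale", call. = FALSE)
  }
}

#' Single-learning-rate Rescorla-Wagner update
#'
#' `V <- V + alpha * (R - V)` for the given deck only.
#'
#' @param state A [rw_state()].
#' @param deck `"a"` or `"b"`.
#' @param outcome Rescaled outcome in \[0.01, 0.99\].
#' @param params List with `alpha` and `beta` (only `alpha` is used here).
#' @return Updated state.
#' @export
rw1_step <- function(state, deck, outcome, params) {
  check_outcome(outcome)
  delta <- outcome - state$v[[deck]]
  state$v[[deck]] <- state$v[[deck]] + params$alpha * delta
  state
}

#' Asymmetric two-learning-rate Rescorla-Wagner update
#'
#' Positive prediction errors (`delta >= 0`, ties included) are scaled by
#' `alpha_pos`, negative ones by `alpha_neg`.
#'
#' @inheritParams rw1_step
#' @param params List with `alpha_pos`, `alpha_neg`, `beta`.
#' @return Updated state.
#' @export
rw2_step <- function(state, deck, outcome, params) {
  check_outcome(outcome)
  delta <- outcome - state$v[[deck]]
  alpha <- if (delta >= 0) params$alpha_pos else params$alpha_neg
  state$v[[deck]] <- state$v[[deck]] + alpha * delta
  state
}

#' Positive learning bias
#'
#' The ratio `alpha_pos / (alpha_pos + alpha_neg)`; 0.5 is symmetric learning,
#' values above 0.5 overweight positive prediction errors (pro-variance).
#'
#' @param alpha_pos,alpha_neg Positive learning rates.
#' @return Ratio in (0, 1).
#' @export
positive_learning_bias <- function(alpha_pos, alpha_neg) {
  if (any(alpha_pos <= 0) || any(alpha_neg <= 0)) {
    stop("learning rates must be > 0", call. = FALSE)
  }
  alpha_pos / (alpha_pos + alpha_neg)
}

#' PEIRS value-and-spread update
#'
#' Learns the expected value with rate `alpha_q` and the expected spread (mean
#' absolute prediction error) with rate `alpha_s`:
#' `V <- V + alpha_q * delta`, `S <- S + alpha_s * (|delta| - S)`.
#'
#' @inheritParams rw1_step
#' @param params List with `alpha_q`, `alpha_s`, `omega`, `s0`, `beta`.
#' @return Updated state (spread stays nonnegative).
#' @export
peirs_step <- function(state, deck, outcome, params) {
  check_outcome(outcome)
  delta <- outcome - state$v[[deck]]
  state$v[[deck]] <- state$v[[deck]] + params$alpha_q * delta
  state$s[[deck]] <- state$s[[deck]] + params$alpha_s * (abs(delta) - state$s[[deck]])
  state
}

#' PEIRS decision values
#'
#' The spread is added to (or subtracted from) the learned values depending on
#' whether the offered options are jointly better or worse than the global
#' mean 0.5: with `d = (V_a + V_b)/2 - 0.5`, the decision value is
#' `V' = V + tanh(omega * d) * S` for each deck.
#'
#' @param state A PEIRS [rw_state()] (with spreads).
#' @param params List with `omega`.
#' @return Named numeric `c(a =, b =)` of decision values.
#' @export
peirs_decision_values <- function(state, params) {
  d_options <- (state$v[["a"]] + state$v[["b"]]) / 2 - 0.5
  adj <- tanh(params$omega * d_options)
  c(a = state$v[["a"]] + adj * state$s[["a"]],
    b = state$v[["b"]] + adj * state$s[["b"]])
}
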