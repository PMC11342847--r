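# Independent oracles and fixture builders. The oracles replay model dynamics
# through the exported single-step functions (or plain loops), never through
# the package's vectorized engines or likelihoods, so engine/likelihood tests
# compare two independent code paths.

ALL_BLOCKS <- c("BHBL", "NHNL", "BHNL", "NHBL", "BHNH", "BLNL", "BiHNH", "BiLNL")
SAME_MEAN <- c("BHNH", "BLNL", "BiHNH", "BiLNL")

# per-trial choice probabilities by stepwise replay
oracle_choice_probs <- function(model, params, outcome_a, outcome_b,
                                n_grid = 481, updatevar = 0.009) {
  n <- length(outcome_a)
  ra <- rescale_card(outcome_a)
  rb <- rescale_card(outcome_b)
  p <- numeric(n)
  if (model == "cvar") {
    ba <- belief_grid(n_grid)
    bb <- belief_grid(n_grid)
    for (t in seq_len(n)) {
      p[t] <- softmax_prob(cvar_readout(ba, params$eta),
                           cvar_readout(bb, params$eta), params$beta)
      ba <- bayes_update(ba, ra[t], updatevar)
      bb <- bayes_update(bb, rb[t], updatevar)
    }
  } else if (model == "peirs") {
    st <- rw_state(s0 = params$s0)
    for (t in seq_len(n)) {
      dv <- peirs_decision_values(st, params)
      p[t] <- softmax_prob(dv[["a"]], dv[["b"]], params$beta)
      st <- peirs_step(st, "a", ra[t], params)
      st <- peirs_step(st, "b", rb[t], params)
    }
  } else {
    st <- rw_state()
    step <- if (model == "rw1") rw1_step else rw2_step
    for (t in seq_len(n)) {
      p[t] <- softmax_prob(st$v[["a"]], st$v[["b"]], params$beta)
      st <- step(st, "a", ra[t], params)
      st <- step(st, "b", rb[t], params)
    }
  }
  p
}

# negative log-likelihood by stepwise replay over the same-mean blocks
oracle_nll <- function(model, params, data, n_grid = 481, updatevar = 0.009) {
  total <- 0
  for (b in SAME_MEAN) {
    d <- data[data$block_type == b, ]
    d <- d[order(d$trial), ]
    p_a <- oracle_choice_probs(model, params, d$outcome_a, d$outcome_b,
                               n_grid, updatevar)
    p <- ifelse(d$choice == "a", p_a, 1 - p_a)
    total <- total - sum(log(p))
  }
  total
}

# brute-force CVaR on a discrete belief: scan for the tail cut, then an
# explicit conditional expectation over the selected grid points
oracle_cvar <- function(grid, w, eta) {
  w <- w / sum(w)
  thr <- if (eta <= 0) 1 + eta else eta
  acc <- 0
  idx <- NA
  for (i in seq_along(w)) {
    acc <- acc + w[i]
    if (acc >= thr - 1e-12) { idx <- i; break }
  }
  sel <- if (eta <= 0) seq_len(idx) else idx:length(w)
  num <- 0; den <- 0
  for (i in sel) { num <- num + grid[i] * w[i]; den <- den + w[i] }
  num / den
}

random_test_params <- function(model, rng) {
  switch(model,
    rw1   = list(alpha = runif(1, 0.05, 0.95), beta = runif(1, 0.5, 10)),
    rw2   = list(alpha_pos = runif(1, 0.05, 0.95), alpha_neg = runif(1, 0.05, 0.95),
                 beta = runif(1, 0.5, 10)),
    peirs = list(alpha_q = runif(1, 0.05, 0.95), alpha_s = runif(1, 0.05, 0.95),
                 omega = runif(1, -8, 8), s0 = runif(1, 0.02, 0.9),
                 beta = runif(1, 0.5, 10)),
    cvar  = list(eta = runif(1, -0.9, 0.9), beta = runif(1, 0.5, 10))
  )
}

# one complete synthetic subject (8 blocks) played under known parameters
make_subject <- function(model, params, seed = 1, id = "S1") {
  rows <- lapply(seq_along(ALL_BLOCKS), function(i) {
    spec <- make_block_spec(ALL_BLOCKS[i])
    sim <- simulate_block(model, params, spec, seed = seed * 100 + i)
    data.frame(subject_id = id, block_type = ALL_BLOCKS[i],
               trial = seq_len(spec$n_trials), choice = sim$choice,
               outcome_a = sim$outcome_a, outcome_b = sim$outcome_b,
               points = sim$points)
  })
  do.call(rbind, rows)
}

# toy trial table with a prescribed number of "a" choices per block
toy_subject <- function(a_counts, n_trials = 30, id = "S1") {
  rows <- lapply(names(a_counts), function(b) {
    ch <- rep(c("a", "b"), c(a_counts[[b]], n_trials - a_counts[[b]]))
    data.frame(subject_id = id, block_type = b, trial = seq_len(n_trials),
               choice = ch, outcome_a = 8L, outcome_b = 6L,
               points = ifelse(ch == "a", 2L, -2L))
  })
  do.call(rbind, rows)
}
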