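# Bayesian distributional learner with a Conditional Value at Risk readout.
# The belief over a deck's value distribution is represented on a fixed grid
# of points strictly inside (0, 1); each observed outcome contributes a Beta
# evidence density with mean equal to the outcome and fixed variance
# `updatevar`, multiplied into the prior pointwise and renormalized.

#' Construct a belief grid
#'
#' A discrete belief over the open unit interval: ordered grid points with one
#' nonnegative weight each, summing to 1. The default flat initialization is
#' the Beta(1, 1) prior (every value equally likely). The default 481-point
#' grid on \[0.01, 0.99\] contains every rescaled card value exactly.
#'
#' @param n Number of grid points (default 481).
#' @param lo,hi Grid end points, `0 < lo < hi < 1`.
#' @param density Optional nonnegative weights (renormalized); default flat.
#' @return List of class `belief_grid` with `grid` and `density`.
#' @export
belief_grid <- function(n = 481, lo = 0.01, hi = 0.99, density = NULL) {
  if (lo <= 0 || hi >= 1 || lo >= hi) stop("grid must lie strictly inside (0, 1)", call. = FALSE)
  grid <- seq(lo, hi, length.out = n)
  if (is.null(density)) {
    density <- rep(1 / n, n)
  } else {
    if (length(density) != n || any(density < 0) || !all(is.finite(density))) {
      stop("density must be nonnegative, finite, one weight per grid point", call. = FALSE)
    }
    density <- density / sum(density)
  }
  structure(list(grid = grid, density = density), class = "belief_grid")
}

#' @export
print.belief_grid <- function(x, ...) {
  cat(sprintf("<belief_grid: %d points on [%.3g, %.3g], mean %.4f>\n",
              length(x$grid), min(x$grid), max(x$grid), belief_mean(x)))
  invisible(x)
}

#' @rdname belief_grid
#' @param belief A `belief_grid`.
#' @export
belief_mean <- function(belief) {
  sum(belief$grid * belief$density)
}

#' Beta evidence-density shapes for an observed outcome
#'
#' Returns the shape pair of the Beta distribution whose mean is the observed
#' rescaled outcome `r` and whose variance is the fixed `updatevar`:
#' with `s = r * (1 - r) / updatevar - 1`, the shapes are `alpha = r * s` and
#' `beta = (1 - r) * s`. Requires `updatevar < r * (1 - r)` for feasibility.
#'
#' @param r Rescaled outcome in \[0.01, 0.99\].
#' @param updatevar Evidence variance hyperparameter (default 0.009).
#' @return Named numeric `c(alpha =, beta =)`, both positive.
#' @export
event_density_params <- function(r, updatevar = 0.009) {
  check_outcome(r)
  if (updatevar <= 0 || any(updatevar >= r * (1 - r))) {
    stop(sprintf("updatevar = %g infeasible for outcome r = %g (needs 0 < updatevar < r(1-r))",
                 updatevar, r[which(updatevar >= r * (1 - r))[1]]), call. = FALSE)
  }
  s <- r * (1 - r) / updatevar - 1
  c(alpha = r * s, beta = (1 - r) * s)
}

#' Bayesian belief update for one observed outcome
#'
#' Multiplies the prior weights pointwise by the Beta evidence density centred
#' on the outcome and renormalizes. Computation is done in log space (shifted
#' by the maximum log density) so the product never underflows.
#'
#' @param belief A [belief_grid()].
#' @param outcome Rescaled outcome in \[0.01, 0.99\].
#' @param updatevar Evidence variance hyperparameter (default 0.009).
#' @return Updated `belief_grid` (weights sum to 1).
#' @export
bayes_update <- function(belief, outcome, updatevar = 0.009) {
  sh <- event_density_params(outcome, updatevar)
  lw <- log(belief$density) + stats::dbeta(belief$grid, sh[["alpha"]], sh[["beta"]], log = TRUE)
  lw <- lw - max(lw)
  w <- exp(lw)
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0) {
    stop("belief update underflowed to an all-zero density", call. = FALSE)
  }
  belief$density <- w / tot
  belief
}

#' Conditional Value at Risk readout of a belief
#'
#' Reads out the mean of the lower tail (`eta <= 0`) or upper tail
#' (`eta > 0`) of the belief distribution. The Value at Risk is the smallest
#' grid point whose cumulative mass reaches `1 + eta` (for `eta <= 0`) or
#' `eta` (for `eta > 0`); the tail mean includes the VaR point. `eta = 0`
#' reads out the mean of the whole distribution; `eta = -0.95` the mean of the
#' lowest 5 percent; `eta = 0.95` the mean of the top 5 percent.
#'
#' @param belief A [belief_grid()].
#' @param eta CVaR level in (-1, 1).
#' @return Decision value (scalar within the grid range).
#' @export
cvar_readout <- function(belief, eta) {
  if (!is.finite(eta) || eta <= -1 || eta >= 1) {
    stop("eta must lie strictly inside (-1, 1)", call. = FALSE)
  }
  w <- belief$density / sum(belief$density)
  cf <- cumsum(w)
  if (eta <= 0) {
    thr <- 1 + eta
    idx <- which(cf >= thr - 1e-12)[1]
    sel <- seq_len(idx)
  } else {
    thr <- eta
    idx <- which(cf >= thr - 1e-12)[1]
    sel <- idx:length(w)
  }
  sum(belief$grid[sel] * w[sel]) / sum(w[sel])
}

#' Value at Risk of a belief
#'
#' The grid point at which [cvar_readout()] cuts the tail, together with the
#' cumulative mass at that point.
#'
#' @inheritParams cvar_readout
#' @return Named numeric `c(var =, cdf =)`.
#' @export
var_readout <- function(belief, eta) {
  if (!is.finite(eta) || eta <= -1 || eta >= 1) {
    stop("eta must lie strictly inside (-1, 1)", call. = FALSE)
  }
  w <- belief$density / sum(belief$density)
  cf <- cumsum(w)
  thr <- if (eta <= 0) 1 + eta else eta
  idx <- which(cf >= thr - 1e-12)[1]
  c(var = belief$grid[idx], cdf = cf[idx])
}

# --- internal fast paths -----------------------------------------------------

# Beta evidence log-densities for each card value, evaluated on `grid`:
# a length(grid) x 13 matrix; column v is the evidence density for card v.
card_evidence_matrix <- function(grid, updatevar = 0.009, log = FALSE) {
  out <- vapply(CARD_VALUES, function(v) {
    sh <- event_density_params(rescale_card(v), updatevar)
    stats::dbeta(grid, sh[["alpha"]], sh[["beta"]], log = log)
  }, numeric(length(grid)))
  out
}

# Batch CVaR readout over precomputed cumulative-mass (`cf`) and cumulative
# grid-weighted-mass (`cz`) matrices (grid points x columns). Returns one
# decision value per column. Columns must be normalized (last row of cf ~ 1).
cvar_readout_batch <- function(cf, cz, eta) {
  n <- nrow(cf)
  thr <- if (eta <= 0) 1 + eta else eta
  idx <- colSums(cf < thr - 1e-12) + 1L
  j <- seq_len(ncol(cf))
  if (eta <= 0) {
    cz[cbind(idx, j)] / cf[cbind(idx, j)]
  } else {
    top_z <- cz[n, ]
    top_f <- cf[n, ]
    below_z <- ifelse(idx > 1L, cz[cbind(pmax(idx - 1L, 1L), j)], 0)
    below_f <- ifelse(idx > 1L, cf[cbind(pmax(idx - 1L, 1L), j)], 0)
    (top_z - below_z) / (top_f - below_f)
  }
}
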