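test_that("evidence shapes invert the Beta mean/variance map exactly", {
  sh <- event_density_params(0.5, 0.009)
  # closed form at the midpoint: -0.5 * (0.25 - 0.5 + 0.009) / 0.009
  expect_equal(unname(sh["alpha"]), 13.38888888888889, tolerance = 1e-12)
  expect_equal(sh[["alpha"]], sh[["beta"]])
  set.seed(11)
  for (i in 1:1000) {
    r <- runif(1, 0.01, 0.99)
    v <- runif(1, 1e-4, r * (1 - r) * 0.99)
    sh <- event_density_params(r, v)
    a <- sh[["alpha"]]; b <- sh[["beta"]]
    expect_true(a > 0 && b > 0)
    expect_equal(a / (a + b), r, tolerance = 1e-10)
    expect_equal(a * b / ((a + b)^2 * (a + b + 1)), v, tolerance = 1e-10)
  }
  # shapes swap under reflection of the outcome about 0.5
  s1 <- event_density_params(0.7, 0.009)
  s2 <- event_density_params(0.3, 0.009)
  expect_equal(s1[["alpha"]], s2[["beta"]], tolerance = 1e-12)
  expect_error(event_density_params(0.01, 0.0099), "infeasible")
})

test_that("belief updating concentrates on the evidence and stays normalized", {
  b <- belief_grid()
  expect_equal(belief_mean(b), 0.5)
  b1 <- bayes_update(b, 0.5)
  expect_equal(b1$grid[which.max(b1$density)], 0.5)  # symmetric kernel at 0.5
  b30 <- b
  for (i in 1:30) b30 <- bayes_update(b30, 0.5)
  expect_lt(abs(belief_mean(b30) - 0.5), 0.01)
  # normalization after every update across a random outcome stream
  set.seed(21)
  bb <- belief_grid()
  for (r in rescale_card(sample(1:13, 30, replace = TRUE))) {
    bb <- bayes_update(bb, r)
    expect_lt(abs(sum(bb$density) - 1), 1e-9)
  }
  expect_error(belief_grid(density = rep(-1, 481)), "nonnegative")
  expect_error(belief_grid(lo = 0, hi = 0.99), "strictly inside")
})

test_that("tail readouts match conditional means of a uniform belief", {
  # midpoint grid emulating a uniform belief on (0, 1)
  n <- 2000
  g <- belief_grid(n = n, lo = 1 / (2 * n), hi = 1 - 1 / (2 * n))
  expect_equal(cvar_readout(g, 0), 0.5)
  expect_equal(cvar_readout(g, -0.95), 0.025, tolerance = 1e-3)
  expect_equal(cvar_readout(g, 0.95), 0.975, tolerance = 1e-3)
  vr <- var_readout(g, -0.95)
  expect_equal(vr[["cdf"]], 0.05, tolerance = 1 / n)
  expect_error(cvar_readout(g, -1), "inside")
  expect_error(cvar_readout(g, 1.2), "inside")
})

test_that("CVaR readout equals the brute-force oracle and is monotone in eta", {
  set.seed(5)
  etas <- seq(-0.99, 0.99, by = 0.03)
  for (i in 1:8) {
    w <- rgamma(481, shape = runif(1, 0.2, 3))
    b <- belief_grid(density = w)
    vals <- vapply(etas, function(e) cvar_readout(b, e), numeric(1))
    oracle <- vapply(etas, function(e) oracle_cvar(b$grid, b$density, e), numeric(1))
    expect_equal(vals, oracle)
    expect_true(all(diff(vals) >= -1e-12))
    m <- belief_mean(b)
    expect_true(all(vals[etas < 0] <= m + 1e-12))
    expect_true(all(vals[etas > 0] >= m - 1e-12))
    expect_true(all(vals >= min(b$grid) & vals <= max(b$grid)))
    # eta = 0 reads out the full mean
    expect_equal(cvar_readout(b, 0), m)
  }
})

test_that("the batch readout used by likelihoods equals the scalar readout", {
  set.seed(6)
  w <- matrix(rgamma(481 * 7, 0.7), 481)
  w <- w / rep(colSums(w), each = 481)
  grid <- seq(0.01, 0.99, length.out = 481)
  cf <- apply(w, 2, cumsum)
  cz <- apply(grid * w, 2, cumsum)
  for (eta in c(-0.95, -0.5, -0.1, 0, 0.2, 0.6, 0.95)) {
    batch <- cvarlearn:::cvar_readout_batch(cf, cz, eta)
    single <- vapply(seq_len(ncol(w)), function(j) {
      cvar_readout(belief_grid(density = w[, j]), eta)
    }, numeric(1))
    expect_equal(batch, single, tolerance = 1e-12)
  }
})
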