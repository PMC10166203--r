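make_truth <- function(n = 121, dt = 10) {
  # smooth heating curve at the can center from the analytic benchmark
  tt <- seq(0, by = dt, length.out = n)
  Tt <- analytic_cylinder_temperature(0.001, 0.06, tt + 200, 1.4e-7,
                                      394.15, 341.15, 0.04945, 0.121,
                                      n_terms = 40)
  probe_series(tt, Tt, position = c(0.001, 0.06))
}

test_that("a noiseless, lag-free probe reproduces its input exactly", {
  tr <- make_truth()
  out <- synthesize_probe(tr, noise_model(sigma = 0, tau = 0))
  expect_identical(out$temperatures, tr$temperatures)
  expect_identical(out$provenance, "synthetic")
})

test_that("a lagged probe responds to a step like a first-order system", {
  tt <- seq(0, 100, by = 0.5)
  Tt <- c(300, rep(350, length(tt) - 1))   # step just after t = 0
  tr <- probe_series(tt, Tt)
  out <- synthesize_probe(tr, noise_model(sigma = 0, tau = 20))
  # 63.2 % of the step recovered one time constant after the jump
  k <- which.min(abs(tt - 20.5))
  expect_equal((out$temperatures[k] - 300) / 50, 1 - exp(-1), tolerance = 0.02)
})

test_that("noise averages out across seeds at the Monte-Carlo rate", {
  tr <- make_truth(n = 61)
  lagged <- synthesize_probe(tr, noise_model(sigma = 0, tau = 5))
  acc <- matrix(0, 200, length(tr$times))
  for (s in 1:200) {
    acc[s, ] <- synthesize_probe(tr, noise_model(sigma = 0.25, tau = 5,
                                                 seed = s))$temperatures
  }
  dev <- colMeans(acc) - lagged$temperatures
  expect_lt(max(abs(dev)), 3 * 0.25 / sqrt(200) * 3)  # 3 SE with headroom
  expect_lt(mean(abs(dev)), 3 * 0.25 / sqrt(200))
})

test_that("general-method F integrates constant and refined series correctly", {
  s <- probe_series(seq(0, 600, by = 30), rep(394.25, 21))
  expect_equal(general_method_F(s), 10, tolerance = 1e-12)
  # quadrature convergence: doubling the sampling changes F by < 0.5 %
  tr1 <- make_truth(n = 61, dt = 20)
  tr2 <- make_truth(n = 121, dt = 10)
  F1 <- general_method_F(tr1); F2 <- general_method_F(tr2)
  expect_lt(abs(F1 - F2) / F2, 0.005)
  expect_error(general_method_F(probe_series(0, 394.25)), "2 samples")
})

test_that("probe comparison reports rmse, deviations and both F values", {
  tr <- make_truth()
  same <- compare_probes(tr, tr)
  expect_equal(same$rmse, 0)
  expect_equal(same$max_abs_dev, 0)
  expect_equal(same$F_pred, same$F_meas)
  off <- probe_series(tr$times, tr$temperatures + 1, position = tr$position)
  cmp <- compare_probes(tr, off)
  expect_equal(cmp$rmse, 1.0, tolerance = 1e-12)
  expect_equal(cmp$max_abs_dev, 1.0, tolerance = 1e-12)
  # swap symmetry on a common grid
  sw <- compare_probes(off, tr)
  expect_equal(sw$rmse, cmp$rmse)
  expect_equal(sw$F_pred, cmp$F_meas)
  expect_equal(sw$F_meas, cmp$F_pred)
})

test_that("synthetic probes deviate from truth consistently with the noise model", {
  tr <- make_truth(n = 121, dt = 10)
  rmses <- vapply(1:50, function(s) {
    syn <- synthesize_probe(tr, noise_model(sigma = 0.25, tau = 5, seed = s))
    compare_probes(tr, syn)$rmse
  }, numeric(1))
  expect_true(all(rmses > 0.1 & rmses < 0.8))
  expect_gt(mean(rmses), 0.2)
})

test_that("simulate -> synthesize -> compare round-trips within the noise budget", {
  m <- quiet_mesh(nr = 10, nz = 20)
  cfg <- solver_config(m, dt = 5, mode = "conduction")
  res <- simulate_can(cfg, parse_schedule("5-15-5/121"),
                      probes = list(c(0, 0.0188)), keep_snapshots = FALSE)
  pred <- probe_from_simulation(res)
  meas <- synthesize_probe(pred, noise_model(sigma = 0.5, tau = 5, seed = 11))
  cmp <- compare_probes(pred, meas)
  expect_lt(cmp$rmse, 1.5)
  expect_lt(abs(cmp$F_pred - cmp$F_meas) / cmp$F_pred, 0.05)
  # consistency: the classical method on the probe equals the co-accumulated
  # cell F at the same position
  expect_equal(general_method_F(pred),
               max(res$probes$F_cell_min), tolerance = 0.01)
})

test_that("degenerate probe inputs are rejected", {
  expect_error(probe_series(c(0, 1, 1), c(1, 2, 3)), "strictly")
  expect_error(probe_series(c(1, 2), c(300, 301)), "start at 0")
  expect_error(probe_series(c(0, 1), c(300, NA)), "finite")
  a <- probe_series(c(0, 10), c(300, 310))
  b <- probe_series(c(0, 10), c(300, 310))
  b$times <- b$times + 100   # disjoint ranges
  expect_error(compare_probes(a, b), "overlap")
})
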