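test_that("annealer solves a quadratic bowl within tolerance", {
  res <- simulated_annealing(function(x) (x - 3)^2, x0 = 8,
                             lower = 0, upper = 10, seed = 4,
                             max_iter = 5000, step = 0.3)
  expect_lt(abs(res$par - 3), 0.05)
  expect_equal(res$value, (res$par - 3)^2)
})

test_that("annealer respects bounds, zero iterations and bad input", {
  res <- simulated_annealing(function(x) sum(x^2), x0 = c(1, 2),
                             lower = c(0.5, 1), upper = c(4, 4),
                             seed = 1, max_iter = 500)
  expect_true(all(res$par >= c(0.5, 1) & res$par <= c(4, 4)))
  res0 <- simulated_annealing(function(x) sum(x^2), x0 = c(1, 2),
                              lower = 0, upper = 4, seed = 1,
                              max_iter = 0)
  expect_equal(res0$par, c(1, 2))
  expect_error(simulated_annealing(function(x) x^2, 1, 0, 2,
                                   max_iter = -1), "nonnegative")
  expect_error(simulated_annealing(function(x) x^2, 1, 0, Inf),
               "finite")
  expect_error(simulated_annealing(function(x) x^2, 9, 0, 2), "bounds")
})

test_that("annealing is reproducible and its best value tracks the trace", {
  f <- function(x) sum((x - c(1, 2, 0.5))^2) + 0.1 * sum(sin(5 * x)^2)
  a <- simulated_annealing(f, c(3, 3, 3), 0, 5, seed = 7, max_iter = 2000)
  b <- simulated_annealing(f, c(3, 3, 3), 0, 5, seed = 7, max_iter = 2000)
  expect_identical(a$par, b$par)
  expect_equal(a$value, min(a$trace$cost))
  # best-ever cost is non-increasing along the trace
  expect_true(all(diff(cummin(a$trace$cost)) <= 0))
  # temperature schedule is non-increasing
  expect_true(all(diff(a$trace$temperature) <= 0))
})

test_that("cost is zero when simulation matches observation inside windows", {
  p <- default_params()
  tr <- run_protocol(p, "muller_LL", burn_in_days = 6, dt = 0.1)
  s <- trajectory_series(tr, "MCL")
  grid <- seq(0, 48, by = 2)
  obs <- stats::approx(s$time_h, s$value, xout = grid)$y
  tg <- fit_target("CL", "muller_LL", grid, obs, w_period = 0,
                   w_phase = 0)
  d <- cost_delta(p, tg, dt = 0.1, burn_in_days = 6)
  expect_lt(d, 1e-8)
  # normalization invariance: scaling the raw observations changes nothing
  tg2 <- fit_target("CL", "muller_LL", grid, 2 * obs, w_period = 0,
                    w_phase = 0)
  expect_equal(cost_delta(p, tg2, dt = 0.1, burn_in_days = 6), d)
})

test_that("period and phase terms are hard-zeroed inside their windows", {
  p <- default_params()
  tr <- run_protocol(p, "muller_LL", burn_in_days = 6, dt = 0.1)
  s <- trajectory_series(tr, "MCL")
  grid <- seq(0, 48, by = 2)
  obs <- stats::approx(s$time_h, s$value, xout = grid)$y
  # wide windows that the calibrated model satisfies: no extra cost
  wide <- fit_target("CL", "muller_LL", grid, obs,
                     period_window = c(18, 34), phase_window = c(0, 24))
  expect_lt(cost_delta(p, wide, dt = 0.1, burn_in_days = 6), 1e-8)
  # an unattainable period window must add a positive penalty
  narrow <- fit_target("CL", "muller_LL", grid, obs,
                       period_window = c(30, 31), phase_window = c(0, 24))
  expect_gt(cost_delta(p, narrow, dt = 0.1, burn_in_days = 6), 0.01)
})

test_that("noisier observations never cheapen the generating parameters", {
  p <- default_params()
  tr <- run_protocol(p, "muller_LL", burn_in_days = 6, dt = 0.1)
  s <- trajectory_series(tr, "MCL")
  grid <- seq(0, 48, by = 2)
  obs <- stats::approx(s$time_h, s$value, xout = grid)$y
  base <- cost_delta(p, fit_target("CL", "muller_LL", grid, obs,
                                   w_period = 0, w_phase = 0),
                     dt = 0.1, burn_in_days = 6)
  deltas <- vapply(1:10, function(sd) {
    set.seed(sd)
    noisy <- obs * stats::rlnorm(length(obs), 0, 0.15)
    cost_delta(p, fit_target("CL", "muller_LL", grid, noisy,
                             w_period = 0, w_phase = 0),
               dt = 0.1, burn_in_days = 6)
  }, numeric(1))
  expect_true(all(deltas >= base))
  expect_gt(mean(deltas), base)
})

test_that("constraint checks isolate the offending gene and window", {
  cons <- clock_constraints()
  mids <- vapply(cons$phase_windows, mean, numeric(1))
  # all genes in-window
  good <- fake_trajectory(as.list(mids), tau = 25)
  rep_good <- check_constraints(good)
  expect_true(attr(rep_good, "pass"))
  # CL displaced to 5 h: only the CL phase check fails
  bad_mids <- as.list(mids); bad_mids$CL <- 5
  rep_bad <- check_constraints(fake_trajectory(bad_mids, tau = 25))
  expect_false(attr(rep_bad, "pass"))
  expect_false(rep_bad$phase_ok[rep_bad$gene == "CL"])
  expect_true(all(rep_bad$phase_ok[rep_bad$gene != "CL"]))
  expect_true(all(rep_bad$period_ok))
})

test_that("an arrhythmic model is flagged as violation, not error", {
  p <- default_params()
  # no degradation anywhere: states ramp monotonically, no rhythm
  degs <- grep("^(m|d)[0-9]+[a-z]?$|^(d|k)_|^k[0-9]+$", param_names(),
               value = TRUE)
  degs <- setdiff(degs, c("k_cn", "k_nd", "k_dn", "d3z"))
  p0 <- set_params(p, stats::setNames(rep(1e-3, length(degs)), degs))
  rep0 <- check_constraints(p0, burn_in_days = 2, dt = 0.1,
                            treatment_days = 3)
  expect_false(attr(rep0, "pass"))
  expect_true(any(!rep0$rhythmic | !rep0$period_ok | !rep0$phase_ok))
})
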