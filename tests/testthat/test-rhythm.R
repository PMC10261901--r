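test_that("harmonic fit nails a pure 24 h cosine", {
  tt <- seq(0, 48, by = 0.5)
  est <- estimate_mfourfit(tt, cos_series(tt, 24, 0))
  expect_equal(est$period, 24, tolerance = 0.01)
  expect_lt(min(est$phase, 24 - est$phase), 0.1)
  expect_false(est$boundary)
})

test_that("harmonic fit recovers a two-harmonic 25.5 h signal with phase 3", {
  tt <- seq(0, 72, by = 0.5)
  y <- cos_series(tt, 25.5, 3, harm2 = 0.3)
  est <- estimate_mfourfit(tt, y)
  expect_equal(est$period, 25.5, tolerance = 0.1)
  expect_equal(est$phase, 3, tolerance = 0.1)
  # brute-force grid over the fundamental as the oracle
  rss_grid <- vapply(seq(18, 34, by = 0.05), function(tau) {
    X <- cbind(1, cos(2 * pi * tt / tau), sin(2 * pi * tt / tau),
               cos(4 * pi * tt / tau), sin(4 * pi * tt / tau),
               cos(6 * pi * tt / tau), sin(6 * pi * tt / tau))
    sum(stats::lm.fit(X, y)$residuals^2)
  }, numeric(1))
  tau_oracle <- seq(18, 34, by = 0.05)[which.min(rss_grid)]
  expect_equal(est$period, tau_oracle, tolerance = 0.05)
})

test_that("white noise is flagged as boundary or low-goodness", {
  flags <- vapply(1:100, function(s) {
    set.seed(s)
    tt <- seq(0, 72, by = 1)
    y <- stats::rnorm(length(tt))
    est <- estimate_mfourfit(tt, y)
    r2 <- 1 - est$goodness / sum((y - mean(y))^2)
    est$boundary || r2 < 0.3
  }, logical(1))
  expect_gt(mean(flags), 0.9)
})

test_that("MESA finds the period of a noisy cosine and of a mixture", {
  set.seed(5)
  tt <- seq(0, 48, by = 1)
  y <- cos_series(tt, 24, 0) + stats::rnorm(length(tt), 0, 0.05)
  est <- estimate_mesa(tt, y)
  expect_gt(est$period, 23.5)
  expect_lt(est$period, 24.5)
  # 24 h and 12 h mixture at 2:1 amplitude: the fundamental dominates
  y2 <- 2 * cos(2 * pi * tt / 24) + cos(2 * pi * tt / 12)
  est2 <- estimate_mesa(tt, y2)
  expect_equal(est2$period, 24, tolerance = 0.5)
  expect_error(estimate_mesa(tt, rep(1, length(tt))), "constant")
})

test_that("Enright periodogram is exact on folds and matches its oracle", {
  tt <- seq(0, 288, by = 1)
  sq <- ifelse((tt %% 24) < 12, 2, 0.5)
  est <- estimate_enright(tt, sq)
  expect_equal(est$period, 24)
  # the statistic across the grid equals the brute-force fold definition
  taus <- seq(18, 34, by = 0.1)
  ours <- vapply(taus, function(tau)
    estimate_enright(tt, sq, candidate_periods = tau)$goodness,
    numeric(1))
  oracle <- enright_oracle(tt, sq, taus)
  expect_equal(ours, oracle, tolerance = 1e-12)
  # off-grid period recovered to within one grid step
  y255 <- cos_series(tt, 25.5, 3)
  est2 <- estimate_enright(tt, y255)
  expect_lte(abs(est2$period - 25.5), 0.1 + 1e-9)
})

test_that("shuffling destroys the Enright statistic's peak", {
  tt <- seq(0, 96, by = 1)
  y <- cos_series(tt, 24, 0)
  set.seed(9)
  ysh <- sample(y)
  est <- estimate_enright(tt, y)
  estsh <- estimate_enright(tt, ysh)
  expect_gt(est$goodness, 5 * estsh$goodness)
})

test_that("period grids below the Nyquist-resolvable range are rejected", {
  tt <- seq(0, 96, by = 4)
  expect_error(estimate_enright(tt, cos_series(tt), candidate_periods =
                                  seq(5, 34, by = 0.5)), "Nyquist")
})

test_that("peak times interpolate sub-grid maxima", {
  tt <- seq(0, 47.9, by = 2)
  pk <- peak_times(tt, cos_series(tt, 24, 5))
  expect_equal(length(pk), 2)
  expect_equal(pk[1], 5, tolerance = 0.1)
  expect_equal(diff(pk), 24, tolerance = 0.2)
  expect_length(peak_times(tt, seq_along(tt)), 0)   # monotone
})

test_that("aggregation combines periods linearly and phases circularly", {
  ests <- lapply(c(24.0, 24.2, 24.4), function(tau)
    rhythm_estimate(tau, 2, 1, "mfourfit", 0))
  agg <- aggregate_estimates(ests)
  expect_equal(agg$period_mean, 24.2)
  expect_equal(agg$period_sd, 0.2)
  wrap <- list(rhythm_estimate(24, 23.8, 1, "mfourfit", 0),
               rhythm_estimate(24, 0.2, 1, "mesa", 0))
  aggw <- aggregate_estimates(wrap)
  expect_lt(min(aggw$phase_mean, 24 - aggw$phase_mean), 0.01)
  expect_error(aggregate_estimates(list(wrap[[1]])), "at least 2")
})

test_that("the three methods agree within 0.5 h on clean oscillations", {
  for (tau in c(22, 24.2, 26.5)) {
    set.seed(round(10 * tau))
    tt <- seq(0, 4 * tau, by = 0.5)
    y <- cos_series(tt, tau, 4, amp = 1, mean = 2, harm2 = 0.15) +
      stats::rnorm(length(tt), 0, 0.1)   # SNR 10
    res <- estimate_rhythm(tt, y)
    periods <- vapply(res$by_method, `[[`, numeric(1), "period")
    expect_lt(max(periods) - min(periods), 0.5)
    expect_equal(unname(res$summary$period_mean), tau, tolerance = 0.4)
  }
})

test_that("series preconditions are enforced", {
  tt <- seq(0, 20, by = 1)
  expect_error(estimate_mfourfit(tt, cos_series(tt)), "cycles")
  expect_error(estimate_mesa(c(0, 1, 3, 7), stats::rnorm(4)), "length|cycles")
})
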