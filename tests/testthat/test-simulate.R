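test_that("RK4 reproduces closed-form solutions at its order", {
  # exponential decay
  tr <- integrate_rk4(function(t, y) -y, 1, t_end = 1, dt = 0.01)
  expect_equal(tr$states[nrow(tr$states), 1], exp(-1), tolerance = 1e-8)
  # quadrature of cos -> sin
  tr2 <- integrate_rk4(function(t, y) cos(t), 0, t_end = 6, dt = 0.05)
  expect_equal(tr2$states[, 1], sin(tr2$time), tolerance = 1e-6)
  # fourth-order convergence: halving dt cuts the error ~16x
  err <- vapply(c(0.1, 0.05), function(h) {
    y <- integrate_rk4(function(t, y) -2 * y, 1, t_end = 2, dt = h)
    abs(y$states[nrow(y$states), 1] - exp(-4))
  }, numeric(1))
  expect_gt(err[1] / err[2], 10)
})

test_that("RK4 validates its inputs and reports blow-ups", {
  expect_error(integrate_rk4(function(t, y) -y, 1, 1, dt = 0), "positive")
  expect_error(integrate_rk4(function(t, y) -y, 1, 1, dt = 0.3), "divide")
  expect_error(integrate_rk4(function(t, y) y^2, 2, 10, dt = 0.1),
               "integration failure")
})

test_that("full-model integration is deterministic and step-converged", {
  p <- default_params()
  proto <- light_protocol(rbind(ld_segment(48, 100), ll_segment(48, 100)))
  a <- integrate_model(p, proto, dt = 0.025, record_every = 0.05)
  b <- integrate_model(p, proto, dt = 0.025, record_every = 0.05)
  expect_identical(a$states, b$states)   # bit-identical
  fine <- integrate_model(p, proto, dt = 0.0125, record_every = 0.05)
  # compare on the common grid at t_end
  ya <- a$states[nrow(a$states), ]
  yb <- fine$states[nrow(fine$states), ]
  expect_lt(max(abs(ya - yb) / pmax(abs(yb), 1e-6)), 1e-4)
})

test_that("trajectories stay nonnegative with P in [0,1]", {
  p <- default_params()
  tr <- run_protocol(p, "muller_LL", burn_in_days = 3, dt = 0.05)
  expect_true(all(tr$states >= 0))
  expect_true(all(tr$states[, "P"] <= 1))
  expect_false(anyNA(tr$states))
  expect_equal(diff(range(diff(tr$time))), 0, tolerance = 1e-9)
})

test_that("dt must divide one hour so switches stay on the grid", {
  p <- default_params()
  proto <- light_protocol(ld_segment(24, 100))
  expect_error(integrate_model(p, proto, dt = 0.3), "divide")
})

test_that("entrained cycles repeat to within 1% after burn-in", {
  p <- default_params()
  tr <- run_protocol(p, "MI_to_MI", burn_in_days = 16, dt = 0.05,
                     treatment_days = 2)
  for (v in c("MCL", "MGI", "P")) {
    c1 <- tr$states[tr$time >= 0 & tr$time < 24, v]
    c2 <- tr$states[tr$time >= 24 & tr$time < 48, v]
    expect_lt(max(abs(c1 - c2)) / max(c2), 0.01)
  }
})

test_that("custom single-segment protocol with zero burn-in starts at y0", {
  p <- default_params()
  proto <- light_protocol(ll_segment(24, 100))
  tr <- run_protocol(p, proto, burn_in_days = 0, dt = 0.05)
  expect_equal(unname(tr$states[1, ]), unname(default_y0()))
  expect_equal(tr$time[1], 0)
})

test_that("treatment windows are re-zeroed at lights-on and carry intensity", {
  p <- default_params()
  tr <- run_protocol(p, "MI_to_LI", burn_in_days = 2, dt = 0.1,
                     treatment_days = 1)
  expect_equal(tr$time[1], 0)
  expect_equal(tr$treatment$intensity, 62.5)
  tr2 <- run_protocol(p, "MI_to_NI", burn_in_days = 2, dt = 0.1,
                      treatment_days = 1)
  expect_equal(tr2$treatment$intensity, 187.5)
})

test_that("normalization modes behave and error as documented", {
  expect_equal(normalize_series(c(1, 2, 4), "max"), c(0.25, 0.5, 1))
  expect_equal(normalize_series(c(1, 2, 4), "minmax"), c(0, 1 / 3, 1))
  x <- normalize_series(c(1, 2, 4), "max")
  expect_equal(normalize_series(x, "max"), x)       # idempotent
  y <- normalize_series(c(1, 2, 4), "minmax")
  expect_equal(normalize_series(y, "minmax"), y)
  expect_error(normalize_series(c(2, 2, 2), "minmax"), "constant")
  expect_error(normalize_series(c(0, 0), "max"), "positive")
})

test_that("trajectory CSV writer emits the long schema with comments", {
  p <- default_params()
  proto <- light_protocol(ll_segment(12, 100))
  tr <- integrate_model(p, proto, dt = 0.125, record_every = 0.25)
  tmp <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, tmp, vars = c("MCL", "MGI"), condition = "LL")
  lines <- readLines(tmp)
  expect_match(lines[1], "^# ")
  tab <- utils::read.csv(tmp, comment.char = "#")
  expect_named(tab, c("time_h", "variable", "value", "condition"))
  expect_setequal(unique(tab$variable), c("MCL", "MGI"))
})
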