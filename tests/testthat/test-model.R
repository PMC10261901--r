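test_that("from an empty state only transcription and constitutive inputs fire", {
  p <- default_params()
  dy <- clock_rhs(rep(0, 29), p, L = 1, D = 0, f = 1)
  mrnas <- c(clock_states("mrna"), "MLhcb1", "MpsbA", "MRbcS1", "MatpA")
  # CL-repressed / basal transcription positive for every unoccupied promoter
  expect_true(all(dy[setdiff(mrnas, "MLhcb1")] > 0))
  # Lhcb1 needs its activator CL, absent here
  expect_equal(unname(dy[["MLhcb1"]]), 0)
  # translated proteins have nothing to translate
  prots <- c("CL", "P97", "P51", "EL", "GI", "RVE8",
             "Lhcb1", "psbA", "RbcS1", "atpA")
  expect_true(all(dy[prots] == 0))
  # complexes need their constituents
  expect_true(all(dy[c("EC", "RL", "ZG")] == 0))
  # constitutive pools (ZTL, COP1, HY5) are produced at basal rate
  expect_true(all(dy[c("ZTL", "COP1c", "HY5")] > 0))
})

test_that("with all synthesis switched off every derivative is non-positive", {
  p <- default_params()
  synth <- grep("^(v|q|p)[0-9]+$|^(v|c|s|g|r|k)_", param_names(),
                value = TRUE)
  p0 <- set_params(p, stats::setNames(rep(0, length(synth)), synth))
  set.seed(42)
  for (i in 1:20) {
    y <- stats::runif(29, 0, 3); y[21] <- stats::runif(1)
    names(y) <- clock_states()
    for (light in list(c(1, 0), c(0, 1))) {
      dy <- clock_rhs(y, p0, L = light[1], D = light[2], f = 1)
      expect_true(all(dy <= 1e-12))
    }
  }
})

test_that("finite-difference Jacobian matches an independent oracle", {
  skip_if_not_installed("pracma")
  p <- default_params()
  set.seed(7)
  y <- stats::runif(29, 0.2, 2); y[21] <- 0.4
  F <- function(x) as.numeric(clock_rhs(abs(x), p, L = 1, D = 0, f = 1))
  J_own <- photoclock:::.fd_jacobian(F, y)
  J_ora <- pracma::jacobian(F, y)
  expect_lt(max(abs(J_own - J_ora)) / max(abs(J_ora)), 1e-6)
})

test_that("light-sensitive protein kinetics respect the [0,1] boundaries", {
  p <- default_params()
  expect_equal(light_protein_rhs(0, L = 0, D = 1, p),
               unname(p[["s_p"]]))
  expect_equal(light_protein_rhs(1, L = 0, D = 1, p), 0)
  expect_lt(light_protein_rhs(1, L = 1, D = 0, p), 0)
  expect_equal(light_protein_rhs(0, L = 1, D = 0, p), 0)
  expect_gt(light_protein_rhs(0.5, L = 0, D = 1, p), 0)
  expect_error(light_protein_rhs(1.2, L = 1, D = 0, p), "0, 1")
  # boundary consistency inside the full RHS: P cannot leave [0,1]
  y <- default_y0(); y["P"] <- 1
  dy <- clock_rhs(y, p, L = 0, D = 1, f = 1)
  expect_lte(unname(dy[["P"]]), 0)
})

test_that("the sawtooth solution of P under square-wave forcing peaks at dawn", {
  # piecewise-exponential closed form: over a night of length Tn,
  # P -> 1 + (P0 - 1) exp(-s_p Tn); over a day, P -> P0 exp(-d_p f Td);
  # at I = 100 the intensity scale is exactly 1
  p <- default_params()
  s <- unname(p[["s_p"]]); d <- unname(p[["d_p"]])
  tr <- run_protocol(p, "MI_to_MI", burn_in_days = 10, dt = 0.05,
                     treatment_days = 2)
  a <- exp(-d * 12); b <- exp(-s * 12)
  P_dawn <- (1 - b) / (1 - a * b)
  dawn <- which(abs(tr$time - 24) < 1e-9)
  expect_equal(unname(tr$states[dawn, "P"]), P_dawn, tolerance = 1e-5)
  # peak at dawn: the dawn value is the maximum over a full cycle
  cyc <- tr$time >= 0 & tr$time <= 24
  expect_equal(max(tr$states[cyc, "P"]), P_dawn, tolerance = 1e-5)
})

test_that("Lhcb1 kinetics: activator, inhibitor and half-saturation identities", {
  p <- default_params()
  # no activator: pure decay in both variants
  expect_equal(lhcb1_rhs(2, CL = 0, GI = 1, p),
               -unname(p[["k7"]]) * 2)
  expect_equal(lhcb1_rhs(2, CL = 0, GI = 1, p, variant = "control"),
               -unname(p[["k7"]]) * 2)
  # inhibitor absent: extended equals control
  expect_equal(lhcb1_rhs(1, CL = 0.7, GI = 0, p),
               lhcb1_rhs(1, CL = 0.7, GI = 0, p, variant = "control"))
  # half-saturation of both Hill factors: synthesis v7/4
  k17 <- unname(p[["K17"]]); k18 <- unname(p[["K18"]])
  expect_equal(lhcb1_rhs(0, CL = k17, GI = k18, p),
               unname(p[["v7"]]) / 4)
  # extended never exceeds control for matched parameters
  set.seed(1)
  for (i in 1:20) {
    cl <- stats::runif(1, 0, 3); gi <- stats::runif(1, 0, 3)
    expect_lte(lhcb1_rhs(0.5, cl, gi, p),
               lhcb1_rhs(0.5, cl, gi, p, variant = "control") + 1e-12)
  }
})

test_that("CL-repressed gene kinetics: derepression, repression, half-saturation", {
  expect_equal(repressed_gene_rhs(0.3, CL = 0, v = 2, K = 0.7, k = 0.5),
               2 - 0.5 * 0.3)
  expect_equal(repressed_gene_rhs(0.3, CL = 1e9, v = 2, K = 0.7, k = 0.5),
               -0.5 * 0.3, tolerance = 1e-12)
  expect_equal(repressed_gene_rhs(0, CL = 0.7, v = 2, K = 0.7, k = 0.5), 1)
  # strictly decreasing in CL
  cls <- seq(0, 3, by = 0.25)
  vals <- vapply(cls, function(cl)
    repressed_gene_rhs(0, cl, v = 2, K = 0.7, k = 0.5), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("translation kinetics settle at the closed-form steady state", {
  expect_equal(protein_rhs(0, 0, 0.6, 0.3), 0)
  Mstar <- 1.7
  Pstar <- 0.6 * Mstar / 0.3
  expect_equal(protein_rhs(Mstar, Pstar, 0.6, 0.3), 0)
  # periodic mRNA drives protein with the first-order-filter lag
  # atan(omega/d)/omega, which stays in (0, 6 h] for d >= 0.2/h
  omega <- 2 * pi / 24
  for (d in c(0.2, 0.5)) {
    M <- function(t) 2 + cos(omega * t)
    tr <- integrate_rk4(function(t, y) protein_rhs(M(t), y, 0.6, d),
                        y0 = 2 * 0.6 / d, t_end = 24 * 6, dt = 0.05)
    last <- tr$time >= 24 * 4
    pk <- peak_times(tr$time[last], tr$states[last, 1])
    lag <- (pk[1] %% 24)
    expect_equal(lag, atan(omega / d) / omega, tolerance = 0.05)
    expect_gt(lag, 0)
    expect_lte(lag, 6)
  }
})

test_that("gas-exchange output model identities hold", {
  cf <- photo_coef(alpha = 2, K1 = 0.5, K2 = 0.8, K3 = 1.2,
                   H = c(0.4, 0.5, 0.6, 0.7))
  # zero drivers: the basal rate
  expect_equal(photosynthetic_parameter(0, 0, rep(0, 4), cf), 2)
  # full GI inhibition: back to basal
  expect_equal(photosynthetic_parameter(1, 1e9, rep(1, 4), cf), 2,
               tolerance = 1e-10)
  # five half-saturated Hill terms with GI = 0: alpha + 2.5 K3^2/K2^2
  expect_equal(
    photosynthetic_parameter(0.5, 0, c(0.4, 0.5, 0.6, 0.7), cf),
    2 + 2.5 * 1.2^2 / 0.8^2)
  # monotone in each driver, bounded above
  set.seed(3)
  for (i in 1:20) {
    cl <- stats::runif(1, 0, 2); gi <- stats::runif(1, 0, 2)
    X <- stats::runif(4, 0, 2)
    base <- photosynthetic_parameter(cl, gi, X, cf)
    expect_gte(base, cf$alpha)
    expect_lte(base, cf$alpha + 5 * cf$K3^2 / cf$K2^2)
    expect_gt(photosynthetic_parameter(cl + 0.3, gi, X, cf), base)
    expect_lt(photosynthetic_parameter(cl, gi + 0.3, X, cf), base)
    for (j in 1:4) {
      X2 <- X; X2[j] <- X2[j] + 0.3
      expect_gt(photosynthetic_parameter(cl, gi, X2, cf), base)
    }
  }
  expect_error(photosynthetic_parameter(-1, 0, rep(0, 4), cf), ">= 0")
})

test_that("state validation rejects bad inputs", {
  p <- default_params()
  expect_error(clock_rhs(rep(-0.1, 29), p, 1, 0), ">= 0")
  expect_error(clock_rhs(rep(0.1, 10), p, 1, 0), "length")
  y <- default_y0(); y["P"] <- 1.5
  expect_error(clock_rhs(y, p, 1, 0), "0, 1")
  expect_error(clock_rhs(default_y0(), p, 1, 1), "complementary")
})
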