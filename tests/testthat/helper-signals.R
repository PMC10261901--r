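# shared fixtures: synthetic oscillations and small parameter edits

clock_genes <- c("CL", "P97", "P51", "EL", "GI", "RVE8")
photo_genes <- c("Lhcb1", "psbA", "RbcS1", "atpA")

# cosine-based series with peak at `phase`, period tau, on grid `time`
cos_series <- function(time, tau = 24, phase = 0, amp = 1, mean = 2,
                       harm2 = 0) {
  mean + amp * cos(2 * pi * (time - phase) / tau) +
    harm2 * cos(4 * pi * (time - phase) / tau)
}

# a fake dense trajectory whose six clock mRNAs are cosines with given
# phases (h) and a common period; used to exercise window logic without
# simulating
fake_trajectory <- function(phases, tau = 25, t_end = 120, dt = 0.25) {
  tg <- seq(0, t_end, by = dt)
  states <- matrix(0.1, length(tg), 29,
                   dimnames = list(NULL, clock_states()))
  for (g in names(phases)) {
    states[, paste0("M", sub("^M", "", g))] <-
      cos_series(tg, tau, phases[[g]])
  }
  structure(list(time = tg, states = states, dt = dt,
                 variant = "extended", protocol = NULL),
            class = "clock_trajectory")
}

# independent brute-force Enright statistic (the fold definition with
# the degrees-of-freedom correction, written separately from the package
# implementation)
enright_oracle <- function(time, value, taus) {
  dt <- diff(time)[1]
  n <- length(value)
  sst <- sum((value - mean(value))^2)
  vapply(taus, function(tau) {
    bin <- floor((time %% tau) / dt)
    mu <- tapply(value, bin, mean)
    ssw <- sum(vapply(split(value, bin), function(v)
      sum((v - mean(v))^2), numeric(1)))
    1 - (ssw / sst) * (n - 1) / (n - length(mu))
  }, numeric(1))
}

# cheap simulation settings for tests that only need qualitative runs
fast_run <- function(params, proto, ...)
  run_protocol(params, proto, burn_in_days = 6, dt = 0.1,
               record_every = 0.25, ...)
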