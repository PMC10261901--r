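#' Rhythm estimates
#'
#' Container for a period/phase/amplitude estimate from one method.
#' \code{phase} is the peak time in ZT hours of the fitted (or folded)
#' curve, in \code{[0, period)}.
#'
#' @param period period in hours.
#' @param phase peak time (ZT h).
#' @param amplitude half peak-to-trough of the fitted curve.
#' @param method one of \code{"mfourfit"}, \code{"mesa"},
#'   \code{"enright"}.
#' @param goodness method-specific quality (residual sum of squares for
#'   the harmonic fit, spectral/statistic peak height otherwise).
#' @param boundary TRUE when the period landed on the search-window edge
#'   (low-confidence flag).
#' @return object of class \code{rhythm_estimate}.
#' @export
rhythm_estimate <- function(period, phase, amplitude, method, goodness,
                            boundary = FALSE) {
  stopifnot(period > 0)
  structure(list(period = period, phase = phase %% period,
                 amplitude = amplitude, method = method,
                 goodness = goodness, boundary = boundary),
            class = "rhythm_estimate")
}

#' @export
print.rhythm_estimate <- function(x, ...) {
  cat(sprintf("<rhythm_estimate %s> period %.2f h, phase %.2f h, amp %.3g%s\n",
              x$method, x$period, x$phase, x$amplitude,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

.check_series <- function(time, value, min_cycles = 2, window = c(18, 34)) {
  stopifnot(length(time) == length(value), length(time) >= 8)
  if (anyNA(time) || anyNA(value)) stop("series must not contain NA")
  span <- diff(range(time))
  if (span < min_cycles * window[1])
    stop("series must span at least ", min_cycles, " cycles of the ",
         "shortest searched period")
  invisible(span)
}

.detrend <- function(time, value) {
  stats::residuals(stats::lm(value ~ time))
}

# harmonic RSS at fundamental tau; returns list(rss, fit function)
.harmonic_fit <- function(time, value, tau, n_harmonics) {
  X <- cbind(1, do.call(cbind, lapply(seq_len(n_harmonics), function(k)
    cbind(cos(2 * pi * k * time / tau), sin(2 * pi * k * time / tau)))))
  fit <- stats::lm.fit(X, value)
  list(rss = sum(fit$residuals^2), coef = fit$coefficients)
}

.harmonic_eval <- function(coef, tau, t, n_harmonics) {
  X <- cbind(1, do.call(cbind, lapply(seq_len(n_harmonics), function(k)
    cbind(cos(2 * pi * k * t / tau), sin(2 * pi * k * t / tau)))))
  drop(X %*% coef)
}

#' Multi-harmonic Fourier period estimation
#'
#' Least-squares fit of a mean plus \code{n_harmonics} harmonics of a
#' shared fundamental period, with the fundamental optimized over the
#' search window (coarse grid then local refinement). Phase is the ZT
#' time of the fitted curve's maximum within one period; amplitude is
#' half its peak-to-trough.
#'
#' @param time,value the series (time in ZT hours). At least two full
#'   cycles; sampling interval at most period/6.
#' @param period_window numeric(2), searched period range in hours.
#' @param n_harmonics number of harmonics (default 3).
#' @param detrend linearly detrend before fitting (default TRUE).
#' @return a \code{rhythm_estimate}.
#' @export
estimate_mfourfit <- function(time, value, period_window = c(18, 34),
                              n_harmonics = 3, detrend = TRUE) {
  .check_series(time, value, window = period_window)
  y <- if (detrend) .detrend(time, value) else value - mean(value)
  rssfun <- function(tau) .harmonic_fit(time, y, tau, n_harmonics)$rss
  taus <- seq(period_window[1], period_window[2], by = 0.25)
  rss <- vapply(taus, rssfun, numeric(1))
  i <- which.min(rss)
  lo <- taus[max(1, i - 1)]; hi <- taus[min(length(taus), i + 1)]
  opt <- stats::optimize(rssfun, c(lo, hi), tol = 1e-4)
  tau <- opt$minimum
  boundary <- tau - period_window[1] < 0.05 ||
    period_window[2] - tau < 0.05
  fit <- .harmonic_fit(time, y, tau, n_harmonics)
  tg <- seq(0, tau, by = 0.01)
  curve <- .harmonic_eval(fit$coef, tau, tg, n_harmonics)
  rhythm_estimate(period = tau, phase = tg[which.max(curve)],
                  amplitude = (max(curve) - min(curve)) / 2,
                  method = "mfourfit", goodness = fit$rss,
                  boundary = boundary)
}

# power spectrum of an AR model at frequencies f (cycles/h)
.ar_spectrum <- function(ar_coef, var_pred, f, dt_samp) {
  k <- seq_along(ar_coef)
  resp <- vapply(f, function(fi)
    abs(1 - sum(ar_coef * exp(-2i * pi * fi * dt_samp * k)))^2, numeric(1))
  var_pred * dt_samp / resp
}

#' Maximum-entropy (Burg) spectral period estimation
#'
#' Mean-centre, fit an autoregressive model by Burg's method (order
#' chosen by AIC, offered up to half the series length), evaluate the AR
#' spectrum on a fine frequency grid, and take the period at the
#' spectral maximum inside the window (with quadratic refinement around
#' the grid peak). Series sampled finer than hourly are decimated to
#' ~1 h first: the AR order must span a period, and at sub-hourly
#' sampling that demands orders the short records cannot support. Phase
#' is obtained by harmonic regression of the series on a cosine at the
#' estimated period.
#'
#' @inheritParams estimate_mfourfit
#' @param order_max maximum AR order offered to the AIC selection.
#' @param df frequency grid step in cycles/h.
#' @param detrend remove a linear trend first (default FALSE: on records
#'   a few cycles long the trend estimate absorbs part of the
#'   oscillation and biases the spectral peak).
#' @return a \code{rhythm_estimate}.
#' @export
estimate_mesa <- function(time, value, period_window = c(18, 34),
                          order_max = NULL, df = 2e-5, detrend = FALSE) {
  .check_series(time, value, window = period_window)
  dt_samp <- diff(time)
  if (diff(range(dt_samp)) > 1e-6)
    stop("MESA needs a uniformly sampled series")
  dt_samp <- dt_samp[1]
  if (dt_samp < 1) {                 # decimate to ~1 h sampling
    stride <- max(1L, as.integer(round(1 / dt_samp)))
    keep <- seq(1, length(time), by = stride)
    time <- time[keep]; value <- value[keep]
    dt_samp <- dt_samp * stride
  }
  y <- if (detrend) .detrend(time, value) else value - mean(value)
  if (stats::sd(y) < 1e-12)
    stop("constant series: no spectral peak to estimate")
  ar <- stats::ar.burg(y, aic = TRUE,
                       order.max = order_max %||%
                         min(length(y) - 2, max(8, floor(length(y) / 2))))
  if (ar$order == 0)
    stop("AR order 0 selected: series has no usable autocorrelation")
  f <- seq(1 / period_window[2], 1 / period_window[1], by = df)
  spec <- .ar_spectrum(ar$ar, ar$var.pred, f, dt_samp)
  i <- which.max(spec)
  if (i > 1 && i < length(spec)) {     # quadratic peak refinement
    num <- spec[i - 1] - spec[i + 1]
    den <- spec[i - 1] - 2 * spec[i] + spec[i + 1]
    shift <- if (abs(den) > 0) 0.5 * num / den else 0
    fpk <- f[i] + shift * df
  } else fpk <- f[i]
  tau <- 1 / fpk
  boundary <- i == 1 || i == length(spec)
  # phase and amplitude from harmonic regression at tau
  fit <- .harmonic_fit(time, y, tau, 1)
  a <- fit$coef[2]; b <- fit$coef[3]
  phase <- (atan2(b, a) * tau / (2 * pi)) %% tau
  rhythm_estimate(period = tau, phase = phase,
                  amplitude = sqrt(a^2 + b^2),
                  method = "mesa", goodness = max(spec),
                  boundary = boundary)
}

#' Enright periodogram period estimation
#'
#' For each candidate period the series is folded into bins of width
#' equal to the sampling interval and scored by the variance of the bin
#' means relative to the total variance, corrected for the fold's
#' degrees of freedom (the adjusted R-squared of the bin-means model:
#' \code{1 - (SSW/SST) * (n-1)/(n-B)} with \code{B} occupied bins).
#' Without the correction the raw ratio inflates as bins empty out,
#' which biases short records towards long candidate periods. The period
#' is the argmax over the candidate grid and the phase is the centre of
#' the peak bin of the folded means.
#'
#' @inheritParams estimate_mfourfit
#' @param candidate_periods candidate period grid (h), default 18 to 34
#'   by 0.1.
#' @return a \code{rhythm_estimate}.
#' @export
estimate_enright <- function(time, value,
                             candidate_periods = seq(18, 34, by = 0.1)) {
  .check_series(time, value,
                window = range(candidate_periods))
  dt_samp <- diff(time)
  if (diff(range(dt_samp)) > 1e-6)
    stop("the Enright periodogram needs a uniformly sampled series")
  dt_samp <- dt_samp[1]
  if (min(candidate_periods) < 2 * dt_samp)
    stop("candidate periods below the Nyquist-resolvable range")
  sst <- sum((value - mean(value))^2)
  if (sst == 0) stop("constant series: no rhythm to estimate")
  n <- length(value)
  stat <- numeric(length(candidate_periods))
  for (k in seq_along(candidate_periods)) {
    tau <- candidate_periods[k]
    bin <- floor((time %% tau) / dt_samp)
    fitted <- stats::ave(value, bin)
    B <- length(unique(bin))
    stat[k] <- 1 - (sum((value - fitted)^2) / sst) * (n - 1) / (n - B)
  }
  i <- which.max(stat)
  tau <- candidate_periods[i]
  bin <- floor((time %% tau) / dt_samp)
  mu <- tapply(value, bin, mean)
  centers <- (as.numeric(names(mu)) + 0.5) * dt_samp
  rhythm_estimate(period = tau, phase = centers[which.max(mu)],
                  amplitude = (max(mu) - min(mu)) / 2,
                  method = "enright", goodness = stat[i],
                  boundary = i == 1 || i == length(candidate_periods))
}

#' Peak times of a series
#'
#' Local maxima located by quadratic interpolation around each discrete
#' argmax; one value per cycle, in the series' own time units (ZT h).
#'
#' @param time,value the series.
#' @param min_prominence smallest peak-to-neighbour-trough height,
#'   relative to the series range, for a maximum to count (default 0.05).
#' @return numeric vector of peak times (possibly empty).
#' @export
peak_times <- function(time, value, min_prominence = 0.05) {
  stopifnot(length(time) == length(value))
  n <- length(value)
  if (n < 3) return(numeric(0))
  rng <- diff(range(value))
  if (rng == 0) return(numeric(0))
  out <- numeric(0)
  for (i in 2:(n - 1)) {
    if (!(value[i] > value[i - 1] && value[i] >= value[i + 1])) next
    # topographic prominence: walk each way until a strictly higher
    # point (or the boundary); the reference saddle is the higher of the
    # two minima found, so twin-tipped peaks count once, through the
    # taller tip
    jl <- i; lmin <- value[i]
    while (jl > 1 && value[jl - 1] <= value[i]) {
      jl <- jl - 1; lmin <- min(lmin, value[jl])
    }
    jr <- i; rmin <- value[i]
    while (jr < n && value[jr + 1] <= value[i]) {
      jr <- jr + 1; rmin <- min(rmin, value[jr])
    }
    prom <- value[i] - max(lmin, rmin)
    if (prom / rng >= min_prominence) {
      den <- value[i - 1] - 2 * value[i] + value[i + 1]
      shift <- if (abs(den) > 0)
        0.5 * (value[i - 1] - value[i + 1]) / den else 0
      out <- c(out, time[i] + shift * (time[i] - time[i - 1]))
    }
  }
  out
}

#' Aggregate rhythm estimates
#'
#' Arithmetic mean and standard deviation for the period; circular mean
#' (and circular standard deviation) for the phase, computed modulo the
#' mean period.
#'
#' @param estimates list of \code{rhythm_estimate} objects (at least 2).
#' @return list with \code{period_mean}, \code{period_sd},
#'   \code{phase_mean}, \code{phase_sd}, \code{n}.
#' @export
aggregate_estimates <- function(estimates) {
  if (inherits(estimates, "rhythm_estimate")) estimates <- list(estimates)
  if (length(estimates) < 2)
    stop("need at least 2 estimates to aggregate")
  ok <- vapply(estimates, inherits, logical(1), "rhythm_estimate")
  if (!all(ok)) stop("estimates must be rhythm_estimate objects")
  periods <- vapply(estimates, `[[`, numeric(1), "period")
  phases <- vapply(estimates, `[[`, numeric(1), "phase")
  tau <- mean(periods)
  ang <- 2 * pi * phases / tau
  S <- mean(sin(ang)); C <- mean(cos(ang))
  phase_mean <- (atan2(S, C) * tau / (2 * pi)) %% tau
  R <- sqrt(S^2 + C^2)
  phase_sd <- if (R >= 1) 0 else sqrt(-2 * log(R)) * tau / (2 * pi)
  list(period_mean = tau, period_sd = stats::sd(periods),
       phase_mean = phase_mean, phase_sd = phase_sd,
       n = length(estimates))
}

#' Period and phase by all three methods
#'
#' Convenience wrapper running the harmonic fit, MESA and the Enright
#' periodogram on one series and aggregating.
#'
#' @inheritParams estimate_mfourfit
#' @return list with the three \code{rhythm_estimate}s (\code{$by_method})
#'   and the aggregate (\code{$summary}).
#' @export
estimate_rhythm <- function(time, value, period_window = c(18, 34)) {
  ests <- list(
    mfourfit = estimate_mfourfit(time, value, period_window),
    mesa = estimate_mesa(time, value, period_window),
    enright = estimate_enright(time, value,
                               seq(period_window[1], period_window[2],
                                   by = 0.1)))
  list(by_method = ests, summary = aggregate_estimates(unname(ests)))
}

#' Circular distance between two phases
#'
#' Shortest distance around the cycle, in hours.
#' @param a,b phases (h).
#' @param period cycle length (h).
#' @return distance in \code{[0, period/2]}.
#' @export
circular_distance <- function(a, b, period = 24) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}
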