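#' Default rhythm constraints of the calibrated clock
#'
#' Free-running (LL) peak-time windows per clock gene (ZT h after release
#' to constant light) and the common period window, the two features the
#' calibration requires the clock genes to meet simultaneously.
#'
#' @return list with \code{period_window} and \code{phase_windows} (named
#'   list of numeric(2)).
#' @export
clock_constraints <- function() {
  list(period_window = c(24, 28),
       phase_windows = list(CL = c(0, 4), P97 = c(6, 10), P51 = c(12, 15),
                            EL = c(10, 15), GI = c(11, 13),
                            RVE8 = c(0, 3)))
}

#' Fitting target
#'
#' One observed series with its rhythm windows and weights, used by
#' \code{\link{cost_delta}}.
#'
#' @param gene gene label (\code{CL}, \code{P97}, \code{P51}, \code{EL},
#'   \code{GI}, \code{RVE8}, or a photosynthetic gene).
#' @param condition protocol name the observations were collected under
#'   (\code{"muller_LL"}, \code{"MI_to_LI"}, \code{"MI_to_NI"},
#'   \code{"MI_to_MI"}).
#' @param time,value observed series; values are max-normalized
#'   internally, so any positive scaling of the raw data is equivalent.
#' @param period_window,phase_window numeric(2) target windows (h); the
#'   corresponding cost terms are zero inside the window.
#' @param w_expr,w_period,w_phase nonnegative weights (not all zero).
#' @return object of class \code{fit_target}.
#' @export
fit_target <- function(gene, condition, time, value,
                       period_window = clock_constraints()$period_window,
                       phase_window = NULL,
                       w_expr = 1, w_period = 1, w_phase = 1) {
  stopifnot(length(time) == length(value), all(value >= 0))
  if (is.null(phase_window))
    phase_window <- clock_constraints()$phase_windows[[gene]] %||% c(0, 24)
  if (any(c(w_expr, w_period, w_phase) < 0) ||
      w_expr + w_period + w_phase == 0)
    stop("weights must be >= 0 and not all zero")
  if (diff(period_window) < 0 || diff(phase_window) < 0)
    stop("windows must be nonempty")
  structure(list(gene = gene, condition = condition, time = time,
                 value = normalize_series(value, "max"),
                 period_window = period_window,
                 phase_window = phase_window,
                 w_expr = w_expr, w_period = w_period, w_phase = w_phase),
            class = "fit_target")
}

# phase = ZT time of the dominant peak within the first cycle after the
# treatment start (small acute-light ripples right after dawn must not
# shadow the real expression peak)
.phase_peak <- function(time, value, tau) {
  pk <- peak_times(time, value)
  pk <- pk[pk >= 0 & pk < tau]
  if (length(pk)) {
    heights <- stats::approx(time, value, xout = pk, rule = 2)$y
    pk[which.max(heights)]
  } else {
    win <- time >= 0 & time < tau
    if (!any(win)) return(NA_real_)
    time[win][which.max(value[win])]
  }
}

# rhythm features of one simulated gene series: period (harmonic fit),
# phase (dominant first-cycle peak), relative amplitude
.sim_features <- function(time, value, period_window = c(18, 34)) {
  est <- try(estimate_mfourfit(time, value, period_window), silent = TRUE)
  if (inherits(est, "try-error")) return(NULL)
  mu <- mean(value)
  list(period = est$period,
       phase = .phase_peak(time, value, est$period),
       relamp = if (mu > 0) (max(value) - min(value)) / mu else 0,
       boundary = est$boundary)
}

#' Cost function over expression, period and phase targets
#'
#' \code{delta = sum over targets of w_expr * RMSE(normalized simulation
#' vs observation at the observed time points) + w_period * |tau_sim -
#' tau_mid| / tau_mid + w_phase * circdist(phi_sim, phi_mid) / 24}, with
#' the period and phase terms hard-zeroed inside the target windows
#' (tau_mid, phi_mid are the window midpoints). A failed simulation
#' contributes a large finite penalty (1e6).
#'
#' @param params a \code{clock_params}.
#' @param targets list of \code{fit_target}s.
#' @param dt,burn_in_days simulation settings (coarser defaults than the
#'   analysis-grade ones: the fit loop favours speed).
#' @return the scalar cost delta (>= 0).
#' @export
cost_delta <- function(params, targets, dt = 0.1, burn_in_days = 6) {
  if (inherits(targets, "fit_target")) targets <- list(targets)
  conditions <- unique(vapply(targets, `[[`, character(1), "condition"))
  sims <- list()
  for (cond in conditions) {
    tr <- try(run_protocol(params, cond, burn_in_days = burn_in_days,
                           dt = dt, record_every = 0.25), silent = TRUE)
    sims[[cond]] <- tr
  }
  delta <- 0
  for (tg in targets) {
    tr <- sims[[tg$condition]]
    if (inherits(tr, "try-error")) { delta <- delta + 1e6; next }
    var <- .gene_mrna[[tg$gene]] %||% tg$gene
    sim <- trajectory_series(tr, var)
    if (max(sim$value) <= 0) { delta <- delta + 1e6; next }
    if (tg$w_expr > 0) {
      at <- stats::approx(sim$time_h, sim$value, xout = tg$time,
                          rule = 2)$y
      if (max(at) <= 0) { delta <- delta + 1e6; next }
      # both sides max-normalized over the observed time points, so the
      # expression term compares waveform shape only
      delta <- delta + tg$w_expr * sqrt(mean((at / max(at) -
                                                tg$value)^2))
    }
    if (tg$w_period > 0 || tg$w_phase > 0) {
      ft <- .sim_features(sim$time_h, sim$value)
      if (is.null(ft) || !is.finite(ft$period)) { delta <- delta + 1e6; next }
      pw <- tg$period_window
      if (tg$w_period > 0 && (ft$period < pw[1] || ft$period > pw[2])) {
        mid <- mean(pw)
        delta <- delta + tg$w_period * abs(ft$period - mid) / mid
      }
      hw <- tg$phase_window
      if (tg$w_phase > 0 &&
          (is.na(ft$phase) || ft$phase < hw[1] || ft$phase > hw[2])) {
        d <- if (is.na(ft$phase)) 12
             else circular_distance(ft$phase, mean(hw))
        delta <- delta + tg$w_phase * d / 24
      }
    }
  }
  delta
}

#' Simulated annealing minimizer
#'
#' Metropolis acceptance \code{exp(-delta_cost / T)} with geometric
#' cooling \code{T <- gamma * T} every \code{cool_every} proposals.
#' Proposals perturb one coordinate at a time: multiplicatively in log
#' space for strictly positive coordinates, additively otherwise, always
#' clipped to the bounds. Reproducible given \code{seed}.
#'
#' @param cost function of a numeric vector returning a scalar cost.
#' @param x0 numeric start vector (named or not).
#' @param lower,upper bounds, recycled to \code{length(x0)}; must be
#'   finite.
#' @param seed integer RNG seed.
#' @param max_iter number of proposals (> 0).
#' @param T0 initial temperature (default: the starting cost, or 1 if it
#'   is zero).
#' @param gamma cooling factor per stage (default 0.95).
#' @param cool_every proposals per cooling stage (default 50).
#' @param T_stop stop when \code{T < T_stop * T0} (default 1e-3).
#' @param step log-space proposal scale (default 0.15).
#' @return object of class \code{fit_result}: list with \code{par} (best
#'   vector), \code{value} (best cost), \code{trace} (data.frame of
#'   accepted moves: iteration, cost, temperature), \code{seed},
#'   \code{iterations}.
#' @export
simulated_annealing <- function(cost, x0, lower, upper, seed = 1,
                                max_iter = 20000, T0 = NULL,
                                gamma = 0.95, cool_every = 50,
                                T_stop = 1e-3, step = 0.15) {
  if (max_iter < 0) stop("max_iter must be nonnegative")
  n <- length(x0)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("bounds must be finite")
  if (any(x0 < lower - 1e-12) || any(x0 > upper + 1e-12))
    stop("x0 must satisfy the bounds")
  set.seed(seed)
  x <- pmin(pmax(as.numeric(x0), lower), upper)
  fx <- cost(x)
  best <- x; fbest <- fx
  if (is.null(T0)) T0 <- if (fx > 0) fx else 1
  Temp <- T0
  tr_it <- integer(0); tr_cost <- numeric(0); tr_T <- numeric(0)
  it <- 0L
  while (it < max_iter && Temp >= T_stop * T0) {
    it <- it + 1L
    j <- sample.int(n, 1)
    xp <- x
    if (x[j] > 1e-8 && lower[j] >= 0) {
      xp[j] <- x[j] * exp(stats::rnorm(1, 0, step))
    } else {
      xp[j] <- x[j] + stats::rnorm(1, 0, step * (upper[j] - lower[j]) / 4)
    }
    xp[j] <- min(max(xp[j], lower[j]), upper[j])
    fp <- cost(xp)
    if (fp <= fx || stats::runif(1) < exp(-(fp - fx) / Temp)) {
      x <- xp; fx <- fp
      tr_it <- c(tr_it, it); tr_cost <- c(tr_cost, fx)
      tr_T <- c(tr_T, Temp)
      if (fx < fbest) { best <- x; fbest <- fx }
    }
    if (it %% cool_every == 0) Temp <- gamma * Temp
  }
  names(best) <- names(x0)
  structure(list(par = best, value = fbest,
                 trace = data.frame(iteration = tr_it, cost = tr_cost,
                                    temperature = tr_T),
                 seed = seed, iterations = it),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> best cost %.4g after %d proposals (seed %d)\n",
              x$value, x$iterations, x$seed))
  invisible(x)
}

#' Fit free clock parameters to targets
#'
#' Runs \code{\link{simulated_annealing}} over the free parameters of
#' \code{params} (the registry's free/fixed mask) against
#' \code{\link{cost_delta}}.
#'
#' @param params starting \code{clock_params}.
#' @param targets list of \code{fit_target}s.
#' @param free character vector of parameter names to fit (default: the
#'   set marked free in \code{params}).
#' @param seed,max_iter,... passed to \code{\link{simulated_annealing}}.
#' @param dt,burn_in_days passed to \code{\link{cost_delta}}.
#' @param polish after annealing, run a bounded Nelder-Mead refinement in
#'   log-parameter space from the annealer's best point (default TRUE;
#'   the annealer locates the basin, the simplex converges inside it).
#' @return \code{fit_result} with an extra element \code{params}, the
#'   refitted \code{clock_params}.
#' @export
fit_clock <- function(params, targets, free = NULL, seed = 1,
                      max_iter = 2000, dt = 0.1, burn_in_days = 6,
                      polish = TRUE, ...) {
  stopifnot(inherits(params, "clock_params"))
  free <- free %||% attr(params, "free")
  lower <- attr(params, "lower")[free]
  upper <- attr(params, "upper")[free]
  x0 <- as.numeric(params[free])
  costfun <- function(x) {
    p <- set_params(params, stats::setNames(x, free))
    cost_delta(p, targets, dt = dt, burn_in_days = burn_in_days)
  }
  res <- simulated_annealing(costfun, stats::setNames(x0, free),
                             lower, upper, seed = seed,
                             max_iter = max_iter, ...)
  if (polish) {
    clamp <- function(x) pmin(pmax(x, pmax(lower, 1e-8)), upper)
    lx <- log(clamp(res$par)); best <- res$value
    for (round in 1:2) {    # restart once: simplexes collapse in valleys
      nm <- stats::optim(lx, function(z) costfun(clamp(exp(z))),
                         method = "Nelder-Mead",
                         control = list(maxit = 500, reltol = 1e-10))
      if (nm$value < best) { best <- nm$value; lx <- nm$par }
    }
    if (best < res$value) {
      res$par <- stats::setNames(clamp(exp(lx)), free)
      res$value <- best
    }
  }
  res$params <- set_params(params, res$par)
  res
}

#' Check the free-running rhythm constraints
#'
#' Simulates (or takes) a constant-light trajectory and reports, per
#' clock gene, whether the estimated period lies in the 24-28 h window
#' and the first folded peak falls in the gene's stated window.
#' Arrhythmic series (relative peak-to-trough below 1%) are flagged as
#' violations, not errors.
#'
#' @param x a \code{clock_params} (a \code{muller_LL} run is performed)
#'   or a \code{clock_trajectory} covering at least 2 LL cycles.
#' @param ... passed to \code{\link{run_protocol}} when \code{x} is a
#'   parameter set.
#' @return data.frame with columns \code{gene}, \code{period},
#'   \code{phase}, \code{period_ok}, \code{phase_ok}, \code{rhythmic};
#'   attribute \code{pass} TRUE when every check holds.
#' @export
check_constraints <- function(x, ...) {
  traj <- if (inherits(x, "clock_params"))
    run_protocol(x, "muller_LL", ...) else x
  stopifnot(inherits(traj, "clock_trajectory"))
  if (max(traj$time) < 48)
    stop("trajectory must cover at least 2 LL cycles")
  cons <- clock_constraints()
  genes <- names(cons$phase_windows)
  rows <- lapply(genes, function(g) {
    s <- trajectory_series(traj, .gene_mrna[[g]])
    ft <- .sim_features(s$time_h, s$value)
    if (is.null(ft) || ft$relamp < 0.01) {
      return(data.frame(gene = g, period = NA_real_, phase = NA_real_,
                        period_ok = FALSE, phase_ok = FALSE,
                        rhythmic = FALSE))
    }
    pw <- cons$period_window; hw <- cons$phase_windows[[g]]
    data.frame(gene = g, period = ft$period, phase = ft$phase,
               period_ok = ft$period >= pw[1] && ft$period <= pw[2],
               phase_ok = !is.na(ft$phase) &&
                 ft$phase >= hw[1] && ft$phase <= hw[2],
               rhythmic = TRUE)
  })
  out <- do.call(rbind, rows)
  attr(out, "pass") <- all(out$period_ok & out$phase_ok & out$rhythmic)
  out
}
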