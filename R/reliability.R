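#' Robustness of period and phase to ±10% parameter changes
#'
#' Perturbs every free parameter by the given fraction in both
#' directions, re-simulates the free-run (LL) protocol, and reports the
#' percent change in period and phase of CL and P51 mRNA relative to the
#' unperturbed run. The phase change is the circular distance divided by
#' the baseline period, times 100 (a scale-free percentage). Perturbed
#' runs that lose rhythmicity are flagged and excluded from the summary
#' maxima with a warning.
#'
#' @param params calibrated \code{clock_params}.
#' @param fraction perturbation size (default 0.1).
#' @param genes gene labels to track (default CL and P51).
#' @param parameters parameter names to perturb (default: all free).
#' @param dt,burn_in_days,treatment_days simulation settings.
#' @return data.frame with one row per parameter x direction x gene:
#'   \code{parameter}, \code{direction}, \code{gene},
#'   \code{period_change_pct}, \code{phase_change_pct}, \code{rhythmic}.
#'   Attributes \code{max_period_change} and \code{max_phase_change}
#'   carry the summary maxima.
#' @export
robustness_scan <- function(params, fraction = 0.1,
                            genes = c("CL", "P51"), parameters = NULL,
                            dt = 0.05, burn_in_days = 10,
                            treatment_days = 4) {
  stopifnot(inherits(params, "clock_params"))
  parameters <- parameters %||% attr(params, "free")
  base <- run_protocol(params, "muller_LL", burn_in_days = burn_in_days,
                       dt = dt, treatment_days = treatment_days)
  # period and phase from the harmonic fit: its fitted-curve peak moves
  # continuously with the parameters, unlike a raw argmax over a
  # multi-modal waveform, so percent changes measure dynamics rather
  # than peak-relabelling
  feats <- function(traj) lapply(genes, function(g) {
    s <- trajectory_series(traj, .gene_mrna[[g]])
    est <- try(estimate_mfourfit(s$time_h, s$value), silent = TRUE)
    if (inherits(est, "try-error")) return(NULL)
    mu <- mean(s$value)
    list(period = est$period, phase = est$phase,
         relamp = if (mu > 0) (max(s$value) - min(s$value)) / mu else 0,
         boundary = est$boundary)
  })
  f0 <- feats(base)
  names(f0) <- genes
  rows <- list()
  for (pn in parameters) {
    for (dir in c(1, -1)) {
      p2 <- set_params(params,
                       stats::setNames(params[[pn]] * (1 + dir * fraction),
                                       pn))
      tr <- try(run_protocol(p2, "muller_LL",
                             burn_in_days = burn_in_days, dt = dt,
                             treatment_days = treatment_days),
                silent = TRUE)
      lab <- if (dir > 0) sprintf("+%g%%", 100 * fraction)
             else sprintf("-%g%%", 100 * fraction)
      ftp <- if (!inherits(tr, "try-error")) feats(tr) else NULL
      names(ftp) <- if (!is.null(ftp)) genes
      for (g in genes) {
        ft <- ftp[[g]]
        rhythmic <- !is.null(ft) && is.finite(ft$period) &&
          ft$relamp >= 0.01 && !ft$boundary
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = pn, direction = lab, gene = g,
          period_change_pct = if (rhythmic)
            100 * abs(ft$period - f0[[g]]$period) / f0[[g]]$period
            else NA_real_,
          phase_change_pct = if (rhythmic)
            100 * circular_distance(ft$phase, f0[[g]]$phase,
                                    f0[[g]]$period) / f0[[g]]$period
            else NA_real_,
          rhythmic = rhythmic)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (any(!out$rhythmic))
    warning(sum(!out$rhythmic),
            " perturbed run(s) lost rhythmicity; excluded from maxima")
  attr(out, "max_period_change") <- max(out$period_change_pct, na.rm = TRUE)
  attr(out, "max_phase_change") <- max(out$phase_change_pct, na.rm = TRUE)
  out
}

#' Log-scale parameter sensitivity scan
#'
#' Scans each parameter over fold changes of its calibrated value on a
#' log grid spanning 1e-3 to 1e3 and records whether the free-running
#' clock still meets both rhythm features (period in 24-28 h and all six
#' peak-time windows; see \code{\link{check_constraints}}). The viable
#' range is the maximal contiguous passing interval containing fold 1.
#'
#' @param params calibrated \code{clock_params}.
#' @param parameters parameter names to scan (default: all free; the
#'   full scan is expensive — restrict for interactive use).
#' @param folds fold-change grid (default 25 log-spaced points over
#'   [1e-3, 1e3], with fold 1 inserted).
#' @param dt,burn_in_days,treatment_days simulation settings.
#' @return data.frame with columns \code{parameter}, \code{fold},
#'   \code{pass}; attribute \code{viable} is a data.frame of per-parameter
#'   viable fold ranges.
#' @export
sensitivity_scan <- function(params, parameters = NULL,
                             folds = NULL, dt = 0.1,
                             burn_in_days = 8, treatment_days = 3) {
  stopifnot(inherits(params, "clock_params"))
  parameters <- parameters %||% attr(params, "free")
  folds <- folds %||% sort(unique(c(1, 10^seq(-3, 3, length.out = 25))))
  if (is.unsorted(folds)) stop("fold grid must be monotone")
  rows <- list()
  for (pn in parameters) {
    for (fold in folds) {
      p2 <- set_params(params, stats::setNames(params[[pn]] * fold, pn))
      res <- try(check_constraints(p2, burn_in_days = burn_in_days,
                                   dt = dt,
                                   treatment_days = treatment_days),
                 silent = TRUE)
      pass <- !inherits(res, "try-error") && isTRUE(attr(res, "pass"))
      rows[[length(rows) + 1L]] <- data.frame(parameter = pn,
                                              fold = fold, pass = pass)
    }
  }
  out <- do.call(rbind, rows)
  viable <- do.call(rbind, lapply(parameters, function(pn) {
    sub <- out[out$parameter == pn, ]
    i1 <- which(sub$fold == 1)
    lo <- i1; while (lo > 1 && sub$pass[lo - 1]) lo <- lo - 1
    hi <- i1; while (hi < nrow(sub) && sub$pass[hi + 1]) hi <- hi + 1
    data.frame(parameter = pn,
               fold_min = if (sub$pass[i1]) sub$fold[lo] else NA_real_,
               fold_max = if (sub$pass[i1]) sub$fold[hi] else NA_real_,
               contiguous = all(sub$pass[lo:hi]) &&
                 !any(sub$pass[-(lo:hi)] &
                        (seq_len(nrow(sub)) < lo | seq_len(nrow(sub)) > hi)))
  }))
  attr(out, "viable") <- viable
  out
}

# central finite-difference Jacobian of F at y
.fd_jacobian <- function(F, y, rel_step = 1e-6) {
  n <- length(y)
  J <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    h <- rel_step * max(1, abs(y[j]))
    yp <- y; ym <- y
    yp[j] <- y[j] + h; ym[j] <- y[j] - h
    J[, j] <- (F(yp) - F(ym)) / (2 * h)
  }
  J
}

# damped Newton for F(y) = 0 starting at y0; NULL on failure
.newton_fixed_point <- function(F, y0, tol = 1e-10, max_iter = 100) {
  y <- y0
  for (i in seq_len(max_iter)) {
    Fy <- F(y)
    if (max(abs(Fy)) < tol) return(y)
    J <- .fd_jacobian(F, y)
    step <- try(solve(J, -Fy), silent = TRUE)
    if (inherits(step, "try-error")) return(NULL)
    lambda <- 1
    repeat {
      yn <- y + lambda * step
      if (sum(F(yn)^2) < sum(Fy^2) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    if (lambda < 1e-6 && sum(F(yn)^2) >= sum(Fy^2)) return(NULL)
    y <- yn
  }
  if (max(abs(F(y))) < 1e-6) y else NULL
}

# amplitude + eigenvalue rhythmicity classification of the full model in
# LL at the given parameter setting
.classify_ll <- function(params, intensity, observable, dt,
                         t_transient, t_window) {
  proto <- light_protocol(ll_segment(t_transient + t_window, intensity))
  tr <- try(integrate_model(params, proto, dt = dt, record_every = 0.25),
            silent = TRUE)
  if (inherits(tr, "try-error"))
    return(list(amplitude = NA_real_, amp_rhythmic = NA,
                eig_real = NA_real_, eig_rhythmic = NA,
                level = NA_real_))
  keep <- tr$time >= t_transient
  obs <- tr$states[keep, observable]
  mu <- mean(obs)
  amp <- max(obs) - min(obs)
  amp_rhythmic <- amp > 0.01 * max(mu, 1e-12)
  f <- intensity_scale(intensity, tr$params)
  F <- function(y) as.numeric(.clock_rhs_cpp(pmax(y, 0),
                                             as.numeric(params),
                                             1, 0, f, 0L))
  ystar <- .newton_fixed_point(F, colMeans(tr$states[keep, , drop = FALSE]))
  if (is.null(ystar)) {
    return(list(amplitude = amp, amp_rhythmic = amp_rhythmic,
                eig_real = NA_real_, eig_rhythmic = NA, level = mu))
  }
  ev <- eigen(.fd_jacobian(F, ystar), only.values = TRUE)$values
  cplx <- ev[abs(Im(ev)) > 1e-8]
  lead <- if (length(cplx)) max(Re(cplx)) else max(Re(ev))
  list(amplitude = amp, amp_rhythmic = amp_rhythmic,
       eig_real = lead, eig_rhythmic = lead > 0, level = mu)
}

#' Hopf / oscillation-death scan
#'
#' Scans a control quantity over a range and classifies rhythmicity by
#' two criteria: (a) amplitude — post-transient peak-to-trough of the
#' observable above 1% of its mean; (b) eigenvalues — sign of the real
#' part of the leading complex pair at the constant-light fixed point
#' (damped Newton from the mean state, finite-difference Jacobian).
#' Bifurcation points are sign changes of each criterion along the grid,
#' bisected to 1e-3 relative accuracy.
#'
#' Two kinds of system are supported: the full model (pass a
#' \code{clock_params}; \code{parameter} is a parameter name or
#' \code{"intensity"} for the LL light level) and a plug-in system for
#' validation (pass a function of the scanned value returning
#' \code{list(rhs = function(t, y), y0, observable = index)}).
#'
#' @param system \code{clock_params} or a plug-in factory function.
#' @param parameter scanned parameter name, or \code{"intensity"}.
#' @param range numeric(2) scan range.
#' @param n_grid number of grid points (default 9).
#' @param observable state name observed for the amplitude criterion
#'   (default \code{"MLhcb1"}).
#' @param dt,t_transient,t_window simulation settings for the amplitude
#'   criterion.
#' @param intensity LL intensity when scanning a kinetic parameter.
#' @return list with \code{scan} (data.frame) and \code{bifurcations}
#'   (data.frame of criterion, lower, upper, point).
#' @export
hopf_scan <- function(system, parameter = "intensity",
                      range = c(50, 1500), n_grid = 9,
                      observable = "MLhcb1", dt = 0.1,
                      t_transient = 240, t_window = 120,
                      intensity = 100) {
  grid <- seq(range[1], range[2], length.out = n_grid)
  if (inherits(system, "clock_params")) {
    classify <- function(v) {
      if (parameter == "intensity") {
        .classify_ll(system, v, observable, dt, t_transient, t_window)
      } else {
        p2 <- set_params(system, stats::setNames(v, parameter))
        .classify_ll(p2, intensity, observable, dt, t_transient, t_window)
      }
    }
  } else if (is.function(system)) {
    classify <- function(v) {
      sys <- system(v)
      tr <- integrate_rk4(sys$rhs, sys$y0, t_transient + t_window, dt)
      keep <- tr$time >= t_transient
      obs <- tr$states[keep, sys$observable %||% 1]
      amp <- max(obs) - min(obs)
      F <- function(y) sys$rhs(0, y)
      ystar <- .newton_fixed_point(F, colMeans(tr$states[keep, ,
                                                         drop = FALSE]))
      eig_real <- NA_real_
      if (!is.null(ystar)) {
        ev <- eigen(.fd_jacobian(F, ystar), only.values = TRUE)$values
        cplx <- ev[abs(Im(ev)) > 1e-8]
        eig_real <- if (length(cplx)) max(Re(cplx)) else max(Re(ev))
      }
      list(amplitude = amp,
           amp_rhythmic = amp > max(0.01 * abs(mean(obs)), 1e-5),
           eig_real = eig_real,
           eig_rhythmic = if (is.na(eig_real)) NA else eig_real > 0,
           level = mean(obs))
    }
  } else stop("system must be clock_params or a factory function")

  res <- lapply(grid, classify)
  scan <- data.frame(value = grid,
                     amplitude = vapply(res, `[[`, numeric(1), "amplitude"),
                     amp_rhythmic = vapply(res, function(r)
                       isTRUE(r$amp_rhythmic), logical(1)),
                     eig_real = vapply(res, `[[`, numeric(1), "eig_real"),
                     eig_rhythmic = vapply(res, function(r)
                       isTRUE(r$eig_rhythmic), logical(1)),
                     level = vapply(res, `[[`, numeric(1), "level"))
  bif <- list()
  bisect <- function(lo, hi, test, flo) {
    while ((hi - lo) / max(abs(hi), abs(lo), 1e-12) > 1e-3) {
      mid <- (lo + hi) / 2
      if (identical(test(mid), flo)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  for (crit in c("amp_rhythmic", "eig_rhythmic")) {
    flags <- scan[[crit]]
    for (i in seq_len(nrow(scan) - 1)) {
      if (is.na(flags[i]) || is.na(flags[i + 1])) next
      if (flags[i] != flags[i + 1]) {
        pt <- bisect(grid[i], grid[i + 1],
                     function(v) {
                       r <- classify(v)
                       isTRUE(r[[crit]])
                     }, flags[i])
        bif[[length(bif) + 1L]] <- data.frame(criterion = crit,
                                              lower = grid[i],
                                              upper = grid[i + 1],
                                              point = pt)
      }
    }
  }
  list(scan = scan,
       bifurcations = if (length(bif)) do.call(rbind, bif)
                      else data.frame(criterion = character(0),
                                      lower = numeric(0),
                                      upper = numeric(0),
                                      point = numeric(0)))
}
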