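#' Classical fixed-step RK4 integration
#'
#' Integrates an arbitrary R-level right-hand side \code{rhs(t, y)} with
#' the classical fourth-order Runge-Kutta scheme on a uniform grid. This
#' generic path is used for small test systems and the bifurcation
#' normal-form checks; the full model goes through the compiled fast path
#' in \code{\link{integrate_model}}.
#'
#' @param rhs function of \code{(t, y)} returning dy/dt.
#' @param y0 initial state.
#' @param t_end final time (h), integration starts at 0.
#' @param dt step size (h), must divide \code{t_end}.
#' @return list with \code{time} and \code{states} (matrix, one row per
#'   grid point).
#' @export
integrate_rk4 <- function(rhs, y0, t_end, dt) {
  if (dt <= 0) stop("dt must be positive")
  n <- round(t_end / dt)
  if (abs(n * dt - t_end) > 1e-8) stop("dt must divide t_end")
  y <- as.numeric(y0)
  out <- matrix(NA_real_, n + 1, length(y))
  out[1, ] <- y
  tgrid <- seq(0, by = dt, length.out = n + 1)
  for (s in seq_len(n)) {
    t <- tgrid[s]
    k1 <- rhs(t, y)
    k2 <- rhs(t + dt / 2, y + dt / 2 * k1)
    k3 <- rhs(t + dt / 2, y + dt / 2 * k2)
    k4 <- rhs(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(y)))
      stop("integration failure: non-finite state at step ", s,
           " (t = ", tgrid[s + 1], ")")
    out[s + 1, ] <- y
  }
  list(time = tgrid, states = out)
}

#' Integrate the full 29-state model under a light protocol
#'
#' Compiled fixed-step RK4 over the whole protocol. Light switches are
#' aligned to the step grid (\code{dt} must divide 1 h), so the scheme
#' never samples a light discontinuity mid-regime.
#'
#' @param params a \code{clock_params}.
#' @param protocol a \code{light_protocol}.
#' @param y0 initial state (default: all states 0.1 except \code{P} 0.5).
#' @param dt step size in hours (default 0.025; must divide 1 h).
#' @param record_every record the state every this many hours (default
#'   \code{dt}, i.e. every step).
#' @param variant Lhcb1 model variant, \code{"extended"} or
#'   \code{"control"}.
#' @return a \code{clock_trajectory}: list with \code{time} (h),
#'   \code{states} (time x 29 matrix with named columns), \code{protocol},
#'   \code{dt}, \code{params}.
#' @export
integrate_model <- function(params, protocol, y0 = default_y0(),
                            dt = 0.025, record_every = dt,
                            variant = c("extended", "control")) {
  variant <- match.arg(variant)
  stopifnot(inherits(params, "clock_params"),
            inherits(protocol, "light_protocol"))
  if (dt <= 0) stop("dt must be positive")
  nper <- round(1 / dt)
  if (abs(nper * dt - 1) > 1e-9)
    stop("dt must divide 1 h so light switches fall on grid points")
  stride <- max(1L, as.integer(round(record_every / dt)))
  res <- .integrate_cpp(as.numeric(y0), as.numeric(params),
                        .protocol_matrix(protocol), 0, protocol$total_h,
                        dt, stride,
                        variant = if (variant == "extended") 0L else 1L)
  states <- res$states
  colnames(states) <- clock_states()
  structure(list(time = res$time, states = states, protocol = protocol,
                 dt = dt, variant = variant, params = params),
            class = "clock_trajectory")
}

#' Default initial conditions
#'
#' All states at 0.1 relative units except the light-sensitive protein
#' \code{P} at 0.5. Burn-in removes any dependence on this choice.
#' @return named numeric vector of length 29.
#' @export
default_y0 <- function() {
  y <- rep(0.1, 29)
  names(y) <- clock_states()
  y["P"] <- 0.5
  y
}

#' @export
print.clock_trajectory <- function(x, ...) {
  cat("<clock_trajectory>", length(x$time), "time points,",
      sprintf("t in [%g, %g] h, dt = %g h\n",
              min(x$time), max(x$time), x$dt))
  invisible(x)
}

#' @export
as.data.frame.clock_trajectory <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(time_h = x$time, x$states, check.names = FALSE)
}

#' Run a named experimental protocol
#'
#' Entrains the model (burn-in, discarded) and returns the trajectory of
#' the treatment window with time 0 at the lights-on of the first
#' treatment day (ZT0).
#'
#' @param params a \code{clock_params}.
#' @param protocol_name \code{"muller_LL"}, \code{"MI_to_LI"},
#'   \code{"MI_to_NI"}, \code{"MI_to_MI"}, or a custom
#'   \code{light_protocol} whose final segment is the treatment.
#' @param burn_in_days extra LD 12:12 cycles at the entrainment intensity
#'   prepended before the protocol's own entrainment segment (default 10).
#' @param dt,record_every,variant passed to \code{\link{integrate_model}}.
#' @param treatment_days treatment window length for named protocols.
#' @return a \code{clock_trajectory} whose time axis starts at 0 = ZT0 of
#'   the treatment.
#' @export
run_protocol <- function(params, protocol_name = "muller_LL",
                         burn_in_days = 10, dt = 0.025,
                         record_every = 0.25, treatment_days = NULL,
                         variant = c("extended", "control")) {
  variant <- match.arg(variant)
  if (inherits(protocol_name, "light_protocol")) {
    proto <- protocol_name
  } else {
    proto <- canonical_protocol(protocol_name,
                                treatment_days = treatment_days)
  }
  segs <- proto$segments[, c("duration_h", "hours_light", "hours_dark",
                             "intensity")]
  if (burn_in_days > 0) {
    # burn-in is entrainment-style LD 12:12 at the first segment's
    # intensity, even when the protocol itself starts in LL
    burn <- ld_segment(24 * burn_in_days, segs$intensity[1])
    segs <- rbind(burn, segs)
  }
  full <- light_protocol(segs)
  traj <- integrate_model(params, full, dt = dt,
                          record_every = record_every, variant = variant)
  # treatment = final segment of the original protocol
  t_treat <- full$total_h - proto$segments$duration_h[nrow(proto$segments)]
  keep <- traj$time >= t_treat - 1e-9
  # snap to the integration grid: cumulative float error must not push
  # t = 0 off the interpolation range
  traj$time <- round((traj$time[keep] - t_treat) / dt) * dt
  traj$states <- traj$states[keep, , drop = FALSE]
  traj$treatment <- proto$segments[nrow(proto$segments), ]
  traj
}

#' Extract one variable's series from a trajectory
#'
#' @param traj a \code{clock_trajectory}.
#' @param var state name (see \code{\link{clock_states}}).
#' @return data.frame with \code{time_h} and \code{value}.
#' @export
trajectory_series <- function(traj, var) {
  stopifnot(inherits(traj, "clock_trajectory"))
  if (!var %in% colnames(traj$states)) stop("unknown variable: ", var)
  data.frame(time_h = traj$time, value = unname(traj$states[, var]))
}

#' Normalize a series
#'
#' \code{"max"} divides by the maximum (peak = 1, the convention used for
#' expression comparisons); \code{"minmax"} maps the range to [0, 1].
#'
#' @param x numeric vector.
#' @param mode \code{"max"} or \code{"minmax"}.
#' @return normalized vector.
#' @export
normalize_series <- function(x, mode = c("max", "minmax")) {
  mode <- match.arg(mode)
  if (mode == "max") {
    m <- max(x)
    if (m <= 0) stop("max-normalization needs a positive maximum")
    x / m
  } else {
    r <- range(x)
    if (diff(r) == 0) stop("minmax-normalization of a constant series")
    (x - r[1]) / diff(r)
  }
}

#' Write a trajectory as long-format CSV
#'
#' Columns \code{time_h, variable, value, condition}; comment header
#' lines (prefixed \code{#}) carry the step size and treatment metadata.
#'
#' @param traj a \code{clock_trajectory}.
#' @param path output path.
#' @param vars variables to write (default: all 29).
#' @param condition condition label stored in the CSV.
#' @param stride write every \code{stride}-th recorded point.
#' @export
write_trajectory_csv <- function(traj, path, vars = clock_states(),
                                 condition = "sim", stride = 1L) {
  stopifnot(inherits(traj, "clock_trajectory"))
  idx <- seq(1, length(traj$time), by = stride)
  long <- do.call(rbind, lapply(vars, function(v)
    data.frame(time_h = traj$time[idx], variable = v,
               value = unname(traj$states[idx, v]),
               condition = condition)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# photoclock trajectory; dt=%g h; variant=%s",
                     traj$dt, traj$variant), con)
  utils::write.csv(long, con, row.names = FALSE)
  invisible(path)
}
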