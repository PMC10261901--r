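#' Extract gas-exchange drivers from a trajectory
#'
#' The Hill output model is driven by CL, GI and the four photosynthetic
#' protein levels; this pulls those six series from a trajectory,
#' optionally interpolated onto a requested time grid.
#'
#' @param traj a \code{clock_trajectory}.
#' @param at optional time grid (h) to interpolate onto.
#' @return data.frame with columns \code{time_h}, \code{CL}, \code{GI},
#'   \code{Lhcb1}, \code{psbA}, \code{RbcS1}, \code{atpA}.
#' @export
photo_drivers <- function(traj, at = NULL) {
  stopifnot(inherits(traj, "clock_trajectory"))
  vars <- c("CL", "GI", "Lhcb1", "psbA", "RbcS1", "atpA")
  out <- data.frame(time_h = traj$time)
  for (v in vars) out[[v]] <- unname(traj$states[, v])
  if (!is.null(at)) {
    out <- data.frame(time_h = at,
                      lapply(out[vars], function(x)
                        stats::approx(traj$time, x, xout = at,
                                      rule = 2)$y))
    names(out) <- c("time_h", vars)
  }
  out
}

.eval_photo <- function(drivers, coef) {
  photosynthetic_parameter(drivers$CL, drivers$GI,
                           as.matrix(drivers[, c("Lhcb1", "psbA",
                                                 "RbcS1", "atpA")]),
                           coef)
}

#' Fit the gas-exchange Hill output model
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \code{minpack.lm::nlsLM}) of the photosynthetic-parameter equation to
#' observed diurnal gas-exchange values, with the clock/protein drivers
#' taken from a simulated trajectory and interpolated onto the observed
#' time grid. Multi-start: \code{n_starts} seeded random initialisations
#' within the bounds, keeping the lowest residual sum of squares, to
#' avoid local minima in the Hill thresholds. Fit one condition at a
#' time.
#'
#' @param observations data.frame with columns \code{time_h},
#'   \code{value} (one gas-exchange parameter, one condition; replicate
#'   values may repeat time points).
#' @param drivers data.frame from \code{\link{photo_drivers}} (any time
#'   grid covering the observations).
#' @param n_starts number of random starts (default 5).
#' @param seed RNG seed for the starts.
#' @param lower,upper coefficient bounds (named like
#'   \code{unlist(photo_coef(...))}).
#' @return a \code{photo_coef} with attributes \code{rss} and
#'   \code{converged}.
#' @export
fit_photoparams <- function(observations, drivers, n_starts = 5,
                            seed = 1, lower = NULL, upper = NULL) {
  stopifnot(all(c("time_h", "value") %in% names(observations)))
  n_coef <- 8L
  if (nrow(observations) < n_coef + 1)
    stop("underdetermined fit: fewer observations than free coefficients")
  # interpolate drivers at observed times
  at <- observations$time_h
  D <- data.frame(time_h = at)
  for (v in c("CL", "GI", "Lhcb1", "psbA", "RbcS1", "atpA"))
    D[[v]] <- stats::approx(drivers$time_h, drivers[[v]], xout = at,
                            rule = 2)$y
  y <- observations$value
  scale_y <- max(abs(y))
  lower <- lower %||% c(alpha = 1e-6, K1 = 1e-3, K2 = 1e-3, K3 = 1e-4,
                        H_Lhcb1 = 1e-3, H_psbA = 1e-3, H_RbcS1 = 1e-3,
                        H_atpA = 1e-3)
  upper <- upper %||% c(alpha = 2 * scale_y + 1e-6,
                        K1 = 20, K2 = 20, K3 = 50 * scale_y + 1,
                        H_Lhcb1 = 20, H_psbA = 20, H_RbcS1 = 20,
                        H_atpA = 20)
  if (stats::sd(y) < 1e-10 * max(abs(y), 1)) {
    # degenerate input: flat observations collapse to the basal rate
    # with the Hill amplitude at its lower boundary
    out <- photo_coef(mean(y), K1 = 1, K2 = 1, K3 = lower[["K3"]],
                      H = rep(1, 4))
    attr(out, "rss") <- sum((y - mean(y))^2)
    attr(out, "converged") <- TRUE
    return(out)
  }
  model <- function(p) {
    cf <- photo_coef(p[["alpha"]], p[["K1"]], p[["K2"]], p[["K3"]],
                     p[c("H_Lhcb1", "H_psbA", "H_RbcS1", "H_atpA")])
    .eval_photo(D, cf)
  }
  set.seed(seed)
  best <- NULL; best_rss <- Inf
  starts <- vector("list", n_starts)
  # first start: data-informed; remaining: log-uniform in the box
  starts[[1]] <- c(alpha = max(min(y), lower[["alpha"]]),
                   K1 = stats::median(D$CL) + 0.01,
                   K2 = stats::median(D$GI) + 0.01,
                   K3 = sqrt(max(diff(range(y)), 1e-3)) *
                     (stats::median(D$GI) + 0.1),
                   H_Lhcb1 = stats::median(D$Lhcb1) + 0.01,
                   H_psbA = stats::median(D$psbA) + 0.01,
                   H_RbcS1 = stats::median(D$RbcS1) + 0.01,
                   H_atpA = stats::median(D$atpA) + 0.01)
  # remaining starts: lognormal jitter around the informed start (wide
  # box-uniform draws land in zero-gradient plateaus of the Hill terms)
  for (s in seq_len(n_starts - 1) + 1)
    starts[[s]] <- starts[[1]] *
      stats::rlnorm(n_coef, 0, 0.6)
  resid_fn <- function(par) y - model(par)
  for (s in seq_len(n_starts)) {
    st <- pmin(pmax(starts[[s]], lower), upper)
    fit <- try(minpack.lm::nls.lm(
      par = st, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500,
                                           ftol = 1e-12, ptol = 1e-12)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- fit$deviance
    if (rss < best_rss) { best <- fit; best_rss <- rss }
  }
  if (is.null(best)) stop("all nonlinear least-squares starts failed")
  p <- best$par
  out <- photo_coef(p[["alpha"]], p[["K1"]], p[["K2"]], p[["K3"]],
                    p[c("H_Lhcb1", "H_psbA", "H_RbcS1", "H_atpA")])
  attr(out, "rss") <- best_rss
  attr(out, "converged") <- TRUE
  out
}
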