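#' Noise specification for synthetic measurements
#'
#' Multiplicative lognormal noise emulating relative-quantification
#' (2^-ddCt-style) replicate scatter: strictly positive, spread
#' proportional to the level. The lognormal is mean-1 parameterised
#' (\code{meanlog = -sigma^2/2}).
#'
#' @param sigma lognormal sigma (default 0.1, a typical qPCR replicate
#'   CV).
#' @param replicates biological replicates per time point (default 3).
#' @param seed RNG seed.
#' @return object of class \code{noise_spec}.
#' @export
noise_spec <- function(sigma = 0.1, replicates = 3, seed = 1) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (replicates < 1) stop("need at least one replicate")
  structure(list(sigma = sigma, replicates = as.integer(replicates),
                 seed = as.integer(seed)), class = "noise_spec")
}

#' Default qPCR sampling grid
#'
#' Every 2 h through the first treatment cycle and every 4 h through the
#' second, 0 h (ZT0 of treatment day 1) as the first sample.
#' @return numeric vector of ZT hours.
#' @export
qpcr_sampling_grid <- function() c(seq(0, 22, by = 2), seq(24, 48, by = 4))

#' Generate synthetic RT-qPCR-style expression series
#'
#' Simulates the truth trajectory under a protocol, samples the gene
#' mRNAs on the qPCR grid, applies i.i.d. mean-1 lognormal multiplicative
#' noise per replicate, and max-normalizes per gene so the replicate-mean
#' curve peaks at 1. Deterministic given the seed.
#'
#' @param params truth \code{clock_params}.
#' @param condition protocol name (or a \code{light_protocol}).
#' @param genes gene labels (default: the six clock genes).
#' @param sampling sampling times (ZT h of the treatment window).
#' @param noise a \code{noise_spec}.
#' @param dt,burn_in_days simulation settings.
#' @return \code{expression_series}: long data.frame (\code{time_h},
#'   \code{gene}, \code{replicate}, \code{condition}, \code{value}) with
#'   the truth parameters attached as attribute \code{truth}.
#' @export
generate_qpcr <- function(params, condition = "MI_to_LI",
                          genes = c("CL", "P97", "P51", "EL", "GI",
                                    "RVE8"),
                          sampling = qpcr_sampling_grid(),
                          noise = noise_spec(), dt = 0.05,
                          burn_in_days = 10) {
  if (length(genes) == 0) stop("empty gene list")
  bad <- setdiff(genes, names(.gene_mrna))
  if (length(bad)) stop("unknown genes: ", paste(bad, collapse = ", "))
  stopifnot(inherits(noise, "noise_spec"))
  cond_label <- if (inherits(condition, "light_protocol")) "custom"
                else condition
  traj <- run_protocol(params, condition, burn_in_days = burn_in_days,
                       dt = dt)
  if (max(sampling) > max(traj$time))
    stop("sampling grid extends past the treatment window")
  set.seed(noise$seed)
  out <- list()
  for (g in genes) {
    s <- trajectory_series(traj, .gene_mrna[[g]])
    truth <- stats::approx(s$time_h, s$value, xout = sampling)$y
    reps <- matrix(truth, nrow = length(sampling),
                   ncol = noise$replicates)
    if (noise$sigma > 0) {
      eps <- matrix(stats::rlnorm(length(reps),
                                  meanlog = -noise$sigma^2 / 2,
                                  sdlog = noise$sigma),
                    nrow = nrow(reps))
      reps <- reps * eps
    }
    scale <- max(rowMeans(reps))
    reps <- reps / scale
    for (r in seq_len(noise$replicates))
      out[[length(out) + 1L]] <- data.frame(
        time_h = sampling, gene = g, replicate = r,
        condition = cond_label, value = reps[, r])
  }
  res <- do.call(rbind, out)
  attr(res, "truth") <- params
  class(res) <- c("expression_series", class(res))
  res
}

#' Units of the four gas-exchange parameters
#' @export
gas_exchange_units <- function() {
  c(Pn = "umol CO2 m-2 s-1", Gs = "mol m-2 s-1",
    Ci = "umol mol-1", Tr = "mmol m-2 s-1")
}

#' Generate synthetic diurnal gas-exchange measurements
#'
#' Evaluates the Hill output model on the drivers of a simulated
#' trajectory at the sampling times, applies mean-1 lognormal replicate
#' noise, and returns the long gas-exchange table.
#'
#' @param coefs named list of \code{photo_coef}s, one per parameter
#'   (names among \code{Pn}, \code{Gs}, \code{Ci}, \code{Tr}).
#' @param traj \code{clock_trajectory} covering the sampling day.
#' @param sampling sampling times (default every 2 h over 24 h).
#' @param noise a \code{noise_spec}.
#' @param condition condition label for the output table.
#' @return long data.frame (\code{time_h}, \code{condition},
#'   \code{parameter}, \code{replicate}, \code{value}, \code{units}).
#' @export
generate_gas_exchange <- function(coefs, traj,
                                  sampling = seq(0, 24, by = 2),
                                  noise = noise_spec(),
                                  condition = "LI") {
  stopifnot(inherits(noise, "noise_spec"))
  units <- gas_exchange_units()
  if (!all(names(coefs) %in% names(units)))
    stop("coefficient names must be among Pn, Gs, Ci, Tr")
  if (max(sampling) > max(traj$time))
    stop("trajectory does not cover the sampling day")
  need <- c("CL", "GI", "Lhcb1", "psbA", "RbcS1", "atpA")
  if (!all(need %in% colnames(traj$states)))
    stop("missing driver variable(s): ",
         paste(setdiff(need, colnames(traj$states)), collapse = ", "))
  D <- photo_drivers(traj, at = sampling)
  set.seed(noise$seed)
  out <- list()
  for (pm in names(coefs)) {
    truth <- .eval_photo(D, coefs[[pm]])
    for (r in seq_len(noise$replicates)) {
      v <- truth
      if (noise$sigma > 0)
        v <- v * stats::rlnorm(length(v), -noise$sigma^2 / 2,
                               noise$sigma)
      out[[length(out) + 1L]] <- data.frame(
        time_h = sampling, condition = condition, parameter = pm,
        replicate = r, value = v, units = unname(units[pm]))
    }
  }
  do.call(rbind, out)
}
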