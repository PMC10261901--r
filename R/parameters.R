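#' Construct a model parameter set
#'
#' A \code{clock_params} object is a named numeric vector over the full
#' 100-parameter registry (see \code{\link{param_registry}}), carrying
#' bounds and the free/fixed mask as attributes. Values must be complete:
#' every registry name present exactly once.
#'
#' @param values named numeric vector of length 100 covering
#'   \code{param_names()}.
#' @param free optional character vector of free parameter names; defaults
#'   to the registry's free mask.
#' @return object of class \code{clock_params}.
#' @export
clock_params <- function(values, free = NULL) {
  reg <- param_registry()
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop("parameter values must be uniquely named")
  missing <- setdiff(reg$name, names(values))
  extra <- setdiff(names(values), reg$name)
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "))
  if (length(extra))
    stop("unknown parameters: ", paste(extra, collapse = ", "))
  v <- as.numeric(values[reg$name])
  names(v) <- reg$name
  if (anyNA(v) || any(!is.finite(v)))
    stop("parameter values must be finite and non-missing")
  if (any(v < 0)) stop("all rates and thresholds must be >= 0")
  if (v["hill"] < 1) stop("Hill exponent must be >= 1")
  if (is.null(free)) free <- reg$name[reg$free]
  if (length(bad <- setdiff(free, reg$name)))
    stop("unknown free parameters: ", paste(bad, collapse = ", "))
  structure(v, class = "clock_params",
            lower = stats::setNames(reg$lower, reg$name),
            upper = stats::setNames(reg$upper, reg$name),
            free = free)
}

#' @export
print.clock_params <- function(x, ...) {
  cat("<clock_params> 100 parameters,", length(attr(x, "free")),
      "free\n")
  utils::str(stats::setNames(as.numeric(x), names(x)), vec.len = 6)
  invisible(x)
}

#' Replace parameter values
#'
#' @param params a \code{clock_params} object.
#' @param ... name = value pairs to replace.
#' @return modified \code{clock_params}.
#' @export
set_params <- function(params, ...) {
  stopifnot(inherits(params, "clock_params"))
  upd <- c(...)
  if (length(upd) == 0) return(params)
  if (is.null(names(upd)) || any(names(upd) == ""))
    stop("replacements must be named")
  v <- stats::setNames(as.numeric(params), names(params))
  bad <- setdiff(names(upd), names(v))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  v[names(upd)] <- upd
  clock_params(v, free = attr(params, "free"))
}

#' The calibrated default parameter set
#'
#' Reads the parameter file shipped with the package. The set was produced
#' by the package's own simulated-annealing calibration under the rhythm
#' constraints the model is built around (free-running period in 24-28 h,
#' the six LL peak-time windows, Aschoff ordering of periods across light
#' intensities); see the methods vignette.
#'
#' @return a \code{clock_params} object.
#' @export
default_params <- function() {
  path <- system.file("extdata", "clock_params.txt", package = "photoclock")
  if (path == "") stop("calibrated parameter file not found")
  read_params(path)
}

#' Read a parameter file
#'
#' Flat whitespace-separated text with columns \code{name value lower
#' upper unit free}; lines starting with \code{#} are comments. Bounds,
#' unit and free flag are optional — registry defaults are used when a
#' column is absent.
#'
#' @param path file path.
#' @return a \code{clock_params} object.
#' @export
read_params <- function(path) {
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("name", "value") %in% names(tab)))
    stop("parameter file needs 'name' and 'value' columns")
  free <- if ("free" %in% names(tab)) tab$name[as.logical(tab$free)] else NULL
  clock_params(stats::setNames(tab$value, tab$name), free = free)
}

#' Write a parameter file
#'
#' @param params a \code{clock_params} object.
#' @param path output path.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "clock_params"))
  reg <- param_registry()
  tab <- data.frame(name = reg$name,
                    value = as.numeric(params),
                    lower = reg$lower, upper = reg$upper,
                    unit = reg$unit,
                    free = reg$name %in% attr(params, "free"))
  utils::write.table(tab, path, quote = c(1L, 5L), row.names = FALSE)
  invisible(path)
}

#' Light-intensity scaling function
#'
#' Evaluates \code{f(I) = I / (I_A*I^2 + I_B*I + I_C)}, the dimensionless
#' factor by which light intensity \code{I} (umol m-2 s-1) scales the
#' light-gated terms of the model. The neutral setting
#' \code{(I_A = 0, I_B = 1, I_C = 0)} gives \code{f = 1} at every
#' intensity. The shipped calibration solves \code{f(100) = 1},
#' \code{f(62.5) = 0.8} with \code{I_A = 0}, which places \code{f(187.5)}
#' at 1.24 and keeps \code{f} strictly increasing in \code{I}.
#'
#' @param I light intensity, umol m-2 s-1 (vectorised).
#' @param constants numeric with names \code{I_A}, \code{I_B}, \code{I_C},
#'   or a \code{clock_params} object.
#' @return dimensionless scale factor(s).
#' @export
intensity_scale <- function(I, constants) {
  if (inherits(constants, "clock_params"))
    constants <- as.numeric(constants[c("I_A", "I_B", "I_C")]) |>
      stats::setNames(c("I_A", "I_B", "I_C"))
  a <- constants[["I_A"]]; b <- constants[["I_B"]]; cc <- constants[["I_C"]]
  den <- a * I^2 + b * I + cc
  if (any(den <= 0 & I > 0)) stop("light function denominator must be positive")
  # I = 0 with I_C = 0 (e.g. the neutral setting): use the I -> 0 limit 1/I_B
  out <- ifelse(I == 0 & cc == 0, 1 / b,
                ifelse(I == 0, 0, I / den))
  out
}
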