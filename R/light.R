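#' Light protocols
#'
#' A \code{light_protocol} is an ordered list of segments, each with a
#' duration (h), a photoperiod (\code{hours_light}:\code{hours_dark},
#' with lights-on at segment-local time 0; \code{hours_dark = 0} means
#' constant light), and an intensity (umol m-2 s-1). Zeitgeber time is
#' counted from lights-on.
#'
#' Canonical protocols:
#' \describe{
#'   \item{\code{muller_LL}}{entrain 5 d LD 12:12 at 100, then constant
#'     light at 100 (the free-run design of the calibration data).}
#'   \item{\code{MI_to_LI}}{entrain LD 12:12 at 100, then 48 h LD 12:12 at
#'     low intensity 62.5.}
#'   \item{\code{MI_to_NI}}{entrain LD 12:12 at 100, then 48 h LD 12:12 at
#'     normal intensity 187.5.}
#'   \item{\code{MI_to_MI}}{entrain LD 12:12 at 100, then 48 h LD 12:12 at
#'     100 (the continuation control).}
#' }
#'
#' @param segments data.frame with columns \code{duration_h},
#'   \code{hours_light}, \code{hours_dark}, \code{intensity}.
#' @return object of class \code{light_protocol}.
#' @export
light_protocol <- function(segments) {
  need <- c("duration_h", "hours_light", "hours_dark", "intensity")
  if (!all(need %in% names(segments)))
    stop("segments need columns: ", paste(need, collapse = ", "))
  segments <- segments[, need]
  if (nrow(segments) == 0) stop("protocol needs at least one segment")
  if (any(segments$duration_h <= 0)) stop("segment durations must be > 0")
  if (any(segments$intensity < 0)) stop("intensities must be >= 0")
  if (any(segments$hours_light <= 0)) stop("hours_light must be > 0")
  if (any(segments$hours_dark < 0)) stop("hours_dark must be >= 0")
  t1 <- cumsum(segments$duration_h)
  segments$t0 <- c(0, t1[-length(t1)])
  segments$t1 <- t1
  structure(list(segments = segments, total_h = t1[length(t1)]),
            class = "light_protocol")
}

#' @export
print.light_protocol <- function(x, ...) {
  cat("<light_protocol>", nrow(x$segments), "segment(s),",
      x$total_h, "h total\n")
  for (i in seq_len(nrow(x$segments))) {
    s <- x$segments[i, ]
    mode <- if (s$hours_dark == 0) "LL"
            else sprintf("LD %g:%g", s$hours_light, s$hours_dark)
    cat(sprintf("  [%g, %g) h  %s  at %g umol m-2 s-1\n",
                s$t0, s$t1, mode, s$intensity))
  }
  invisible(x)
}

#' Convenience segment constructors
#' @param duration_h segment duration in hours.
#' @param intensity light intensity, umol m-2 s-1.
#' @param hours_light,hours_dark photoperiod split, lights-on first.
#' @return one-row segment data.frame for \code{\link{light_protocol}}.
#' @export
ld_segment <- function(duration_h, intensity, hours_light = 12,
                       hours_dark = 12) {
  data.frame(duration_h = duration_h, hours_light = hours_light,
             hours_dark = hours_dark, intensity = intensity)
}

#' @rdname ld_segment
#' @export
ll_segment <- function(duration_h, intensity) {
  data.frame(duration_h = duration_h, hours_light = 24, hours_dark = 0,
             intensity = intensity)
}

#' Canonical experimental protocols
#'
#' @param name one of \code{"muller_LL"}, \code{"MI_to_LI"},
#'   \code{"MI_to_NI"}, \code{"MI_to_MI"}.
#' @param entrain_days days of LD 12:12 entrainment before the treatment
#'   segment (default 5, as in the designs the model is built on; the
#'   simulation engine usually adds extra burn-in on top).
#' @param entrain_intensity entrainment intensity (default 100).
#' @param treatment_days length of the treatment window in days.
#' @return a \code{light_protocol}.
#' @export
canonical_protocol <- function(name = c("muller_LL", "MI_to_LI",
                                        "MI_to_NI", "MI_to_MI"),
                               entrain_days = 5, entrain_intensity = 100,
                               treatment_days = NULL) {
  name <- match.arg(name)
  ent <- ld_segment(24 * entrain_days, entrain_intensity)
  treat <- switch(name,
    muller_LL = ll_segment(24 * (treatment_days %||% 5), entrain_intensity),
    MI_to_LI  = ld_segment(24 * (treatment_days %||% 2), 62.5),
    MI_to_NI  = ld_segment(24 * (treatment_days %||% 2), 187.5),
    MI_to_MI  = ld_segment(24 * (treatment_days %||% 2), entrain_intensity))
  light_protocol(rbind(ent, treat))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.protocol_matrix <- function(protocol) {
  s <- protocol$segments
  as.matrix(s[, c("t0", "t1", "hours_light", "hours_dark", "intensity")])
}

#' Light state at a time point
#'
#' Returns the light flag \code{L}, dark flag \code{D} (\code{L + D = 1};
#' 1 means lights on / off respectively) and the active segment's
#' intensity \code{I} at time \code{t}. The gate is right-continuous:
#' at a switch instant the new regime applies.
#'
#' @param t time in hours from the protocol start (vectorised).
#' @param protocol a \code{light_protocol}.
#' @return data.frame with columns \code{t}, \code{L}, \code{D}, \code{I}.
#' @export
light_gate <- function(t, protocol) {
  stopifnot(inherits(protocol, "light_protocol"))
  if (any(t < 0 | t > protocol$total_h))
    stop("t outside the protocol's total duration")
  m <- .protocol_matrix(protocol)
  out <- t(vapply(t, function(ti) .light_gate_cpp(ti, m), numeric(3)))
  data.frame(t = t, L = out[, 1], D = out[, 2], I = out[, 3])
}
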