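#' Piecewise-cosine boundary waveform
#'
#' Container for the pulsatile boundary signals used at the aortic inlet and
#' outlets. Each segment is \eqn{A \cos(\omega (t - t_s) + \phi) + C} on a
#' half-open interval \eqn{(t_0, t_1]}; the intervals partition one cardiac
#' cycle \eqn{(0, T]} with \eqn{T = 1} s, and evaluation at any time wraps
#' periodically via \code{t mod T}.
#'
#' @param segments data.frame with columns \code{amplitude}, \code{omega}
#'   (rad/s), \code{tshift} (s), \code{phase} (rad), \code{offset},
#'   \code{t0}, \code{t1} (s).
#' @param period cycle length in seconds (1.0 for the cardiac cycle used here).
#' @param units signal units: \code{"m/s"}, \code{"mmHg"} or \code{"Pa"}.
#' @return object of class \code{pc_waveform}.
#' @export
pc_waveform <- function(segments, period = 1.0, units = c("m/s", "mmHg", "Pa")) {
  units <- match.arg(units)
  need <- c("amplitude", "omega", "tshift", "phase", "offset", "t0", "t1")
  stopifnot(is.data.frame(segments), all(need %in% names(segments)))
  segments <- segments[order(segments$t0), , drop = FALSE]
  if (abs(segments$t0[1]) > 1e-12 || abs(segments$t1[nrow(segments)] - period) > 1e-12)
    stop("segments must partition (0, period]")
  if (nrow(segments) > 1 &&
      any(abs(segments$t1[-nrow(segments)] - segments$t0[-1]) > 1e-12))
    stop("segment intervals must be contiguous")
  structure(list(segments = segments, period = period, units = units),
            class = "pc_waveform")
}

#' Evaluate a waveform
#'
#' @param w a [pc_waveform()].
#' @param t time(s) in seconds, any non-negative values; evaluation is periodic.
#' @return numeric vector of signal values in \code{w$units}.
#' @export
wf_eval <- function(w, t) {
  stopifnot(inherits(w, "pc_waveform"), all(t >= 0 | abs(t) < 1e-12))
  tm <- t %% w$period
  # the cycle is the half-open interval (0, T]: t = 0 maps to T
  tm[tm < 1e-14] <- w$period
  seg <- w$segments
  idx <- findInterval(tm, seg$t0, left.open = TRUE)   # t in (t0_i, t1_i]
  idx <- pmin(pmax(idx, 1L), nrow(seg))
  s <- seg[idx, , drop = FALSE]
  s$amplitude * cos(s$omega * (tm - s$tshift) + s$phase) + s$offset
}

#' Pulsatile inlet-velocity waveform
#'
#' Cross-section mean blood velocity at the ascending-aorta inlet over one
#' cardiac cycle (period 1 s), as a three-piece cosine: systolic acceleration
#' peaking at 1.06 m/s at t = 0.15 s, then two diastolic pieces, continuous at
#' the junctions (t = 0.3 s and 0.6 s) and periodic with v(0) = v(1) =
#' 0.295 m/s. The printed angular coefficients are taken as the exact
#' rationals 20\eqn{\pi}/3 and 10\eqn{\pi}/3 so the junctions close to
#' machine precision.
#'
#' @return a [pc_waveform()] in m/s.
#' @export
inlet_velocity_waveform <- function() {
  pc_waveform(data.frame(
    amplitude = c(-0.3825, -0.1405, -0.1405),
    omega     = c(20 * pi / 3, 10 * pi / 3, 2.5 * pi),
    tshift    = c(0, 0.3, 1.0),
    phase     = c(0, 0, 0),
    offset    = c(0.6775, 0.4355, 0.4355),
    t0        = c(0, 0.3, 0.6),
    t1        = c(0.3, 0.6, 1.0)), units = "m/s")
}

#' Pulsatile outlet-pressure waveform
#'
#' Physiological outlet pressure over one cardiac cycle in mmHg. The systolic
#' piece is \eqn{-25\cos(4\pi t) + 115} on (0, 0.35] (90 mmHg at t = 0+,
#' 140 mmHg at t = 0.25 s). The diastolic piece is the adopted reading
#' \eqn{(p(0.35) - 90)\cos(0.7692\pi(t - 0.35) + \pi - 1.5) + p(0.35)},
#' chosen so the cycle closes periodically (p(1) differs from p(0+) by
#' about 0.1 mmHg); the ~2.3 mmHg jump at t = 0.35 s is a property of the
#' source signal and is reported by [waveform_diagnostics()]. The diastolic
#' reading is a named, swappable policy via \code{diastolic}.
#'
#' @param diastolic interpretation of the diastolic piece; only
#'   \code{"periodic_cosine"} is currently implemented.
#' @return a [pc_waveform()] in mmHg.
#' @export
outlet_pressure_waveform <- function(diastolic = "periodic_cosine") {
  diastolic <- match.arg(diastolic)
  p035 <- -25 * cos(4 * pi * 0.35) + 115
  pc_waveform(data.frame(
    amplitude = c(-25, p035 - 90),
    omega     = c(4 * pi, 0.7692 * pi),
    tshift    = c(0, 0.35),
    phase     = c(0, pi - 1.5),
    offset    = c(115, p035),
    t0        = c(0, 0.35),
    t1        = c(0.35, 1.0)), units = "mmHg")
}

#' Inlet velocity at time t
#'
#' Convenience evaluator for the pulsatile inlet waveform.
#' @param t time in seconds (vectorized, periodic with period 1 s).
#' @return velocity in m/s.
#' @export
inlet_velocity <- function(t) wf_eval(inlet_velocity_waveform(), t)

#' Outlet pressure at time t
#'
#' Convenience evaluator for the pulsatile outlet-pressure waveform.
#' @param t time in seconds (vectorized, periodic with period 1 s).
#' @return pressure in mmHg.
#' @export
outlet_pressure <- function(t) wf_eval(outlet_pressure_waveform(), t)

#' Convert mmHg to Pa
#'
#' @param p pressure in mmHg.
#' @return pressure in Pa (1 mmHg = 133.322 Pa).
#' @export
to_pascals <- function(p) p * 133.322

#' Waveform diagnostics
#'
#' Reports the discontinuity at every internal segment junction, the
#' periodicity gap |w(T) - w(0+)|, and the cycle mean (adaptive quadrature,
#' relative tolerance 1e-8).
#'
#' @param w a [pc_waveform()].
#' @return list with \code{junctions} (data.frame: time, left, right, jump),
#'   \code{period_gap}, \code{cycle_mean}, \code{units}.
#' @export
waveform_diagnostics <- function(w) {
  stopifnot(inherits(w, "pc_waveform"))
  seg <- w$segments
  eval_seg <- function(i, t)
    seg$amplitude[i] * cos(seg$omega[i] * (t - seg$tshift[i]) + seg$phase[i]) + seg$offset[i]
  n <- nrow(seg)
  junc <- NULL
  if (n > 1) {
    tj <- seg$t1[-n]
    left <- vapply(seq_len(n - 1), function(i) eval_seg(i, seg$t1[i]), 0)
    right <- vapply(seq_len(n - 1), function(i) eval_seg(i + 1, seg$t1[i]), 0)
    junc <- data.frame(time = tj, left = left, right = right,
                       jump = abs(left - right))
  } else {
    junc <- data.frame(time = numeric(), left = numeric(), right = numeric(),
                       jump = numeric())
  }
  period_gap <- abs(eval_seg(n, seg$t1[n]) - eval_seg(1, seg$t0[1]))
  mean_val <- sum(vapply(seq_len(n), function(i) {
    stats::integrate(function(t) eval_seg(i, t), seg$t0[i], seg$t1[i],
                     rel.tol = 1e-8)$value
  }, 0)) / w$period
  list(junctions = junc, period_gap = period_gap, cycle_mean = mean_val,
       units = w$units)
}

#' Sample a waveform to a data frame
#'
#' Uniform samples over one cycle, e.g. for CSV export or plotting.
#' @param w a [pc_waveform()].
#' @param n number of samples over one period.
#' @return data.frame with columns \code{t} and \code{value}.
#' @export
wf_sample <- function(w, n = 200) {
  t <- seq(0, w$period, length.out = n + 1)
  data.frame(t = t, value = wf_eval(w, t))
}

#' @export
print.pc_waveform <- function(x, ...) {
  cat("Piecewise-cosine waveform (", x$units, "), period ",
      x$period, " s, ", nrow(x$segments), " segments\n", sep = "")
  d <- waveform_diagnostics(x)
  cat("  cycle mean:", format(d$cycle_mean, digits = 4), x$units, "\n")
  if (nrow(d$junctions))
    cat("  max junction jump:", format(max(d$junctions$jump), digits = 3),
        "; periodicity gap:", format(d$period_gap, digits = 3), "\n")
  invisible(x)
}

#' @export
plot.pc_waveform <- function(x, n = 500, ...) {
  s <- wf_sample(x, n)
  graphics::plot(s$t, s$value, type = "l", xlab = "t (s)",
                 ylab = x$units, ...)
  invisible(x)
}
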