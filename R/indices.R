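#' Wall shear stress field container
#'
#' Time series of tangential viscous traction vectors on wall facets over one
#' cardiac cycle. Created by [compute_wss()] or, for testing the index
#' formulas, by [synthetic_wss_series()].
#'
#' @param traction numeric array \code{nf x d x nt}: traction vector (Pa) per
#'   facet, component, time.
#' @param times snapshot times (s), strictly increasing, covering one period.
#' @param facet_area facet areas (m^2; lengths in planar mode).
#' @param facet_normal \code{nf x d} outward unit normals (optional).
#' @param facet_ids indices of the wall facets in the parent mesh (optional).
#' @param period cycle length (s).
#' @return object of class \code{wall_shear_field}.
#' @export
wall_shear_field <- function(traction, times, facet_area,
                             facet_normal = NULL, facet_ids = NULL,
                             period = 1.0) {
  stopifnot(length(dim(traction)) == 3, dim(traction)[3] == length(times),
            dim(traction)[1] == length(facet_area),
            all(diff(times) > 0))
  structure(list(traction = traction, times = times, facet_area = facet_area,
                 facet_normal = facet_normal,
                 facet_ids = facet_ids %||% seq_len(dim(traction)[1]),
                 period = period),
            class = "wall_shear_field")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.wall_shear_field <- function(x, ...) {
  cat("Wall shear field:", dim(x$traction)[1], "facets,",
      length(x$times), "snapshots over", x$period, "s\n")
  tw <- compute_tawss(x)
  cat("  TAWSS range:", format(range(tw), digits = 3), "Pa\n")
  invisible(x)
}

#' Synthetic wall-shear time series
#'
#' Deterministic traction-series fixtures on a unit wall patch, used to
#' exercise the TAWSS/OSI/RRT formulas against closed forms:
#' \describe{
#'   \item{constant}{\eqn{\tau = (\mathrm{offset}, 0, 0)} at all times.}
#'   \item{reversing}{\eqn{(+A,0,0)} on the first half-period, \eqn{(-A,0,0)}
#'     on the second: fully oscillatory shear (OSI = 0.5).}
#'   \item{offset_sinusoid}{\eqn{(\mathrm{offset} + A\sin(2\pi t/T), 0, 0)}.}
#' }
#'
#' @param kind one of \code{"constant"}, \code{"reversing"},
#'   \code{"offset_sinusoid"}.
#' @param amplitude amplitude A (Pa).
#' @param offset offset (Pa).
#' @param n_timesteps number of equal intervals over one period (>= 4);
#'   samples are taken at the n+1 interval endpoints.
#' @param period cycle length (s).
#' @return a [wall_shear_field()] with a single unit-area facet.
#' @export
synthetic_wss_series <- function(kind = c("constant", "reversing", "offset_sinusoid"),
                                 amplitude = 1, offset = 0,
                                 n_timesteps = 100, period = 1.0) {
  kind <- match.arg(kind)
  stopifnot(n_timesteps >= 4, period > 0)
  t <- seq(0, period, length.out = n_timesteps + 1)
  tx <- switch(kind,
    constant = rep(offset, length(t)),
    # +A on [0, T/2), -A on [T/2, T); the closing sample at t = T repeats the
    # t = 0 value so the periodic trapezoid mean is exactly zero
    reversing = {
      v <- ifelse(t < period / 2 - 1e-14, amplitude, -amplitude)
      v[length(v)] <- v[1]
      v
    },
    offset_sinusoid = offset + amplitude * sin(2 * pi * t / period))
  tr <- array(0, dim = c(1, 3, length(t)))
  tr[1, 1, ] <- tx
  wall_shear_field(tr, times = t, facet_area = 1,
                   facet_normal = matrix(c(0, 0, 1), 1), period = period)
}

# periodic trapezoid weights for sample times covering one cycle.
# If the grid already closes the period (last = first + T) the plain composite
# trapezoid is used; otherwise the last interval wraps around to the first
# sample.
trapezoid_weights <- function(times, period) {
  n <- length(times)
  stopifnot(n >= 2)
  span <- times[n] - times[1]
  dt <- diff(times)
  w <- numeric(n)
  if (abs(span - period) <= 1e-9 * period) {
    w[1] <- dt[1] / 2
    w[n] <- dt[n - 1] / 2
    if (n > 2) w[2:(n - 1)] <- (dt[-1] + dt[-(n - 1)]) / 2
  } else {
    gap <- period - span
    if (gap < 0) stop("snapshot times span more than one period")
    # wrap: interval from last sample back to (first + period)
    w[1] <- dt[1] / 2 + gap / 2
    w[n] <- dt[n - 1] / 2 + gap / 2
    if (n > 2) w[2:(n - 1)] <- (dt[-1] + dt[-(n - 1)]) / 2
  }
  w
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' \deqn{\mathrm{TAWSS} = \tau_{abs} = \frac{1}{T}\int_0^T |\vec\tau_w|\,dt}
#' computed per facet by composite trapezoid over the snapshot grid with
#' periodic closure.
#'
#' @param wss a [wall_shear_field()] covering exactly one period.
#' @return numeric vector, Pa per facet.
#' @export
compute_tawss <- function(wss) {
  stopifnot(inherits(wss, "wall_shear_field"))
  if (length(wss$times) < 2) stop("empty or degenerate traction series")
  w <- trapezoid_weights(wss$times, wss$period)
  mag <- sqrt(apply(wss$traction^2, c(1, 3), sum))  # nf x nt
  as.numeric(mag %*% w) / wss$period
}

#' Magnitude of the time-averaged wall shear vector
#'
#' \deqn{\tau_{mean} = \left|\frac{1}{T}\int_0^T \vec\tau_w\,dt\right|}
#' (vector average first, then magnitude). Always \eqn{\le} TAWSS.
#'
#' @inheritParams compute_tawss
#' @return numeric vector, Pa per facet.
#' @export
compute_mean_shear <- function(wss) {
  stopifnot(inherits(wss, "wall_shear_field"))
  if (length(wss$times) < 2) stop("empty or degenerate traction series")
  w <- trapezoid_weights(wss$times, wss$period)
  d <- dim(wss$traction)
  avg <- sapply(seq_len(d[2]), function(k)
    wss$traction[, k, , drop = FALSE][, 1, ] %*% w)
  avg <- matrix(avg, nrow = d[1]) / wss$period
  sqrt(rowSums(avg^2))
}

#' Oscillatory shear index (OSI)
#'
#' \deqn{\mathrm{OSI} = \frac{1}{2}\left(1 - \frac{\tau_{mean}}{\tau_{abs}}\right)}
#' 0 for unidirectional shear, 0.5 for fully reversing shear. Facets with
#' \eqn{\tau_{abs} < \epsilon} are undefined: OSI is set to 0 there and the
#' count is attached as attribute \code{n_undefined} (with a warning).
#'
#' @param tawss per-facet TAWSS (Pa).
#' @param tau_mean per-facet mean-shear magnitude (Pa).
#' @param eps threshold below which TAWSS is treated as zero (Pa).
#' @return numeric vector in \[0, 0.5\].
#' @export
compute_osi <- function(tawss, tau_mean, eps = 1e-12) {
  stopifnot(length(tawss) == length(tau_mean), all(tawss >= -eps))
  und <- tawss < eps
  osi <- numeric(length(tawss))
  osi[!und] <- 0.5 * (1 - tau_mean[!und] / tawss[!und])
  osi <- pmin(pmax(osi, 0), 0.5)  # clip fp round-off outside [0, 0.5]
  if (any(und)) {
    warning(sum(und), " facet(s) with TAWSS below eps: OSI undefined, set to 0")
    osi[und] <- 0
  }
  attr(osi, "n_undefined") <- sum(und)
  osi
}

#' Relative residence time (RRT)
#'
#' \deqn{\mathrm{RRT} = \frac{1}{\mathrm{TAWSS}\,(1 - 2\,\mathrm{OSI})}}
#' Facets where the denominator falls below \code{eps} (fully reversing flow
#' or vanishing shear) are flagged infinite and reported at the sentinel
#' \code{cap}; the flag is preserved as attribute \code{infinite}.
#'
#' @param tawss per-facet TAWSS (Pa).
#' @param osi per-facet OSI.
#' @param cap sentinel value for flagged-infinite facets (Pa^-1).
#' @param eps denominator threshold (Pa).
#' @return numeric vector, Pa^-1, with logical attribute \code{infinite}.
#' @export
compute_rrt <- function(tawss, osi, cap = 1e6, eps = 1e-12) {
  stopifnot(length(tawss) == length(osi))
  den <- tawss * (1 - 2 * osi)
  inf <- den < eps
  rrt <- numeric(length(den))
  rrt[!inf] <- 1 / den[!inf]
  rrt[inf] <- cap
  rrt <- pmin(rrt, cap)
  attr(rrt, "infinite") <- inf
  rrt
}

#' All WSS-derived index maps for a wall shear field
#'
#' Computes TAWSS, mean-shear magnitude, OSI and RRT per wall facet.
#'
#' @inheritParams compute_tawss
#' @param rrt_cap sentinel for flagged-infinite RRT (Pa^-1).
#' @return object of class \code{index_maps}: list with numeric vectors
#'   \code{tawss}, \code{tau_mean}, \code{osi}, \code{rrt}, logical
#'   \code{rrt_infinite}, \code{facet_area}, \code{facet_ids}.
#' @export
compute_index_maps <- function(wss, rrt_cap = 1e6) {
  tawss <- compute_tawss(wss)
  tau_mean <- compute_mean_shear(wss)
  # guard fp round-off: the time-averaged vector magnitude can exceed the
  # average magnitude only through round-off
  tau_mean <- pmin(tau_mean, tawss)
  osi <- suppressWarnings(compute_osi(tawss, tau_mean))
  rrt <- compute_rrt(tawss, osi, cap = rrt_cap)
  structure(list(tawss = tawss, tau_mean = tau_mean,
                 osi = as.numeric(osi), rrt = as.numeric(rrt),
                 rrt_infinite = attr(rrt, "infinite"),
                 osi_undefined = attr(osi, "n_undefined"),
                 facet_area = wss$facet_area, facet_ids = wss$facet_ids),
            class = "index_maps")
}

#' @export
print.index_maps <- function(x, ...) {
  cat("Hemodynamic index maps over", length(x$tawss), "wall facets\n")
  f <- function(v) paste(format(range(v), digits = 3), collapse = " .. ")
  cat("  TAWSS (Pa):   ", f(x$tawss), "\n")
  cat("  OSI:          ", f(x$osi), "\n")
  cat("  RRT (1/Pa):   ", f(x$rrt),
      if (any(x$rrt_infinite)) paste0(" [", sum(x$rrt_infinite), " flagged infinite]"),
      "\n", sep = "")
  invisible(x)
}

#' Classify atherosclerosis-risk regions
#'
#' Applies the risk thresholds (low TAWSS < 0.4 Pa, high OSI > 0.25, high
#' RRT > 5 Pa^-1; strict inequalities) to wall facets and reports masked
#' areas, both absolute and as a fraction of the wall. Facets flagged
#' RRT-infinite count as exceeding the RRT threshold. When a mesh is
#' supplied, flow-extension surfaces are excluded (they are numerical
#' artifacts) and a per-anatomical-region breakdown is added.
#'
#' @param maps an [compute_index_maps()] result.
#' @param mesh optional [labeled_mesh()] the maps were computed on.
#' @param thresholds named numeric vector: \code{tawss_low}, \code{osi_high},
#'   \code{rrt_high} (all positive).
#' @return object of class \code{risk_region_report}: list with
#'   \code{summary} data.frame (criterion, area_cm2, fraction),
#'   \code{by_region} data.frame (criterion, region, area_cm2), the three
#'   facet \code{masks}, and the wall area used as denominator.
#' @export
classify_risk_regions <- function(maps, mesh = NULL,
                                  thresholds = c(tawss_low = 0.4,
                                                 osi_high = 0.25,
                                                 rrt_high = 5)) {
  stopifnot(inherits(maps, "index_maps"), all(thresholds > 0))
  keep <- rep(TRUE, length(maps$tawss))
  region <- rep("wall", length(maps$tawss))
  if (!is.null(mesh)) {
    fr <- mesh$facet_region[maps$facet_ids]
    ext <- mesh$facet_extension[maps$facet_ids]
    keep <- !ext
    region <- fr
  }
  area <- maps$facet_area
  wall_area <- sum(area[keep])
  masks <- list(
    tawss_low = keep & maps$tawss < thresholds[["tawss_low"]],
    osi_high  = keep & maps$osi > thresholds[["osi_high"]],
    rrt_high  = keep & (maps$rrt > thresholds[["rrt_high"]] | maps$rrt_infinite))
  summ <- data.frame(
    criterion = names(masks),
    threshold = as.numeric(thresholds[c("tawss_low", "osi_high", "rrt_high")]),
    area_cm2 = vapply(masks, function(m) sum(area[m]) * 1e4, 0),
    fraction = vapply(masks, function(m)
      if (wall_area > 0) sum(area[m]) / wall_area else 0, 0),
    row.names = NULL)
  by_region <- do.call(rbind, lapply(names(masks), function(cr) {
    m <- masks[[cr]]
    regs <- sort(unique(region[keep]))
    data.frame(criterion = cr, region = regs,
               area_cm2 = vapply(regs, function(r)
                 sum(area[m & region == r]) * 1e4, 0),
               row.names = NULL)
  }))
  structure(list(summary = summ, by_region = by_region, masks = masks,
                 wall_area_cm2 = wall_area * 1e4, thresholds = thresholds),
            class = "risk_region_report")
}

#' @export
print.risk_region_report <- function(x, ...) {
  cat("Risk-region report (wall area ", format(x$wall_area_cm2, digits = 4),
      " cm^2)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
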