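#' Per-outlet perfusion summary
#'
#' Cycle-averaged volumetric flow through every outlet, by surface
#' integration of \eqn{u \cdot n} over the tagged facets (outward positive)
#' and composite trapezoid in time over the stored cycle. An outlet tag that
#' is absent from the mesh (e.g. the occluded LSA) is reported with zero
#' flow and a note, not an error.
#'
#' @param field a [flow_field()] covering one cycle.
#' @param mesh the [labeled_mesh()].
#' @param outlets outlet names to report; defaults to the tags present plus
#'   any listed in \code{expected}.
#' @param expected outlet names that should appear even when absent from the
#'   mesh.
#' @return object of class \code{perfusion_summary}: data.frame with columns
#'   \code{outlet}, \code{mean_flow} (m^3/s; per-unit-depth m^2/s in planar
#'   mode), \code{mean_flow_ml_min}, \code{fraction} (of inlet mean flow),
#'   \code{present}; attribute \code{inlet_mean_flow}.
#' @export
outlet_flow_rates <- function(field, mesh, outlets = NULL,
                              expected = character()) {
  stopifnot(inherits(field, "flow_field"))
  present_tags <- unique(mesh$facet_tag[startsWith(mesh$facet_tag, "outlet:")])
  present <- sub("^outlet:", "", present_tags)
  outlets <- outlets %||% union(present, expected)
  nt <- length(field$times)
  w <- if (nt > 1) trapezoid_weights(field$times, field$period) else 1
  Tspan <- if (nt > 1) field$period else 1
  flux_tag <- function(sel) {
    if (!any(sel)) return(0)
    phi <- vapply(seq_len(nt), function(k) {
      Uk <- matrix(field$U[, , k], nrow = dim(field$U)[1], ncol = field$dim)
      facet_flux(mesh, Uk, sel)
    }, 0)
    sum(phi * w) / Tspan
  }
  inlet_mean <- -flux_tag(mesh$facet_tag == "inlet")
  rows <- lapply(outlets, function(o) {
    sel <- mesh$facet_tag == paste0("outlet:", o)
    data.frame(outlet = o, mean_flow = flux_tag(sel),
               present = any(sel))
  })
  df <- do.call(rbind, rows)
  df$mean_flow_ml_min <- df$mean_flow * 6e7
  df$fraction <- if (abs(inlet_mean) > 0) df$mean_flow / inlet_mean else NA_real_
  df <- df[, c("outlet", "mean_flow", "mean_flow_ml_min", "fraction", "present")]
  structure(df, class = c("perfusion_summary", "data.frame"),
            inlet_mean_flow = inlet_mean)
}

#' @export
print.perfusion_summary <- function(x, ...) {
  cat("Perfusion summary (inlet mean flow ",
      format(attr(x, "inlet_mean_flow") * 6e7, digits = 4), " mL/min",
      ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  if (any(!x$present))
    cat("note: absent outlet(s) reported as zero flow: ",
        paste(x$outlet[!x$present], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Trunk centerline of an arch case
#'
#' Samples the analytic trunk centerline (ascending segment, arch, descending
#' segment; branches and flow extensions excluded) and attaches cumulative
#' arc length and the discrete curvature-radius profile.
#'
#' @param spec an [arch_case_spec()].
#' @param n number of samples (>= 200).
#' @return object of class \code{centerline_path}: list with \code{points}
#'   (n x 2), \code{s} (arc length), \code{arc_coord} (trunk arc-length
#'   coordinate), \code{curvature_radius} (m, \code{Inf} where the path is
#'   locally straight), and \code{segment} labels.
#' @export
extract_centerline <- function(spec, n = 256) {
  stopifnot(inherits(spec, "arch_case_spec"), n >= 200)
  s <- seq(0, trunk_length(spec), length.out = n)
  fr <- trunk_frame(spec, s)
  seg <- rep("ascending", n)
  seg[s > spec$ascending_length] <- "arch"
  seg[s > spec$ascending_length + arch_span(spec)] <- "descending"
  arclen <- c(0, cumsum(sqrt(rowSums(diff(fr$point)^2))))
  cr <- curvature_radius_profile(fr$point)
  structure(list(points = fr$point, s = arclen, arc_coord = s,
                 curvature_radius = cr, segment = seg,
                 case_label = spec$case_label),
            class = "centerline_path")
}

#' @export
print.centerline_path <- function(x, ...) {
  cat("Centerline path '", x$case_label %||% "", "': ", nrow(x$points),
      " points, length ", format(max(x$s), digits = 4), " m\n", sep = "")
  fin <- is.finite(x$curvature_radius)
  if (any(fin))
    cat("  min curvature radius:",
        format(min(x$curvature_radius[fin]) * 1e3, digits = 4), "mm\n")
  invisible(x)
}

#' @export
plot.centerline_path <- function(x, ...) {
  graphics::plot(x$points[, 1], x$points[, 2], type = "l", asp = 1,
                 xlab = "x (m)", ylab = "y (m)", ...)
  invisible(x)
}

#' Discrete curvature-radius profile of a polyline
#'
#' Curvature by the circumscribed circle of sliding point triples
#' \code{(i - h, i, i + h)} with \code{h = floor(window/2)}; exact on points
#' sampled from a circle and invariant to rigid motions. Collinear triples
#' give an infinite radius (flagged, not an error); endpoints are NA.
#'
#' @param points n x 2 or n x 3 matrix of path points (n >= 3).
#' @param window arc-length smoothing window in samples (default 5).
#' @return numeric vector of curvature radii (m), NA at the ends.
#' @export
curvature_radius_profile <- function(points, window = 5) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(n >= 3)
  h <- max(1L, floor(window / 2))
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - h < 1 || i + h > n) next
    A <- points[i - h, ]; B <- points[i, ]; C <- points[i + h, ]
    a <- sqrt(sum((B - C)^2)); b <- sqrt(sum((A - C)^2)); c <- sqrt(sum((A - B)^2))
    # Heron with guard against round-off for near-collinear triples
    s2 <- (a + b + c) / 2
    arg <- s2 * (s2 - a) * (s2 - b) * (s2 - c)
    K <- if (arg <= 0) 0 else sqrt(arg)
    kappa <- 4 * K / (a * b * c + 1e-300)
    out[i] <- if (kappa * max(a, b, c) < 1e-9) Inf else 1 / kappa
  }
  out
}

#' Minimum arch curvature radius of a case
#'
#' Convenience morphometric: the minimum finite curvature radius of the
#' trunk centerline over the arch span.
#'
#' @param spec an [arch_case_spec()].
#' @param n centerline samples.
#' @return scalar (m).
#' @export
min_arch_curvature_radius <- function(spec, n = 256) {
  cl <- extract_centerline(spec, n)
  sel <- cl$segment == "arch" & is.finite(cl$curvature_radius)
  if (!any(sel)) return(Inf)
  min(cl$curvature_radius[sel])
}

#' Align centerlines at their apices
#'
#' Translation-only alignment for plotting several stages together: each
#' path is shifted so its highest point (arch apex) sits at the origin.
#'
#' @param paths list of [extract_centerline()] results.
#' @return the list with shifted \code{points}.
#' @export
align_centerlines <- function(paths) {
  lapply(paths, function(p) {
    apex <- p$points[which.max(p$points[, 2]), ]
    p$points <- sweep(p$points, 2, apex)
    p
  })
}
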