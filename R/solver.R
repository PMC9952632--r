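#' Blood fluid properties
#'
#' Newtonian blood model: density 1060 kg/m^3, dynamic viscosity 0.0035 Pa s.
#'
#' @param density kg/m^3.
#' @param dynamic_viscosity Pa s.
#' @return object of class \code{fluid_properties}.
#' @export
fluid_properties <- function(density = 1060, dynamic_viscosity = 0.0035) {
  stopifnot(density > 0, dynamic_viscosity > 0)
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "fluid_properties")
}

#' Solver configuration
#'
#' @param time_step fixed time step (s); must divide the cycle period.
#' @param n_cycles cycles to simulate (>= 2); only the final cycle is kept,
#'   earlier ones wash out the impulsive start transient.
#' @param save_stride store every \code{save_stride}-th step of the final
#'   cycle (must divide the steps per cycle).
#' @param inlet_profile spatial inlet profile: \code{"plug"} (default) or
#'   \code{"parabolic"}, both scaled to the prescribed mean velocity.
#' @param nonlinear_tolerance relative change between Picard iterates at
#'   which a step is accepted (default 0.005).
#' @param max_step hard cap on the time step (s).
#' @param max_picard Picard iteration cap per step.
#' @param graddiv grad-div (mass conservation) stabilization scale.
#' @param theta time-weighting of the viscous/convective operator: 1 =
#'   backward Euler (robust default), 0.5 = Crank-Nicolson (second-order,
#'   used for oscillatory-flow verification).
#' @param backflow scale of the outlet backflow-stabilization penalty
#'   (rho/2 (u.n)_- u, scaled); 0 disables it. Keep the default for the
#'   arch cases (diastolic outlet backflow); disable it for verification
#'   problems driven by reversing cap pressures, where it would bias the
#'   effective traction.
#' @return object of class \code{solver_config}.
#' @export
solver_config <- function(time_step = 0.002, n_cycles = 2, save_stride = 5,
                          inlet_profile = c("plug", "parabolic"),
                          nonlinear_tolerance = 0.005, max_step = 0.05,
                          max_picard = 8, graddiv = 1.0, theta = 1.0,
                          backflow = 1.0) {
  inlet_profile <- match.arg(inlet_profile)
  stopifnot(time_step > 0, time_step <= max_step, n_cycles >= 2,
            nonlinear_tolerance > 0, nonlinear_tolerance < 1,
            theta >= 0.5, theta <= 1)
  structure(list(time_step = time_step, n_cycles = n_cycles,
                 save_stride = save_stride, inlet_profile = inlet_profile,
                 nonlinear_tolerance = nonlinear_tolerance,
                 max_step = max_step, max_picard = max_picard,
                 graddiv = graddiv, theta = theta, backflow = backflow),
            class = "solver_config")
}

#' Flow field container
#'
#' Velocity/pressure snapshots over exactly one cardiac cycle (the final
#' simulated cycle), on the nodes of the mesh the solve was run on.
#'
#' @param times snapshot times (s), relative to the start of the stored
#'   cycle; strictly increasing.
#' @param U numeric array N x d x nt of nodal velocities (m/s).
#' @param P numeric matrix N x nt of nodal pressures (Pa).
#' @param period cycle length (s).
#' @return object of class \code{flow_field}.
#' @export
flow_field <- function(times, U, P, period = 1.0) {
  stopifnot(length(dim(U)) == 3, dim(U)[3] == length(times),
            nrow(P) == dim(U)[1], ncol(P) == length(times),
            all(diff(times) > 0) || length(times) == 1)
  structure(list(times = times, U = U, P = P, period = period,
                 dim = dim(U)[2]), class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat("Flow field:", dim(x$U)[1], "nodes,", length(x$times),
      "snapshots over", if (length(x$times) > 1)
        diff(range(x$times)) else 0, "s\n")
  vm <- sqrt(apply(x$U^2, c(1, 3), sum))
  cat("  max |u|:", format(max(vm), digits = 4), "m/s;  pressure range:",
      paste(format(range(x$P), digits = 4), collapse = " .. "), "Pa\n")
  invisible(x)
}

# ---- boundary helpers -------------------------------------------------------

node_set <- function(mesh, tag_match) {
  sel <- grepl(tag_match, mesh$facet_tag)
  sort(unique(as.integer(mesh$facets[sel, ])))
}

# inward inlet direction, cap centroid and rim radius for profile scaling
inlet_geometry <- function(mesh) {
  sel <- mesh$facet_tag == "inlet"
  if (!any(sel)) stop("mesh has no inlet facets")
  nrm <- colSums(mesh$facet_normal[sel, , drop = FALSE] *
                   mesh$facet_area[sel])
  dirv <- -nrm / sqrt(sum(nrm^2))
  mid <- facet_midpoints(mesh$nodes, mesh$facets[sel, , drop = FALSE])
  ctr <- colSums(mid * mesh$facet_area[sel]) / sum(mesh$facet_area[sel])
  nodes <- node_set(mesh, "^inlet$")
  dx <- sweep(mesh$nodes[nodes, , drop = FALSE], 2, ctr)
  ax <- as.numeric(dx %*% dirv)
  r <- sqrt(pmax(rowSums(dx^2) - ax^2, 0))
  list(nodes = nodes, dir = dirv, center = ctr, rim = max(r), r = r,
       area = sum(mesh$facet_area[sel]))
}

# per-node multiplier so the cross-section mean of the profile is 1
inlet_profile_shape <- function(geom, profile, d) {
  if (profile == "plug") return(rep(1, length(geom$nodes)))
  peak <- if (d == 2) 1.5 else 2
  peak * (1 - (geom$r / geom$rim)^2)
}

# surface flux integral(u . n dA) for the given facets (P1-exact quadrature)
facet_flux <- function(mesh, U, facet_sel) {
  f <- mesh$facets[facet_sel, , drop = FALSE]
  if (!nrow(f)) return(0)
  nn <- ncol(f)
  un <- 0
  for (k in seq_len(nn)) {
    uk <- U[f[, k], , drop = FALSE]
    un <- un + rowSums(uk * mesh$facet_normal[facet_sel, , drop = FALSE]) / nn
  }
  sum(un * mesh$facet_area[facet_sel])
}

apply_dirichlet <- function(A, b, idx, val) {
  nd <- length(b)
  keep <- rep(1, nd); keep[idx] <- 0
  Pd <- Matrix::Diagonal(x = keep)
  xbc <- numeric(nd); xbc[idx] <- val
  A2 <- Pd %*% A %*% Pd + Matrix::Diagonal(x = 1 - keep)
  b2 <- as.numeric(Pd %*% (b - A %*% xbc))
  b2[idx] <- val
  list(A = A2, b = b2)
}

min_edge_length <- function(mesh) {
  cells <- mesh$cells; nodes <- mesh$nodes
  nv <- ncol(cells)
  m <- Inf
  for (a in seq_len(nv - 1)) for (b in (a + 1):nv) {
    e <- nodes[cells[, a], , drop = FALSE] - nodes[cells[, b], , drop = FALSE]
    m <- min(m, min(rowSums(e^2)))
  }
  sqrt(m)
}

# assemble the raw (no-Dirichlet) system for one linearization state,
# including the weak outlet traction and backflow stabilization
ns_assemble_raw <- function(mesh, props, idt, Uprev, Uadv, p_out_val, cfg,
                            outlet_sel) {
  d <- mesh$dim; N <- nrow(mesh$nodes)
  asm <- assemble_ns_system(mesh$nodes, mesh$cells, props$density,
                            props$dynamic_viscosity, idt, Uprev, Uadv,
                            TRUE, cfg$graddiv,
                            if (idt > 0) cfg$theta %||% 1.0 else 1.0)
  ti <- asm$i + 1L; tj <- asm$j + 1L; tx <- asm$x
  b <- asm$rhs
  if (any(outlet_sel)) {
    f <- mesh$facets[outlet_sel, , drop = FALSE]
    nn <- ncol(f)
    nrm <- mesh$facet_normal[outlet_sel, , drop = FALSE]
    ar <- mesh$facet_area[outlet_sel]
    pv <- p_out_val[mesh$facet_tag[outlet_sel]]
    an <- 0
    for (k in seq_len(nn)) an <- an + rowSums(Uadv[f[, k], , drop = FALSE] * nrm) / nn
    beta <- (cfg$backflow %||% 1) * props$density * pmax(-an, 0) / 2
    for (k in seq_len(nn)) {
      w <- ar / nn
      for (comp in seq_len(d)) {
        dof <- (comp - 1L) * N + f[, k]
        b[dof] <- b[dof] - pv * nrm[, comp] * w
      }
      add <- beta * w
      if (any(add > 0)) {
        for (comp in seq_len(d)) {
          dof <- (comp - 1L) * N + f[, k]
          ti <- c(ti, dof); tj <- c(tj, dof); tx <- c(tx, add)
        }
      }
    }
  }
  list(A = Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                                dims = c(asm$ndof, asm$ndof)),
       b = b)
}

# Dirichlet-constrained reference operator; the sparse LU is computed once
# and cached inside the Matrix object, so repeated solves are cheap
ns_make_reference <- function(A, bc_idx) {
  nd <- nrow(A)
  keep <- rep(1, nd); keep[bc_idx] <- 0
  Pd <- Matrix::Diagonal(x = keep)
  Pd %*% A %*% Pd + Matrix::Diagonal(x = 1 - keep)
}

# Solve the (nonlinear) system for one state. Outer sweeps are Picard
# linearizations (reassembly at the current iterate); each linearized system
# is solved by defect-correction against a frozen factorized reference
# operator (inner loop: residual + cached-LU correction only), which is
# refreshed whenever the inner iteration fails to contract fast enough.
# x must enter satisfying the Dirichlet values.
ns_defect_solve <- function(mesh, props, idt, Uprev, x, bc_idx, bc_val,
                            p_out_val, cfg, ref, tol, max_it,
                            lin_tol = NULL, lin_max = 12L) {
  d <- mesh$dim; N <- nrow(mesh$nodes)
  lin_tol <- lin_tol %||% min(tol / 10, 1e-6)
  x[bc_idx] <- bc_val
  vel <- seq_len(d * N)
  it <- 0L
  hist <- numeric()
  repeat {
    it <- it + 1L
    Uadv <- matrix(x[vel], N, d)
    raw <- ns_assemble_raw(mesh, props, idt, Uprev, Uadv, p_out_val, cfg,
                           ref$outlet_sel)
    if (is.null(ref$A2)) {
      ref$A2 <- ns_make_reference(raw$A, bc_idx)
      ref$n_factor <- (ref$n_factor %||% 0L) + 1L
    }
    x_in <- x
    lin_ok <- FALSE
    for (attempt in 1:2) {
      x <- x_in
      prev <- Inf
      for (li in seq_len(lin_max)) {
        r <- raw$b - as.numeric(raw$A %*% x)
        r[bc_idx] <- 0
        dx <- as.numeric(Matrix::solve(ref$A2, r, sparse = TRUE))
        x <- x + dx
        rel <- sqrt(sum(dx[vel]^2)) / max(sqrt(sum(x[vel]^2)), 1e-30)
        if (!is.finite(rel)) break
        if (rel < lin_tol) { lin_ok <- TRUE; break }
        if (li >= 2 && rel > 0.7 * prev) break  # stalling or diverging
        prev <- rel
      }
      if (lin_ok) break
      # frozen operator too stale for this linearization: refactor exactly
      ref$A2 <- ns_make_reference(raw$A, bc_idx)
      ref$n_factor <- ref$n_factor + 1L
    }
    if (!lin_ok)
      stop("linear defect iteration failed to converge even after ",
           "refactoring; defect history: ",
           paste(format(utils::tail(hist, 5), digits = 3), collapse = ", "))
    change <- sqrt(sum((x[vel] - x_in[vel])^2)) /
      max(sqrt(sum(x[vel]^2)), 1e-30)
    hist <- c(hist, change)
    if ((change < tol && lin_ok) || it >= max_it) break
  }
  list(x = x, change = change, iterations = it, history = hist)
}

# ---- pulsatile solve --------------------------------------------------------

#' Solve pulsatile laminar flow over the cardiac cycle
#'
#' Integrates the incompressible Newtonian Navier-Stokes equations on a
#' labeled mesh with a velocity-inlet waveform, pressure-outlet waveform
#' (applied weakly as a normal traction, with backflow stabilization), and
#' rigid no-slip walls. Backward-Euler time stepping with semi-implicit
#' (Picard-linearized) convection on stabilized linear elements; the first
#' \code{n_cycles - 1} cycles are discarded as transient and snapshots of the
#' final cycle are returned.
#'
#' @param mesh a [labeled_mesh()].
#' @param inlet inlet-velocity [pc_waveform()] (m/s, cross-section mean), or
#'   NULL for a purely pressure-driven problem (e.g. oscillatory forcing
#'   between two pressure caps).
#' @param outlet outlet-pressure [pc_waveform()] (mmHg converted internally,
#'   or Pa), applied at every \code{outlet:*} tag; or a named list of
#'   waveforms keyed by full outlet tag for per-outlet signals.
#' @param props [fluid_properties()].
#' @param cfg [solver_config()].
#' @param verbose print per-cycle progress.
#' @return a [flow_field()] covering the final cycle (closed: first and last
#'   snapshot one period apart).
#' @export
solve_pulsatile <- function(mesh, inlet, outlet, props = fluid_properties(),
                            cfg = solver_config(), verbose = FALSE) {
  stopifnot(inherits(mesh, "labeled_mesh"),
            is.null(inlet) || inherits(inlet, "pc_waveform"))
  outlet_sel <- startsWith(mesh$facet_tag, "outlet:")
  outlet_tags <- unique(mesh$facet_tag[outlet_sel])
  ow <- if (inherits(outlet, "pc_waveform")) {
    stats::setNames(rep(list(outlet), length(outlet_tags)), outlet_tags)
  } else {
    stopifnot(is.list(outlet), all(outlet_tags %in% names(outlet)))
    outlet
  }
  Tper <- if (!is.null(inlet)) inlet$period else ow[[1]]$period
  d <- mesh$dim; N <- nrow(mesh$nodes)
  spc <- round(Tper / cfg$time_step)
  dt <- Tper / spc
  if (spc %% cfg$save_stride != 0)
    stop("save_stride must divide the steps per cycle (", spc, ")")
  p_conv <- vapply(ow, function(w) if (w$units == "mmHg") 133.322 else 1, 0)

  wall <- node_set(mesh, "^wall$")
  if (!is.null(inlet)) {
    geom <- inlet_geometry(mesh)
    inlet_only <- setdiff(geom$nodes, wall)  # rim nodes keep the wall value
    shape <- inlet_profile_shape(geom, cfg$inlet_profile, d)
    shape <- shape[match(inlet_only, geom$nodes)]
  } else {
    geom <- list(dir = numeric(d))
    inlet_only <- integer()
    shape <- numeric()
  }

  bc_nodes <- c(wall, inlet_only)
  bc_idx <- unlist(lapply(seq_len(d) - 1L,
                          function(k) k * N + bc_nodes))

  hmin <- min_edge_length(mesh)
  U <- matrix(0, N, d); P <- numeric(N)
  x <- numeric((d + 1) * N)
  nsnap <- spc %/% cfg$save_stride + 1L
  Us <- array(0, dim = c(N, d, nsnap)); Ps <- matrix(0, N, nsnap)
  times <- (seq_len(nsnap) - 1L) * cfg$save_stride * dt
  cfl_warned <- FALSE
  hist <- numeric()
  ref <- new.env()
  ref$outlet_sel <- outlet_sel
  nw <- length(wall); nio <- length(inlet_only)

  total <- cfg$n_cycles * spc
  for (step in seq_len(total)) {
    t1 <- step * dt
    bcv <- numeric(length(bc_idx))
    if (!is.null(inlet)) {
      vmean <- wf_eval(inlet, t1)
      for (k in seq_len(d)) {
        off <- (k - 1L) * (nw + nio)
        bcv[off + nw + seq_len(nio)] <- vmean * shape * geom$dir[k]
      }
    }
    p_out_val <- vapply(outlet_tags, function(tg)
      wf_eval(ow[[tg]], t1) * p_conv[[tg]], 0)

    sol <- tryCatch(
      ns_defect_solve(mesh, props, 1 / dt, U, x, bc_idx, bcv, p_out_val,
                      cfg, ref, tol = cfg$nonlinear_tolerance,
                      max_it = cfg$max_picard),
      error = function(e)
        stop("solver diverged at step ", step, " (t = ", t1, " s): ",
             conditionMessage(e)))
    x <- sol$x
    hist <- c(hist, sol$change)
    U <- matrix(x[seq_len(d * N)], N, d)
    P <- x[d * N + seq_len(N)]
    if (!cfl_warned) {
      cfl <- max(sqrt(rowSums(U^2))) * dt / hmin
      if (cfl > 5) {
        warning("advective CFL = ", format(cfl, digits = 3), " > 5")
        cfl_warned <- TRUE
      }
    }
    cyc_step <- step - (cfg$n_cycles - 1L) * spc
    if (cyc_step == 0L) { Us[, , 1L] <- U; Ps[, 1L] <- P }
    if (cyc_step > 0L && cyc_step %% cfg$save_stride == 0L) {
      k <- cyc_step %/% cfg$save_stride + 1L
      Us[, , k] <- U; Ps[, k] <- P
    }
    if (verbose && step %% spc == 0L)
      message("cycle ", step %/% spc, "/", cfg$n_cycles, " done")
  }
  out <- flow_field(times, Us, Ps, period = Tper)
  attr(out, "picard_history") <- hist
  out
}

#' Solve steady laminar flow at a prescribed inflow rate
#'
#' Picard iteration on the steady stabilized system, starting from the Stokes
#' solution, with a parabolic (default) or plug inlet profile scaled to the
#' prescribed volumetric inflow and zero outlet pressure.
#'
#' @param mesh a [labeled_mesh()].
#' @param inflow_rate volumetric inflow (m^3/s; m^2/s per unit depth in
#'   planar mode).
#' @param props [fluid_properties()].
#' @param profile inlet profile.
#' @param tol relative-change convergence tolerance.
#' @param max_iter Picard cap.
#' @return a [flow_field()] with a single snapshot; attribute
#'   \code{convergence} holds the relative-change history.
#' @export
solve_steady <- function(mesh, inflow_rate, props = fluid_properties(),
                         profile = c("parabolic", "plug"),
                         tol = 1e-8, max_iter = 80) {
  profile <- match.arg(profile)
  stopifnot(inflow_rate >= 0)
  d <- mesh$dim; N <- nrow(mesh$nodes)
  if (inflow_rate == 0) {   # degenerate: hydrostatic rest state
    out <- flow_field(0, array(0, dim = c(N, d, 1)), matrix(0, N, 1))
    attr(out, "convergence") <- 0
    return(out)
  }
  cfg <- solver_config(inlet_profile = profile)
  wall <- node_set(mesh, "^wall$")
  geom <- inlet_geometry(mesh)
  inlet_only <- setdiff(geom$nodes, wall)
  shape <- inlet_profile_shape(geom, profile, d)
  shape <- shape[match(inlet_only, geom$nodes)]
  vmean <- inflow_rate / geom$area
  outlet_sel <- startsWith(mesh$facet_tag, "outlet:")
  outlet_tags <- unique(mesh$facet_tag[outlet_sel])
  p_out_val <- stats::setNames(rep(0, length(outlet_tags)), outlet_tags)
  bc_nodes <- c(wall, inlet_only)
  bc_idx <- unlist(lapply(seq_len(d) - 1L, function(k) k * N + bc_nodes))
  nw <- length(wall); nio <- length(inlet_only)
  bcv <- numeric(length(bc_idx))
  for (k in seq_len(d)) {
    off <- (k - 1L) * (nw + nio)
    bcv[off + nw + seq_len(nio)] <- vmean * shape * geom$dir[k]
  }
  ref <- new.env()
  ref$outlet_sel <- outlet_sel
  Uzero <- matrix(0, N, d)
  sol <- ns_defect_solve(mesh, props, 0, Uzero, numeric((d + 1) * N),
                         bc_idx, bcv, p_out_val, cfg, ref,
                         tol = tol, max_it = max_iter, lin_tol = tol / 10)
  if (sol$change >= tol)
    warning("steady Picard did not reach tol = ", tol,
            " (final change ", format(sol$change, digits = 3), ")")
  U <- matrix(sol$x[seq_len(d * N)], N, d)
  out <- flow_field(0, array(U, dim = c(N, d, 1)),
                    matrix(sol$x[d * N + seq_len(N)], N, 1))
  attr(out, "convergence") <- sol$history
  out
}

#' Mass-conservation check
#'
#' Maximum over the stored snapshots of the relative imbalance between the
#' total outlet flux and the inlet flux,
#' \eqn{\max_t |\sum_{out}\Phi - \Phi_{in}| / |\Phi_{in}|}. A zero-flow field
#' returns 0 by convention.
#'
#' @param field a [flow_field()].
#' @param mesh the [labeled_mesh()] it was computed on.
#' @return non-negative scalar.
#' @export
check_mass_conservation <- function(field, mesh) {
  inlet_sel <- mesh$facet_tag == "inlet"
  outlet_sel <- startsWith(mesh$facet_tag, "outlet:")
  nt <- length(field$times)
  phi_in <- phi_out <- numeric(nt)
  for (k in seq_len(nt)) {
    Uk <- field$U[, , k, drop = FALSE][, , 1, drop = FALSE]
    dim(Uk) <- dim(field$U)[1:2]
    phi_in[k] <- -facet_flux(mesh, Uk, inlet_sel)   # inward positive
    phi_out[k] <- facet_flux(mesh, Uk, outlet_sel)
  }
  scale <- max(abs(phi_in))
  if (scale == 0) return(0)
  max(abs(phi_out - phi_in) / pmax(abs(phi_in), 1e-12 * scale))
}

#' Womersley number
#'
#' \eqn{\alpha = R\sqrt{\omega\rho/\mu}} with \eqn{\omega = 2\pi/T}: the
#' ratio of pulsatile to viscous effects in oscillatory tube flow.
#'
#' @param radius tube radius (m).
#' @param period cycle period (s).
#' @param props [fluid_properties()].
#' @return dimensionless alpha.
#' @export
womersley_number <- function(radius, period = 1, props = fluid_properties()) {
  stopifnot(radius >= 0, period > 0)
  radius * sqrt(2 * pi / period * props$density / props$dynamic_viscosity)
}
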