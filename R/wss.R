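#' Wall shear stress extraction
#'
#' Computes the tangential viscous traction on every wall facet and snapshot.
#' The velocity gradient at the facet midpoint is reconstructed either by
#' quadratic patch recovery (default: least-squares fit of each velocity
#' component over the node patch around the wall-adjacent cell — exact for
#' quadratic profiles such as Poiseuille flow) or as the piecewise-constant
#' gradient of the adjacent cell (\code{method = "cell"}; exact for linear
#' fields, first-order at curved-profile walls). The full viscous traction
#' \eqn{\mu(\nabla u + \nabla u^T) n} is then formed with the outward facet
#' normal and its normal component removed, so every stored vector is
#' orthogonal to its facet normal by construction. Facets whose adjacent
#' cell is degenerate (volume below 1e-6 of the median) are excluded and
#' counted in attribute \code{n_excluded}; facets whose patch is too small
#' for a quadratic fit fall back to the cell gradient.
#'
#' @param field a [flow_field()].
#' @param mesh the [labeled_mesh()] the field lives on.
#' @param props [fluid_properties()].
#' @param method gradient reconstruction: \code{"patch"} (default) or
#'   \code{"cell"}.
#' @return a [wall_shear_field()]; traction vectors are padded to 3
#'   components in planar mode (third component zero).
#' @export
compute_wss <- function(field, mesh, props = fluid_properties(),
                        method = c("patch", "cell")) {
  stopifnot(inherits(field, "flow_field"), inherits(mesh, "labeled_mesh"))
  method <- match.arg(method)
  d <- mesh$dim
  wall_sel <- which(mesh$facet_tag == "wall")
  adj <- mesh$facet_cell[wall_sel]
  vol <- abs(mesh$cell_volume[adj])
  ok <- vol > 1e-6 * stats::median(abs(mesh$cell_volume))
  n_excluded <- sum(!ok)
  if (n_excluded)
    warning(n_excluded, " wall facet(s) with degenerate adjacent cells excluded")
  wall_sel <- wall_sel[ok]
  adj <- adj[ok]
  nf <- length(wall_sel)
  nt <- length(field$times)
  nrm <- mesh$facet_normal[wall_sel, , drop = FALSE]
  mids <- facet_midpoints(mesh$nodes, mesh$facets[wall_sel, , drop = FALSE])
  mu <- props$dynamic_viscosity

  patches <- NULL
  hscale <- 1
  if (method == "patch") {
    # node patch: nodes of all cells touching any node of the adjacent cell
    node_cells <- split(rep(seq_len(nrow(mesh$cells)), ncol(mesh$cells)),
                        as.integer(mesh$cells))
    patches <- lapply(adj, function(e) {
      nd <- mesh$cells[e, ]
      cl <- unique(unlist(node_cells[as.character(nd)], use.names = FALSE))
      sort(unique(as.integer(mesh$cells[cl, ])))
    })
    hscale <- mean(sqrt(if (d == 2) mesh$cell_volume * 2
                        else (6 * mesh$cell_volume)^(2 / 3)))
  }

  tr <- array(0, dim = c(nf, 3, nt))
  for (k in seq_len(nt)) {
    Uk <- matrix(field$U[, , k], nrow = dim(field$U)[1], ncol = d)
    L <- cell_velocity_gradients(mesh$nodes, mesh$cells,
                                 as.integer(adj), Uk)   # nf x (d*d)
    if (method == "patch") {
      Lp <- patch_velocity_gradients(mesh$nodes, patches, mids, Uk, hscale)
      use <- !is.na(Lp[, 1])
      L[use, ] <- Lp[use, , drop = FALSE]
    }
    tfull <- matrix(0, nf, d)
    for (kk in seq_len(d)) for (ll in seq_len(d)) {
      Skl <- L[, (kk - 1) * d + ll] + L[, (ll - 1) * d + kk]
      tfull[, kk] <- tfull[, kk] + mu * Skl * nrm[, ll]
    }
    tn <- rowSums(tfull * nrm)
    ttan <- tfull - tn * nrm
    tr[, seq_len(d), k] <- ttan
  }
  nrm3 <- cbind(nrm, matrix(0, nf, 3 - d))
  out <- wall_shear_field(tr, times = field$times,
                          facet_area = mesh$facet_area[wall_sel],
                          facet_normal = nrm3, facet_ids = wall_sel,
                          period = field$period)
  attr(out, "n_excluded") <- n_excluded
  attr(out, "method") <- method
  out
}
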