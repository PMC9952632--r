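#' Parametric arch case specification
#'
#' Describes one idealized aortic-arch lumen: a trunk (straight ascending
#' segment, toroidal arch of curvature radius \code{arch_curvature_radius},
#' straight descending segment) with supra-aortic branch channels on the
#' outer (greater-curvature) wall, an optional saccular aneurysm bulge, and
#' flow extensions of \code{extension_factor} local diameters at every open
#' end. Arc-length coordinates run from 0 at the start of the ascending
#' segment (flow extensions have negative / beyond-range coordinates).
#'
#' @param case_label one of \code{"normal"}, \code{"preop"},
#'   \code{"postop1w"}, \code{"postop6m"} (or a free label for custom specs).
#' @param lumen_radius trunk lumen radius (m).
#' @param ascending_length,descending_length straight segment lengths (m).
#' @param arch_curvature_radius torus radius of the arch centerline (m);
#'   \code{Inf} degenerates the trunk to a straight tube (no arch span).
#' @param branches data.frame with columns \code{name} (IA, LCCA, LSA),
#'   \code{ostium_s} (arc-length of the ostium center, m), \code{radius} (m;
#'   half-width in planar mode), \code{length} (m, before the flow
#'   extension), \code{present} (logical). The IA carries the bifurcation
#'   into RSA and RCCA described by \code{ia_bifurcation}.
#' @param ia_bifurcation list(\code{split_length}: IA channel length before
#'   the RSA/RCCA split (m), \code{branch_radius}, \code{branch_length},
#'   \code{angle}: half-angle between the daughter channels, rad).
#' @param aneurysm NULL or list(\code{center_s}: arc position of the sac
#'   center (m), \code{bulge_radius}: maximal outward bulge (m),
#'   \code{neck_halfwidth}: half-extent of the neck along the arch (m)).
#' @param extension_factor flow extensions, in local diameters (default 5).
#' @param boundary_layer_count graded near-wall layers (default 6).
#' @param boundary_layer_ratio grading ratio between successive layers.
#' @param mesh_size target core element edge length (m).
#' @return object of class \code{arch_case_spec}.
#' @export
arch_case_spec <- function(case_label, lumen_radius = 0.0125,
                           ascending_length = 0.06, descending_length = 0.10,
                           arch_curvature_radius = 0.032,
                           branches = NULL,
                           ia_bifurcation = list(split_length = 0.02,
                                                 branch_radius = 0.003,
                                                 branch_length = 0.025,
                                                 angle = 0.45),
                           aneurysm = NULL,
                           extension_factor = 5,
                           boundary_layer_count = 6,
                           boundary_layer_ratio = 1.2,
                           mesh_size = 0.004) {
  if (is.null(branches))
    branches <- data.frame(name = character(), ostium_s = numeric(),
                           radius = numeric(), length = numeric(),
                           present = logical())
  spec <- structure(list(
    case_label = case_label, lumen_radius = lumen_radius,
    ascending_length = ascending_length, descending_length = descending_length,
    arch_curvature_radius = arch_curvature_radius,
    branches = branches, ia_bifurcation = ia_bifurcation,
    aneurysm = aneurysm, extension_factor = extension_factor,
    boundary_layer_count = boundary_layer_count,
    boundary_layer_ratio = boundary_layer_ratio,
    mesh_size = mesh_size), class = "arch_case_spec")
  validate_arch_case_spec(spec)
  spec
}

#' Validate an arch case specification
#'
#' Checks the structural invariants of a single spec: positive dimensions,
#' arch curvature radius exceeding the lumen radius, branch radii below the
#' lumen radius, branch ostia inside the trunk, and no overlap between
#' branch necks or between a branch and the aneurysm neck. Infeasible
#' geometry is reported with the offending components named.
#'
#' @param spec an [arch_case_spec()].
#' @return the spec, invisibly; stops with a descriptive error otherwise.
#' @export
validate_arch_case_spec <- function(spec) {
  stopifnot(inherits(spec, "arch_case_spec"))
  if (spec$lumen_radius <= 0) stop("lumen_radius must be positive")
  if (spec$arch_curvature_radius <= spec$lumen_radius)
    stop("arch_curvature_radius must exceed lumen_radius")
  br <- spec$branches
  pres <- br[br$present, , drop = FALSE]
  if (nrow(pres)) {
    bad <- pres$name[pres$radius >= spec$lumen_radius]
    if (length(bad))
      stop("branch radius must be below lumen radius: ", paste(bad, collapse = ", "))
    trunk_len <- trunk_length(spec)
    lo <- pres$ostium_s - pres$radius
    hi <- pres$ostium_s + pres$radius
    out <- pres$name[lo < 0 | hi > trunk_len]
    if (length(out))
      stop("branch ostium outside trunk: ", paste(out, collapse = ", "))
    if (nrow(pres) > 1) {
      o <- order(lo)
      lo <- lo[o]; hi <- hi[o]; nm <- pres$name[o]
      ov <- which(lo[-1] < hi[-length(hi)])
      if (length(ov))
        stop("overlapping branches: ",
             paste(nm[ov], nm[ov + 1], sep = "/", collapse = ", "))
    }
  }
  an <- spec$aneurysm
  if (!is.null(an)) {
    alo <- an$center_s - an$neck_halfwidth
    ahi <- an$center_s + an$neck_halfwidth
    if (nrow(pres)) {
      hit <- pres$name[pmax(alo, pres$ostium_s - pres$radius) <
                         pmin(ahi, pres$ostium_s + pres$radius)]
      if (length(hit))
        stop("aneurysm intersects branch: ", paste(hit, collapse = ", "))
    }
    La <- spec$ascending_length
    arch_len <- arch_span(spec)
    if (alo < La || ahi > La + arch_len)
      stop("aneurysm neck must lie on the arch span")
  }
  invisible(spec)
}

arch_span <- function(spec) {
  if (!is.finite(spec$arch_curvature_radius)) 0 else pi * spec$arch_curvature_radius
}

trunk_length <- function(spec)
  spec$ascending_length + arch_span(spec) + spec$descending_length

#' Default case specifications for the four morphological stages
#'
#' Returns the preset geometries emulating the four reconstructed lumens:
#' \describe{
#'   \item{normal}{all three supra-aortic branches on the arch, no aneurysm.}
#'   \item{preop}{as normal plus a saccular aneurysm bulge on the distal
#'     arch.}
#'   \item{postop1w}{1 week postoperative: aneurysm sac excluded, LSA
#'     occluded, IA/LCCA ostia relocated proximally onto the ascending
#'     segment, arch curvature radius reduced.}
#'   \item{postop6m}{6 months postoperative: as postop1w but the arch
#'     curvature radius partially recovers toward normal.}
#' }
#' All absolute dimensions are adult-aortic presets (lumen radius 12.5 mm,
#' arch curvature radius 32/32/25/29 mm across the stages, branch radii
#' 6/4/4 mm for IA/LCCA/LSA, aneurysm bulge 20 mm); they preserve the
#' qualitative inter-stage orderings (curvature dip at 1 week with partial
#' recovery at 6 months, proximal ostium relocation, LSA occlusion).
#'
#' @param mesh_size target core element edge length (m) stored in each spec.
#' @return named list of four [arch_case_spec()] objects.
#' @export
default_case_specs <- function(mesh_size = 0.004) {
  branches_pre <- data.frame(
    name = c("IA", "LCCA", "LSA"),
    ostium_s = c(0.075, 0.095, 0.112),
    radius = c(0.006, 0.004, 0.004),
    length = c(0.020, 0.030, 0.030),
    present = c(TRUE, TRUE, TRUE))
  branches_post <- data.frame(
    name = c("IA", "LCCA", "LSA"),
    ostium_s = c(0.040, 0.054, NA),
    radius = c(0.006, 0.004, 0.004),
    length = c(0.020, 0.030, 0.030),
    present = c(TRUE, TRUE, FALSE))
  sac <- list(center_s = 0.135, bulge_radius = 0.020, neck_halfwidth = 0.010)
  list(
    normal = arch_case_spec("normal", arch_curvature_radius = 0.032,
                            branches = branches_pre, mesh_size = mesh_size),
    preop = arch_case_spec("preop", arch_curvature_radius = 0.032,
                           branches = branches_pre, aneurysm = sac,
                           mesh_size = mesh_size),
    postop1w = arch_case_spec("postop1w", arch_curvature_radius = 0.025,
                              branches = branches_post, mesh_size = mesh_size),
    postop6m = arch_case_spec("postop6m", arch_curvature_radius = 0.029,
                              branches = branches_post, mesh_size = mesh_size))
}

#' @export
print.arch_case_spec <- function(x, ...) {
  cat("Arch case spec '", x$case_label, "'\n", sep = "")
  cat("  lumen radius ", x$lumen_radius * 1e3, " mm, arch curvature radius ",
      x$arch_curvature_radius * 1e3, " mm\n", sep = "")
  pres <- x$branches[x$branches$present, , drop = FALSE]
  cat("  branches:", if (nrow(pres)) paste(pres$name, collapse = ", ") else "none",
      "| aneurysm:", if (is.null(x$aneurysm)) "absent" else "present", "\n")
  invisible(x)
}

# ---- trunk centerline frame -------------------------------------------------

# centerline point, tangent and outer-wall normal at arc coordinate s
# (vectorized over s; extensions continue the end tangents)
trunk_frame <- function(spec, s) {
  La <- spec$ascending_length
  Ra <- spec$arch_curvature_radius
  arch_len <- arch_span(spec)
  Ld <- spec$descending_length
  n <- length(s)
  P <- matrix(0, n, 2); Tg <- matrix(0, n, 2); Nv <- matrix(0, n, 2)
  asc <- s <= La
  P[asc, 1] <- 0; P[asc, 2] <- s[asc]
  Tg[asc, ] <- rep(c(0, 1), each = sum(asc))
  Nv[asc, ] <- rep(c(-1, 0), each = sum(asc))
  if (arch_len > 0) {
    inarch <- s > La & s <= La + arch_len
    th <- pi - (s[inarch] - La) / Ra
    P[inarch, 1] <- Ra + Ra * cos(th)
    P[inarch, 2] <- La + Ra * sin(th)
    Tg[inarch, 1] <- sin(th); Tg[inarch, 2] <- -cos(th)
    Nv[inarch, 1] <- cos(th); Nv[inarch, 2] <- sin(th)
  }
  dsc <- s > La + arch_len
  x_d <- if (arch_len > 0) 2 * Ra else 0
  P[dsc, 1] <- x_d
  P[dsc, 2] <- if (arch_len > 0) La - (s[dsc] - La - arch_len) else s[dsc]
  if (arch_len > 0) {
    Tg[dsc, ] <- rep(c(0, -1), each = sum(dsc))
    Nv[dsc, ] <- rep(c(1, 0), each = sum(dsc))
  } else {
    Tg[dsc, ] <- rep(c(0, 1), each = sum(dsc))
    Nv[dsc, ] <- rep(c(-1, 0), each = sum(dsc))
  }
  list(point = P, tangent = Tg, normal = Nv)
}

# ---- 1D grids ---------------------------------------------------------------

# transverse breakpoints across a channel of width `total` with n_bl graded
# boundary layers (ratio r) at both walls and a ~h_core uniform core
graded_spacing <- function(total, h_core, n_bl, ratio, bl_frac_max = 0.25) {
  t1 <- h_core / ratio^(n_bl - 1)
  bl_total <- t1 * (ratio^n_bl - 1) / (ratio - 1)
  cap <- bl_frac_max * total
  if (bl_total > cap) {
    t1 <- t1 * cap / bl_total
    bl_total <- cap
  }
  wl <- t1 * ratio^(seq_len(n_bl) - 1)     # increasing away from the wall
  core_len <- total - 2 * bl_total
  n_core <- max(1L, round(core_len / h_core))
  widths <- c(wl, rep(core_len / n_core, n_core), rev(wl))
  c(0, cumsum(widths)) * (total / sum(widths))
}

# axial breakpoints covering `breaks`, ~h spacing, honoring per-interval
# minimum counts (named by interval index) and even-count requirements
segmented_axis <- function(breaks, h, even_intervals = integer()) {
  breaks <- sort(unique(breaks))
  out <- breaks[1]
  for (i in seq_len(length(breaks) - 1)) {
    span <- breaks[i + 1] - breaks[i]
    n <- max(1L, ceiling(span / h))
    if (i %in% even_intervals && n %% 2L == 1L) n <- n + 1L
    out <- c(out, breaks[i] + span * seq_len(n) / n)
  }
  out
}

# ---- structured patches -----------------------------------------------------

# triangulate an ni x nj grid of points; returns cells indexing the grid
# nodes in column-major order, two triangles per quad with a fixed diagonal
grid_triangles <- function(ni, nj) {
  i <- rep(seq_len(ni - 1), nj - 1)
  j <- rep(seq_len(nj - 1), each = ni - 1)
  n00 <- (j - 1) * ni + i
  n10 <- n00 + 1L
  n01 <- n00 + ni
  n11 <- n01 + 1L
  rbind(cbind(n00, n10, n11), cbind(n00, n11, n01))
}

# quad index (within the (ni-1)x(nj-1) grid) of each triangle from
# grid_triangles, used to attach per-cell metadata
grid_triangle_quad <- function(ni, nj) {
  q <- seq_len((ni - 1) * (nj - 1))
  c(q, q)
}

# ---- planar arch builder ----------------------------------------------------

#' Build the lumen mesh for an arch case
#'
#' Generates the labeled simplex mesh for a case specification. The default
#' planar mode produces the production 2D lumen (trunk with graded
#' boundary-layer spacing near both walls, branch channels with the IA
#' bifurcating into RSA and RCCA, aneurysm bulge, flow extensions at every
#' open end). The \code{tube3d} mode sweeps the trunk cross-section disc
#' along the centerline into tetrahedra and supports branch-free specs only.
#' Meshing is fully deterministic: identical specs give bitwise-identical
#' node coordinates.
#'
#' @param spec an [arch_case_spec()].
#' @param mode \code{"planar"} (default, production) or \code{"tube3d"}.
#' @return a [labeled_mesh()] with tags \code{inlet}, \code{wall} and
#'   \code{outlet:<name>} for each present outlet, anatomical region labels
#'   and flow-extension flags on wall facets, and per-cell arc-length
#'   metadata for the trunk.
#' @export
build_case_geometry <- function(spec, mode = c("planar", "tube3d")) {
  mode <- match.arg(mode)
  validate_arch_case_spec(spec)
  if (mode == "tube3d") return(build_trunk_tube3d(spec))
  build_arch_planar(spec)
}

build_arch_planar <- function(spec) {
  R <- spec$lumen_radius
  h <- spec$mesh_size
  ext_trunk <- spec$extension_factor * 2 * R
  La <- spec$ascending_length
  arch_len <- arch_span(spec)
  Ld <- spec$descending_length
  s_end <- La + arch_len + Ld
  pres <- spec$branches[spec$branches$present, , drop = FALSE]

  # trunk axial grid: breakpoints at segment boundaries, ostium and neck edges
  breaks <- c(-ext_trunk, 0, La, La + arch_len, s_end, s_end + ext_trunk)
  span_edges <- c()
  if (nrow(pres))
    span_edges <- c(span_edges, pres$ostium_s - pres$radius,
                    pres$ostium_s + pres$radius)
  if (!is.null(spec$aneurysm))
    span_edges <- c(span_edges,
                    spec$aneurysm$center_s - spec$aneurysm$neck_halfwidth,
                    spec$aneurysm$center_s + spec$aneurysm$neck_halfwidth)
  breaks <- sort(unique(c(breaks, span_edges)))
  # IA ostium interval must have an even cell count for the downstream split
  even_iv <- integer()
  if (nrow(pres) && "IA" %in% pres$name) {
    ia <- pres[pres$name == "IA", ]
    lo <- ia$ostium_s - ia$radius
    even_iv <- which(abs(breaks[-length(breaks)] - lo) < 1e-12)
  }
  s_grid <- segmented_axis(breaks, h, even_intervals = even_iv)
  q_grid <- graded_spacing(2 * R, h, spec$boundary_layer_count,
                           spec$boundary_layer_ratio) - R

  fr <- trunk_frame(spec, s_grid)
  ni <- length(s_grid); nj <- length(q_grid)
  X <- matrix(0, ni, nj); Y <- matrix(0, ni, nj)
  for (j in seq_len(nj)) {
    X[, j] <- fr$point[, 1] + fr$normal[, 1] * q_grid[j]
    Y[, j] <- fr$point[, 2] + fr$normal[, 2] * q_grid[j]
  }
  nodes <- cbind(as.numeric(X), as.numeric(Y))
  cells <- grid_triangles(ni, nj)
  quad <- grid_triangle_quad(ni, nj)
  qi <- (quad - 1L) %% (ni - 1L) + 1L   # axial cell index
  qj <- (quad - 1L) %/% (ni - 1L) + 1L  # transverse cell index
  s_mid <- (s_grid[-1] + s_grid[-ni]) / 2
  q_mid <- (q_grid[-1] + q_grid[-nj]) / 2
  cell_s <- s_mid[qi]
  cell_q <- q_mid[qj]
  region <- rep("ascending", length(cell_s))
  region[cell_s < 0] <- "inlet_extension"
  region[cell_s >= La & cell_s < La + arch_len] <- "arch"
  region[cell_s >= La + arch_len] <- "descending"
  region[cell_s > s_end] <- "descending_extension"
  extension <- region %in% c("inlet_extension", "descending_extension")

  patches <- list(list(nodes = nodes, cells = cells, region = region,
                       extension = extension, cell_s = cell_s, cell_q = cell_q))
  caps <- list(
    list(tag = "inlet",
         point = as.numeric(trunk_frame(spec, -ext_trunk)$point),
         normal = c(0, 1), radius = 1.5 * R),
    list(tag = "outlet:descending",
         point = as.numeric(trunk_frame(spec, s_end + ext_trunk)$point),
         normal = c(0, 1), radius = 1.5 * R))

  # saccular aneurysm: a side pouch (cavity) on the outer wall, open to the
  # lumen across its neck and closed everywhere else; the shear of the main
  # stream across the neck drives a recirculating cavity flow
  an <- spec$aneurysm
  if (!is.null(an)) {
    idx <- which(s_grid >= an$center_s - an$neck_halfwidth - 1e-12 &
                   s_grid <= an$center_s + an$neck_halfwidth + 1e-12)
    base <- cbind(X[idx, nj], Y[idx, nj])
    dirv <- as.numeric(trunk_frame(spec, an$center_s)$normal)
    patches <- c(patches, list(sac_pouch(base, dirv, an, h)))
  }

  # branch channels off the outer wall
  for (b in seq_len(nrow(pres))) {
    nm <- pres$name[b]
    w <- pres$radius[b]
    sc <- pres$ostium_s[b]
    idx <- which(s_grid >= sc - w - 1e-12 & s_grid <= sc + w + 1e-12)
    base <- cbind(X[idx, nj], Y[idx, nj])
    dirv <- as.numeric(trunk_frame(spec, sc)$normal)
    if (nm == "IA") {
      bp <- build_ia_tree(spec, base, dirv, h)
    } else {
      ext_b <- spec$extension_factor * 2 * w
      bp <- extrude_channel(base, dirv, pres$length[b], ext_b, h, nm)
      bp$caps <- list(end_cap(bp, dirv, paste0("outlet:", nm), 1.5 * w))
    }
    patches <- c(patches, bp$patches)
    caps <- c(caps, bp$caps)
  }

  assemble_patches(patches, caps, spec)
}

# extrude a base polyline along direction d into a channel patch of length
# len + ext; cells beyond len are flagged as flow extension
extrude_channel <- function(base, d, len, ext, h, region_name) {
  total <- len + ext
  hb <- min(h, 0.8 * max(stats::dist(base[c(1, nrow(base)), ])))
  l_grid <- segmented_axis(c(0, len, total), hb)
  ni <- nrow(base); nj <- length(l_grid)
  # the base polyline is generally skewed/curved relative to d (arc sag on
  # the arch, oblique split rows); blend in an axial correction so the end
  # row is exactly perpendicular to d (planar outlet cross-section)
  proj <- as.numeric(base %*% d)
  corr <- mean(proj) - proj
  lmat <- outer(rep(1, ni), l_grid) + outer(corr, l_grid / total)
  X <- outer(base[, 1], rep(1, nj)) + d[1] * lmat
  Y <- outer(base[, 2], rep(1, nj)) + d[2] * lmat
  cells <- grid_triangles(ni, nj)
  quad <- grid_triangle_quad(ni, nj)
  qj <- (quad - 1L) %/% (ni - 1L) + 1L
  l_mid <- (l_grid[-1] + l_grid[-nj]) / 2
  extension <- l_mid[qj] > len
  list(patches = list(list(nodes = cbind(as.numeric(X), as.numeric(Y)),
                           cells = cells,
                           region = rep(region_name, nrow(cells)),
                           extension = extension,
                           cell_s = rep(NA_real_, nrow(cells)),
                           cell_q = rep(NA_real_, nrow(cells)))),
       top = cbind(X[, nj], Y[, nj]))
}

end_cap <- function(bp, d, tag, radius) {
  top <- bp$top
  list(tag = tag, point = colMeans(top), normal = d, radius = radius)
}

rot2 <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                         sin(a) * v[1] + cos(a) * v[2])

# closed side-pouch patch for the aneurysm sac: extrude the neck-span base
# outward by the bulge depth, tapering the width toward a rounded dome; no
# cap tag is attached, so the topological boundary stays no-slip wall
sac_pouch <- function(base, d, an, h) {
  L <- an$bulge_radius
  hb <- min(h, L / 4)
  l_grid <- seq(0, L, length.out = max(4L, ceiling(L / hb)) + 1L)
  ni <- nrow(base); nj <- length(l_grid)
  proj <- as.numeric(base %*% d)
  corr <- mean(proj) - proj          # flatten the curved base outward
  mid <- colMeans(base)
  # dome taper: full neck width at the base, ~55% near the dome
  f <- 1 - 0.45 * (l_grid / L)^2
  X <- matrix(0, ni, nj); Y <- matrix(0, ni, nj)
  for (j in seq_len(nj)) {
    lx <- l_grid[j] + corr * (l_grid[j] / L)
    X[, j] <- mid[1] + (base[, 1] - mid[1]) * f[j] + d[1] * lx
    Y[, j] <- mid[2] + (base[, 2] - mid[2]) * f[j] + d[2] * lx
  }
  cells <- grid_triangles(ni, nj)
  list(nodes = cbind(as.numeric(X), as.numeric(Y)), cells = cells,
       region = rep("aneurysm", nrow(cells)),
       extension = rep(FALSE, nrow(cells)),
       cell_s = rep(NA_real_, nrow(cells)),
       cell_q = rep(NA_real_, nrow(cells)))
}

# IA channel that bifurcates into RSA and RCCA half-channels
build_ia_tree <- function(spec, base, dirv, h) {
  bif <- spec$ia_bifurcation
  ia <- extrude_channel(base, dirv, bif$split_length, 0, h, "IA")
  top <- ia$top
  m <- nrow(top)
  stopifnot(m %% 2L == 1L)  # even cell count => odd node count
  half <- (m + 1L) %/% 2L
  ext_b <- spec$extension_factor * 2 * bif$branch_radius
  d1 <- rot2(dirv, bif$angle)
  d2 <- rot2(dirv, -bif$angle)
  b1 <- extrude_channel(top[1:half, , drop = FALSE], d1,
                        bif$branch_length, ext_b, h, "RSA")
  b2 <- extrude_channel(top[half:m, , drop = FALSE], d2,
                        bif$branch_length, ext_b, h, "RCCA")
  list(patches = c(ia$patches, b1$patches, b2$patches),
       caps = list(end_cap(b1, d1, "outlet:RSA", 1.5 * bif$branch_radius),
                   end_cap(b2, d2, "outlet:RCCA", 1.5 * bif$branch_radius)))
}

assemble_patches <- function(patches, caps, spec) {
  offs <- 0L
  nodes <- NULL; cells <- NULL
  region <- character(); extension <- logical()
  cell_s <- numeric(); cell_q <- numeric()
  for (p in patches) {
    nodes <- rbind(nodes, p$nodes)
    cells <- rbind(cells, p$cells + offs)
    offs <- offs + nrow(p$nodes)
    region <- c(region, p$region)
    extension <- c(extension, p$extension)
    cell_s <- c(cell_s, p$cell_s)
    cell_q <- c(cell_q, p$cell_q)
  }
  w <- weld_nodes(nodes, cells)
  labeled_mesh(w$nodes, w$cells, caps = caps,
               cell_region = region, cell_extension = extension,
               tol = 1e-7,
               meta = list(spec = spec, cell_s = cell_s, cell_q = cell_q,
                           mode = "planar"))
}

# ---- verification meshes ----------------------------------------------------

#' Planar channel mesh
#'
#' Rectangular channel \code{[0, length] x [-height/2, height/2]} with graded
#' wall spacing, for analytic verification runs (plane Poiseuille, Couette,
#' oscillatory Stokes-layer flow).
#'
#' @param length,height channel dimensions (m).
#' @param h target core element size (m).
#' @param n_bl,ratio boundary-layer count and grading ratio.
#' @param left,right tags for the two end caps (e.g. two pressure outlets for
#'   oscillatory forcing).
#' @return a [labeled_mesh()].
#' @export
mesh_channel_2d <- function(length, height, h, n_bl = 6, ratio = 1.2,
                            left = "inlet", right = "outlet:descending") {
  x <- seq(0, length, by = min(h, length / 4))
  if (abs(x[base::length(x)] - length) > 1e-12) x <- c(x, length)
  y <- graded_spacing(height, h, n_bl, ratio) - height / 2
  ni <- base::length(x); nj <- base::length(y)
  nodes <- cbind(rep(x, nj), rep(y, each = ni))
  cells <- grid_triangles(ni, nj)
  caps <- list(
    list(tag = left, point = c(0, 0), normal = c(1, 0), radius = height),
    list(tag = right, point = c(length, 0), normal = c(1, 0), radius = height))
  labeled_mesh(nodes, cells, caps = caps,
               meta = list(mode = "planar", h = h))
}

#' Symmetric bifurcating channel (planar Y fixture)
#'
#' A vertical trunk channel whose top edge splits into two mirrored daughter
#' channels of half width at \code{+/-angle}; by symmetry the flow split is
#' 50/50, which makes it an oracle for per-outlet flux integration.
#'
#' @param width trunk width (m).
#' @param trunk_length,branch_length lengths (m).
#' @param angle daughter channel half-angle (rad).
#' @param h target element size (m).
#' @return a [labeled_mesh()] with outlets \code{outlet:RSA}/\code{outlet:RCCA}.
#' @export
mesh_bifurcating_channel_2d <- function(width = 0.01, trunk_length = 0.03,
                                        branch_length = 0.03, angle = 0.4,
                                        h = 0.001) {
  nx <- max(4L, ceiling(width / h)); if (nx %% 2L == 1L) nx <- nx + 1L
  xs <- seq(-width / 2, width / 2, length.out = nx + 1L)
  ys <- seq(0, trunk_length, by = min(h, trunk_length / 4))
  if (abs(ys[length(ys)] - trunk_length) > 1e-12) ys <- c(ys, trunk_length)
  ni <- length(xs); nj <- length(ys)
  nodes <- cbind(rep(xs, nj), rep(ys, each = ni))
  cells <- grid_triangles(ni, nj)
  trunkp <- list(nodes = nodes, cells = cells,
                 region = rep("trunk", nrow(cells)),
                 extension = rep(FALSE, nrow(cells)),
                 cell_s = rep(NA_real_, nrow(cells)),
                 cell_q = rep(NA_real_, nrow(cells)))
  top <- cbind(xs, trunk_length)
  half <- (ni + 1L) %/% 2L
  d1 <- rot2(c(0, 1), angle)
  d2 <- rot2(c(0, 1), -angle)
  b1 <- extrude_channel(top[1:half, , drop = FALSE], d1, branch_length, 0, h, "RSA")
  b2 <- extrude_channel(top[half:ni, , drop = FALSE], d2, branch_length, 0, h, "RCCA")
  caps <- list(
    list(tag = "inlet", point = c(0, 0), normal = c(0, 1), radius = width),
    end_cap(b1, d1, "outlet:RSA", width),
    end_cap(b2, d2, "outlet:RCCA", width))
  assemble_patches(c(list(trunkp), b1$patches, b2$patches), caps,
                   spec = NULL)
}

# ---- 3D tube sweep ----------------------------------------------------------

# disc cross-section: center node + rings with graded radial spacing near the
# wall; returns local 2D coords and triangles
disc_section <- function(R, h, n_bl, ratio) {
  hr <- 0.6 * h          # radial spacing finer than circumferential: the
                         # profile curvature lives in the radial direction
  t1 <- hr / ratio^(n_bl - 1)
  bl_total <- t1 * (ratio^n_bl - 1) / (ratio - 1)
  cap <- 0.4 * R
  if (bl_total > cap) { t1 <- t1 * cap / bl_total; bl_total <- cap }
  wl <- rev(t1 * ratio^(seq_len(n_bl) - 1))  # decreasing toward the wall
  core_len <- R - bl_total
  n_core <- max(2L, round(core_len / hr))   # resolve the core profile
  widths <- c(rep(core_len / n_core, n_core), wl)
  radii <- cumsum(widths) * (R / sum(widths))
  ncirc <- max(12L, ceiling(2 * pi * R / h))
  ang <- 2 * pi * (seq_len(ncirc) - 1) / ncirc
  pts <- rbind(c(0, 0),
               do.call(rbind, lapply(radii, function(r) cbind(r * cos(ang), r * sin(ang)))))
  ring_id <- function(i, k) 1L + (i - 1L) * ncirc + ((k - 1L) %% ncirc) + 1L
  tris <- do.call(rbind, lapply(seq_len(ncirc), function(k)
    c(1L, ring_id(1L, k), ring_id(1L, k + 1L))))
  for (i in seq_len(length(radii) - 1L)) {
    for (k in seq_len(ncirc)) {
      a <- ring_id(i, k); b <- ring_id(i + 1L, k)
      cc <- ring_id(i + 1L, k + 1L); dd <- ring_id(i, k + 1L)
      tris <- rbind(tris, c(a, b, cc), c(a, cc, dd))
    }
  }
  list(points = pts, tris = tris)
}

# split a prism (bottom a b c, top d e f; d above a, ...) into 3 tets with
# globally consistent quad-face diagonals (diagonal through the smallest
# global vertex of each quad face)
split_prisms <- function(pris) {
  # pris: n x 6 matrix of global node ids
  out <- matrix(0L, 3L * nrow(pris), 4L)
  for (r in seq_len(nrow(pris))) {
    v <- pris[r, ]
    w <- which.min(v)
    if (w > 3L) {            # flip upside down (orientation-preserving relabel)
      v <- v[c(4L, 6L, 5L, 1L, 3L, 2L)]
      w <- which.min(v)
    }
    if (w == 2L) v <- v[c(2L, 3L, 1L, 5L, 6L, 4L)]
    if (w == 3L) v <- v[c(3L, 1L, 2L, 6L, 4L, 5L)]
    if (min(v[2], v[6]) < min(v[3], v[5])) {
      tets <- rbind(c(v[1], v[2], v[3], v[6]),
                    c(v[1], v[2], v[6], v[5]),
                    c(v[1], v[5], v[6], v[4]))
    } else {
      tets <- rbind(c(v[1], v[2], v[3], v[5]),
                    c(v[1], v[5], v[3], v[6]),
                    c(v[1], v[5], v[6], v[4]))
    }
    out[(3L * r - 2L):(3L * r), ] <- tets
  }
  out
}

#' Tetrahedral tube mesh
#'
#' Sweeps a boundary-layer-graded disc cross-section along a straight axis
#' (z from 0 to \code{length}) into a tetrahedral tube with tagged inlet
#' (z = 0), outlet (z = length) and wall.
#'
#' @param radius tube radius (m).
#' @param length tube length (m).
#' @param h target core element size (m).
#' @param n_bl,ratio radial boundary-layer count and grading ratio.
#' @param outlet_tag tag for the z = length cap.
#' @return a [labeled_mesh()] of tetrahedra.
#' @export
mesh_tube_3d <- function(radius, length, h, n_bl = 6, ratio = 1.2,
                         outlet_tag = "outlet:descending") {
  sec <- disc_section(radius, h, n_bl, ratio)
  npts <- nrow(sec$points)
  # axial spacing coarser than the cross-section: tube flow is axially smooth
  z <- seq(0, length, length.out = max(2L, ceiling(length / (1.4 * h))) + 1L)
  nz <- base::length(z)
  nodes <- cbind(sec$points[rep(seq_len(npts), nz), , drop = FALSE],
                 rep(z, each = npts))
  pris <- NULL
  for (l in seq_len(nz - 1L)) {
    lo <- (l - 1L) * npts
    hi <- l * npts
    pris <- rbind(pris, cbind(sec$tris + lo, sec$tris + hi))
  }
  tets <- split_prisms(pris)
  caps <- list(
    list(tag = "inlet", point = c(0, 0, 0), normal = c(0, 0, 1),
         radius = 1.5 * radius),
    list(tag = outlet_tag, point = c(0, 0, length), normal = c(0, 0, 1),
         radius = 1.5 * radius))
  labeled_mesh(nodes, tets, caps = caps,
               meta = list(mode = "tube3d", h = h, radius = radius,
                           length = length))
}

# 3D sweep of the trunk for branch-free specs (degenerate straight tube or
# pure arch); planar frame + out-of-plane axis, no torsion
build_trunk_tube3d <- function(spec) {
  if (any(spec$branches$present))
    stop("tube3d mode supports branch-free specs only (branches: ",
         paste(spec$branches$name[spec$branches$present], collapse = ", "), ")")
  if (!is.null(spec$aneurysm))
    stop("tube3d mode supports specs without an aneurysm sac")
  R <- spec$lumen_radius
  h <- spec$mesh_size
  ext <- spec$extension_factor * 2 * R
  s_end <- trunk_length(spec)
  sec <- disc_section(R, h, spec$boundary_layer_count, spec$boundary_layer_ratio)
  s_grid <- segmented_axis(unique(c(-ext, 0, spec$ascending_length,
                                    spec$ascending_length + arch_span(spec),
                                    s_end, s_end + ext)), h)
  fr <- trunk_frame(spec, s_grid)
  npts <- nrow(sec$points)
  ns <- length(s_grid)
  nodes <- matrix(0, npts * ns, 3)
  for (i in seq_len(ns)) {
    rows <- (i - 1L) * npts + seq_len(npts)
    nodes[rows, 1] <- fr$point[i, 1] + fr$normal[i, 1] * sec$points[, 1]
    nodes[rows, 2] <- fr$point[i, 2] + fr$normal[i, 2] * sec$points[, 1]
    nodes[rows, 3] <- sec$points[, 2]
  }
  pris <- NULL
  for (l in seq_len(ns - 1L)) {
    lo <- (l - 1L) * npts
    hi <- l * npts
    pris <- rbind(pris, cbind(sec$tris + lo, sec$tris + hi))
  }
  tets <- split_prisms(pris)
  region <- rep("trunk", nrow(tets))
  s_mid <- (s_grid[-1] + s_grid[-ns]) / 2
  cell_s <- s_mid[rep(seq_len(ns - 1L), each = 3L * nrow(sec$tris))]
  extension <- cell_s < 0 | cell_s > s_end
  tg0 <- as.numeric(trunk_frame(spec, -ext)$tangent)
  tg1 <- as.numeric(trunk_frame(spec, s_end + ext)$tangent)
  caps <- list(
    list(tag = "inlet", point = c(trunk_frame(spec, -ext)$point, 0),
         normal = c(tg0, 0), radius = 1.5 * R),
    list(tag = "outlet:descending",
         point = c(trunk_frame(spec, s_end + ext)$point, 0),
         normal = c(tg1, 0), radius = 1.5 * R))
  labeled_mesh(nodes, tets, caps = caps,
               cell_region = region, cell_extension = extension,
               tol = 1e-7,
               meta = list(spec = spec, mode = "tube3d", cell_s = cell_s))
}
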