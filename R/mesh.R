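#' Labeled unstructured mesh
#'
#' Simplex mesh (triangles in planar mode, tetrahedra in 3D) with tagged
#' boundary facets. The boundary is extracted topologically (facets belonging
#' to exactly one cell), oriented outward, and tagged by matching against the
#' cap planes recorded by the generator; everything not on a cap is a no-slip
#' wall. Wall facets inherit an anatomical region label and a flow-extension
#' flag from their adjacent cell, so that area statistics can exclude the
#' numerical flow extensions.
#'
#' @param nodes numeric matrix N x d of coordinates (m), d = 2 or 3.
#' @param cells integer matrix M x (d+1), 1-based connectivity.
#' @param caps list of cap descriptors \code{list(tag, point, normal, radius)}:
#'   a boundary facet whose nodes all lie on the cap plane (within \code{tol})
#'   and within \code{radius} of \code{point} receives \code{tag}.
#' @param cell_region character vector (length M) of anatomical labels;
#'   defaults to \code{"wall"}.
#' @param cell_extension logical vector (length M): cell belongs to a flow
#'   extension; defaults to FALSE.
#' @param tol plane-matching tolerance (m).
#' @param meta free-form list (generator spec, grid metadata, ...).
#' @return object of class \code{labeled_mesh}.
#' @export
labeled_mesh <- function(nodes, cells, caps = list(),
                         cell_region = NULL, cell_extension = NULL,
                         tol = 1e-8, meta = list()) {
  nodes <- as.matrix(nodes)
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  d <- ncol(nodes)
  stopifnot(d %in% c(2L, 3L), ncol(cells) == d + 1L)
  cells <- orient_cells(nodes, cells)
  vol <- cell_volumes(nodes, cells)
  if (any(vol <= 0)) stop("mesh contains non-positive-volume cells")
  bnd <- extract_boundary(nodes, cells)
  tag <- tag_facets(nodes, bnd$facets, caps, tol)
  cr <- cell_region %||% rep("wall", nrow(cells))
  ce <- cell_extension %||% rep(FALSE, nrow(cells))
  structure(list(
    dim = d, nodes = nodes, cells = cells, cell_volume = vol,
    facets = bnd$facets, facet_cell = bnd$facet_cell,
    facet_area = bnd$area, facet_normal = bnd$normal,
    facet_tag = tag,
    facet_region = cr[bnd$facet_cell],
    facet_extension = ce[bnd$facet_cell],
    cell_region = cr, cell_extension = ce,
    meta = meta), class = "labeled_mesh")
}

# signed simplex volumes (areas in 2D)
cell_volumes <- function(nodes, cells) {
  d <- ncol(nodes)
  p0 <- nodes[cells[, 1], , drop = FALSE]
  if (d == 2) {
    e1 <- nodes[cells[, 2], , drop = FALSE] - p0
    e2 <- nodes[cells[, 3], , drop = FALSE] - p0
    (e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / 2
  } else {
    e1 <- nodes[cells[, 2], , drop = FALSE] - p0
    e2 <- nodes[cells[, 3], , drop = FALSE] - p0
    e3 <- nodes[cells[, 4], , drop = FALSE] - p0
    (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
     e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
     e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])) / 6
  }
}

# flip inverted cells so all volumes are positive
orient_cells <- function(nodes, cells) {
  vol <- cell_volumes(nodes, cells)
  neg <- vol < 0
  if (any(neg)) cells[neg, c(1, 2)] <- cells[neg, c(2, 1)]
  cells
}

# facets used by exactly one cell, with adjacent cell, outward normal, area
extract_boundary <- function(nodes, cells) {
  d <- ncol(nodes)
  m <- nrow(cells)
  if (d == 2) {
    loc <- rbind(c(1, 2), c(2, 3), c(3, 1))
  } else {
    loc <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  }
  nf <- nrow(loc)
  faces <- do.call(rbind, lapply(seq_len(nf), function(k)
    cells[, loc[k, ], drop = FALSE]))
  owner <- rep(seq_len(m), times = nf)
  key <- apply(faces, 1, function(r) paste(sort(r), collapse = "_"))
  cnt <- table(key)
  on_bnd <- cnt[key] == 1L
  fb <- faces[on_bnd, , drop = FALSE]
  ob <- owner[on_bnd]
  # geometry
  if (d == 2) {
    e <- nodes[fb[, 2], , drop = FALSE] - nodes[fb[, 1], , drop = FALSE]
    area <- sqrt(rowSums(e^2))
    nrm <- cbind(e[, 2], -e[, 1]) / area
  } else {
    e1 <- nodes[fb[, 2], , drop = FALSE] - nodes[fb[, 1], , drop = FALSE]
    e2 <- nodes[fb[, 3], , drop = FALSE] - nodes[fb[, 1], , drop = FALSE]
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    area <- sqrt(rowSums(cr^2)) / 2
    nrm <- cr / (2 * area)
  }
  # outward orientation: away from the adjacent cell centroid
  cc <- cell_centroids(nodes, cells)[ob, , drop = FALSE]
  fm <- facet_midpoints(nodes, fb)
  flip <- rowSums((fm - cc) * nrm) < 0
  nrm[flip, ] <- -nrm[flip, , drop = FALSE]
  list(facets = fb, facet_cell = ob, area = area, normal = nrm)
}

cell_centroids <- function(nodes, cells) {
  d1 <- ncol(cells)
  out <- nodes[cells[, 1], , drop = FALSE]
  for (k in 2:d1) out <- out + nodes[cells[, k], , drop = FALSE]
  out / d1
}

facet_midpoints <- function(nodes, facets) {
  d1 <- ncol(facets)
  out <- nodes[facets[, 1], , drop = FALSE]
  for (k in 2:d1) out <- out + nodes[facets[, k], , drop = FALSE]
  out / d1
}

tag_facets <- function(nodes, facets, caps, tol) {
  tag <- rep("wall", nrow(facets))
  if (!length(caps)) return(tag)
  for (cap in caps) {
    p0 <- cap$point
    nv <- cap$normal / sqrt(sum(cap$normal^2))
    rad <- cap$radius %||% Inf
    ok <- rep(TRUE, nrow(facets))
    for (k in seq_len(ncol(facets))) {
      dx <- sweep(nodes[facets[, k], , drop = FALSE], 2, p0)
      dist_plane <- abs(as.numeric(dx %*% nv))
      dist_rad <- sqrt(pmax(rowSums(dx^2) - dist_plane^2, 0))
      ok <- ok & dist_plane < tol & dist_rad <= rad + tol
    }
    tag[ok] <- cap$tag
  }
  tag
}

#' Check mesh watertightness
#'
#' The boundary of a closed volume satisfies
#' \eqn{\oint \vec n\,dA = \vec 0}; returns the magnitude of the summed
#' outward area vectors relative to the total boundary area.
#'
#' @param mesh a [labeled_mesh()].
#' @return non-negative scalar; ~1e-16 for a watertight boundary.
#' @export
watertightness <- function(mesh) {
  s <- colSums(mesh$facet_normal * mesh$facet_area)
  sqrt(sum(s^2)) / sum(mesh$facet_area)
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat(if (x$dim == 2) "Planar" else "3D", "labeled mesh:",
      nrow(x$nodes), "nodes,", nrow(x$cells),
      if (x$dim == 2) "triangles," else "tetrahedra,",
      nrow(x$facets), "boundary facets\n")
  tt <- table(x$facet_tag)
  cat("  tags:", paste(sprintf("%s (%d)", names(tt), tt), collapse = ", "), "\n")
  cat("  watertightness:", format(watertightness(x), digits = 3), "\n")
  invisible(x)
}

#' @export
summary.labeled_mesh <- function(object, ...) {
  print(object)
  cat("  total volume:", format(sum(object$cell_volume), digits = 6),
      if (object$dim == 2) "m^2" else "m^3", "\n")
  cat("  wall area:", format(sum(object$facet_area[object$facet_tag == "wall"]),
                             digits = 6),
      if (object$dim == 2) "m (per unit depth)" else "m^2", "\n")
  regs <- table(object$facet_region[object$facet_tag == "wall"])
  cat("  wall regions:", paste(names(regs), collapse = ", "), "\n")
  invisible(object)
}

#' @export
plot.labeled_mesh <- function(x, ...) {
  if (x$dim != 2) {
    # 3D: plot boundary facet midpoints colored by tag
    fm <- facet_midpoints(x$nodes, x$facets)
    graphics::plot(fm[, 1], fm[, 3], asp = 1, pch = 16, cex = 0.3,
                   col = as.integer(factor(x$facet_tag)),
                   xlab = "x (m)", ylab = "z (m)", ...)
    return(invisible(x))
  }
  graphics::plot(NA, xlim = range(x$nodes[, 1]), ylim = range(x$nodes[, 2]),
                 asp = 1, xlab = "x (m)", ylab = "y (m)", ...)
  graphics::segments(x$nodes[x$facets[, 1], 1], x$nodes[x$facets[, 1], 2],
                     x$nodes[x$facets[, 2], 1], x$nodes[x$facets[, 2], 2],
                     col = as.integer(factor(x$facet_tag)))
  invisible(x)
}

# weld duplicate nodes (exact up to rounding) and re-index cells
weld_nodes <- function(nodes, cells, digits = 9) {
  key <- apply(round(nodes, digits), 1, paste, collapse = "|")
  first <- !duplicated(key)
  newid <- match(key, key[first])   # new index of every original node
  list(nodes = nodes[first, , drop = FALSE],
       cells = matrix(newid[cells], nrow = nrow(cells)))
}
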