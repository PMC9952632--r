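#' Write a mesh as ASCII VTU
#'
#' Unstructured-grid XML (VTK) with the volume cells, plus cell data for the
#' anatomical region and flow-extension flag and optional extra cell/point
#' fields. Readable by ParaView/VTK and meshio.
#'
#' @param mesh a [labeled_mesh()].
#' @param path output file.
#' @param point_data named list of per-node numeric vectors/matrices.
#' @param cell_data named list of per-cell numeric vectors.
#' @return the path, invisibly.
#' @export
write_mesh_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$cells)
  d <- mesh$dim
  pts <- cbind(mesh$nodes, matrix(0, n, 3 - d))
  vtk_type <- if (d == 2) 5L else 10L   # triangle / tetra
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="', n, '" NumberOfCells="', m, '">')
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  cat(t(pts), file = con); w("")
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int32" Name="connectivity" format="ascii">')
  cat(t(mesh$cells) - 1L, file = con); w("")
  w('</DataArray><DataArray type="Int32" Name="offsets" format="ascii">')
  cat(seq_len(m) * (d + 1L), file = con); w("")
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  cat(rep(vtk_type, m), file = con); w("")
  w('</DataArray></Cells>')
  cell_data <- c(list(region = as.integer(factor(mesh$cell_region)),
                      extension = as.integer(mesh$cell_extension)), cell_data)
  w('<CellData>')
  for (nm in names(cell_data)) {
    w('<DataArray type="Float64" Name="', nm, '" format="ascii">')
    cat(as.numeric(cell_data[[nm]]), file = con); w("")
    w('</DataArray>')
  }
  w('</CellData>')
  if (length(point_data)) {
    w('<PointData>')
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      nc <- if (is.matrix(v)) ncol(v) else 1L
      w('<DataArray type="Float64" Name="', nm,
        '" NumberOfComponents="', nc, '" format="ascii">')
      cat(if (is.matrix(v)) t(v) else v, file = con); w("")
      w('</DataArray>')
    }
    w('</PointData>')
  }
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}

#' Write a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Volume cells plus tagged boundary facets; boundary tags are exported as
#' physical groups with their names in \code{$PhysicalNames}.
#'
#' @param mesh a [labeled_mesh()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_mesh_msh <- function(mesh, path) {
  d <- mesh$dim
  tags <- sort(unique(mesh$facet_tag))
  tag_id <- stats::setNames(seq_along(tags), tags)
  vol_id <- length(tags) + 1L
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("$MeshFormat"); w("2.2 0 8"); w("$EndMeshFormat")
  w("$PhysicalNames"); w(length(tags) + 1L)
  for (t in tags) w(d - 1L, " ", tag_id[[t]], ' "', t, '"')
  w(d, " ", vol_id, ' "volume"')
  w("$EndPhysicalNames")
  n <- nrow(mesh$nodes)
  w("$Nodes"); w(n)
  pts <- cbind(mesh$nodes, matrix(0, n, 3 - d))
  utils::write.table(cbind(seq_len(n), pts), con, row.names = FALSE,
                     col.names = FALSE)
  w("$EndNodes")
  nf <- nrow(mesh$facets); m <- nrow(mesh$cells)
  ftype <- if (d == 2) 1L else 2L    # line / triangle
  vtype <- if (d == 2) 2L else 4L    # triangle / tetra
  w("$Elements"); w(nf + m)
  for (i in seq_len(nf)) {
    id <- tag_id[[mesh$facet_tag[i]]]
    w(paste(c(i, ftype, 2L, id, id, mesh$facets[i, ]), collapse = " "))
  }
  for (i in seq_len(m)) {
    w(paste(c(nf + i, vtype, 2L, vol_id, vol_id, mesh$cells[i, ]),
            collapse = " "))
  }
  w("$EndElements")
  invisible(path)
}

#' Serialize an arch case spec to a YAML file
#'
#' Plain-text configuration mirroring the spec fields (SI units), readable
#' back with [read_case_spec()].
#'
#' @param spec an [arch_case_spec()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_case_spec <- function(spec, path) {
  x <- unclass(spec)
  x$branches <- as.list(as.data.frame(x$branches))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read an arch case spec from YAML
#'
#' @param path file written by [write_case_spec()] (or hand-edited).
#' @return an [arch_case_spec()].
#' @export
read_case_spec <- function(path) {
  x <- yaml::read_yaml(path)
  br <- if (length(x$branches$name)) as.data.frame(x$branches) else NULL
  arch_case_spec(case_label = x$case_label, lumen_radius = x$lumen_radius,
                 ascending_length = x$ascending_length,
                 descending_length = x$descending_length,
                 arch_curvature_radius = x$arch_curvature_radius,
                 branches = br, ia_bifurcation = x$ia_bifurcation,
                 aneurysm = x$aneurysm,
                 extension_factor = x$extension_factor,
                 boundary_layer_count = x$boundary_layer_count,
                 boundary_layer_ratio = x$boundary_layer_ratio,
                 mesh_size = x$mesh_size)
}

#' Write a wall shear stress time series as CSV
#'
#' Long-format table (facet, time, tx, ty, tz) of the tangential traction
#' vectors.
#'
#' @param wss a [wall_shear_field()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_wss_csv <- function(wss, path) {
  nf <- dim(wss$traction)[1]; nt <- dim(wss$traction)[3]
  out <- data.frame(
    facet = rep(wss$facet_ids, nt),
    time = rep(wss$times, each = nf),
    tx = as.numeric(wss$traction[, 1, ]),
    ty = as.numeric(wss$traction[, 2, ]),
    tz = as.numeric(wss$traction[, 3, ]))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write the wall surface with index maps as ASCII VTU
#'
#' Boundary wall facets (line cells in planar mode, triangles in 3D) with
#' per-facet TAWSS, OSI, RRT and the three risk masks as cell data.
#'
#' @param mesh a [labeled_mesh()].
#' @param maps an [compute_index_maps()] result on that mesh.
#' @param path output file.
#' @param thresholds risk thresholds for the mask fields.
#' @return the path, invisibly.
#' @export
write_wall_vtu <- function(mesh, maps, path,
                           thresholds = c(tawss_low = 0.4, osi_high = 0.25,
                                          rrt_high = 5)) {
  f <- mesh$facets[maps$facet_ids, , drop = FALSE]
  d <- mesh$dim
  n <- nrow(mesh$nodes); m <- nrow(f)
  pts <- cbind(mesh$nodes, matrix(0, n, 3 - d))
  vtk_type <- if (d == 2) 3L else 5L    # line / triangle
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="', n, '" NumberOfCells="', m, '">')
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  cat(t(pts), file = con); w("")
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int32" Name="connectivity" format="ascii">')
  cat(t(f) - 1L, file = con); w("")
  w('</DataArray><DataArray type="Int32" Name="offsets" format="ascii">')
  cat(seq_len(m) * d, file = con); w("")
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  cat(rep(vtk_type, m), file = con); w("")
  w('</DataArray></Cells>')
  fields <- list(tawss = maps$tawss, tau_mean = maps$tau_mean,
                 osi = maps$osi, rrt = maps$rrt,
                 mask_low_tawss = as.numeric(maps$tawss < thresholds[["tawss_low"]]),
                 mask_high_osi = as.numeric(maps$osi > thresholds[["osi_high"]]),
                 mask_high_rrt = as.numeric(maps$rrt > thresholds[["rrt_high"]] |
                                              maps$rrt_infinite))
  w('<CellData>')
  for (nm in names(fields)) {
    w('<DataArray type="Float64" Name="', nm, '" format="ascii">')
    cat(fields[[nm]], file = con); w("")
    w('</DataArray>')
  }
  w('</CellData>')
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}
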