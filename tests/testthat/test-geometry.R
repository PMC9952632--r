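specs <- default_case_specs()

test_that("the four presets satisfy the morphological stage invariants", {
  expect_named(specs, c("normal", "preop", "postop1w", "postop6m"))
  for (s in specs) expect_silent(validate_arch_case_spec(s))
  expect_null(specs$normal$aneurysm)
  expect_false(is.null(specs$preop$aneurysm))
  br <- function(s, nm) s$branches[s$branches$name == nm, ]
  expect_true(br(specs$normal, "LSA")$present)
  expect_false(br(specs$postop1w, "LSA")$present)
  expect_false(br(specs$postop6m, "LSA")$present)
  # postoperative ostia relocate proximally (smaller arc coordinate)
  for (nm in c("IA", "LCCA")) {
    expect_lt(br(specs$postop1w, nm)$ostium_s, br(specs$preop, nm)$ostium_s)
    expect_lt(br(specs$postop6m, nm)$ostium_s, br(specs$preop, nm)$ostium_s)
  }
  # curvature radius dips at 1 week and partially recovers by 6 months
  expect_lt(specs$postop1w$arch_curvature_radius,
            specs$postop6m$arch_curvature_radius)
  expect_lte(specs$postop6m$arch_curvature_radius,
             specs$normal$arch_curvature_radius)
  expect_lt(specs$postop1w$arch_curvature_radius,
            specs$normal$arch_curvature_radius)
  for (s in specs) {
    expect_gt(s$arch_curvature_radius, s$lumen_radius)
    expect_true(all(s$branches$radius < s$lumen_radius))
  }
})

test_that("infeasible geometry is refused with the offending parts named", {
  br <- data.frame(name = c("LCCA", "LSA"), ostium_s = c(0.09, 0.095),
                   radius = c(0.004, 0.004), length = c(0.03, 0.03),
                   present = c(TRUE, TRUE))
  expect_error(arch_case_spec("bad", branches = br), "LCCA/LSA")
  br2 <- data.frame(name = "LSA", ostium_s = 0.112, radius = 0.004,
                    length = 0.03, present = TRUE)
  expect_error(
    arch_case_spec("bad", branches = br2,
                   aneurysm = list(center_s = 0.113, bulge_radius = 0.02,
                                   neck_halfwidth = 0.01)),
    "aneurysm intersects branch: LSA")
  expect_error(arch_case_spec("bad", lumen_radius = 0.02,
                              arch_curvature_radius = 0.015),
               "arch_curvature_radius")
})

test_that("planar case meshes carry the expected outlets and are watertight", {
  m <- build_case_geometry(specs$normal)
  tags <- unique(m$facet_tag)
  for (o in c("outlet:RSA", "outlet:RCCA", "outlet:LCCA", "outlet:LSA",
              "outlet:descending"))
    expect_true(o %in% tags)
  expect_true("inlet" %in% tags)
  expect_lt(watertightness(m), 1e-10)
  expect_true(all(m$cell_volume > 0))

  m1 <- build_case_geometry(specs$postop1w)
  expect_false("outlet:LSA" %in% unique(m1$facet_tag))
  expect_true(all(c("outlet:RSA", "outlet:RCCA", "outlet:LCCA") %in%
                    unique(m1$facet_tag)))
})

test_that("meshing is deterministic", {
  a <- build_case_geometry(specs$preop)
  b <- build_case_geometry(specs$preop)
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$cells, b$cells)
})

test_that("the degenerate straight-tube spec meshes to a cylinder", {
  tube <- arch_case_spec("tube", lumen_radius = 0.004,
                         ascending_length = 0.03, descending_length = 0,
                         arch_curvature_radius = Inf,
                         extension_factor = 0, mesh_size = 0.0012)
  m <- build_case_geometry(tube, mode = "tube3d")
  expect_equal(m$dim, 3L)
  wall_area <- sum(m$facet_area[m$facet_tag == "wall"])
  expect_equal(wall_area, 2 * pi * 0.004 * 0.03, tolerance = 0.02)
  expect_lt(watertightness(m), 1e-10)
})

test_that("3D mode refuses branched or aneurysmal specs by name", {
  expect_error(build_case_geometry(specs$normal, mode = "tube3d"),
               "IA, LCCA, LSA")
})

test_that("halving the mesh size refines consistently", {
  coarse <- build_case_geometry(specs$normal)
  spec_f <- specs$normal; spec_f$mesh_size <- specs$normal$mesh_size / 2
  fine <- build_case_geometry(spec_f)
  expect_gte(nrow(fine$cells), 2 * nrow(coarse$cells))
  a0 <- sum(coarse$facet_area); a1 <- sum(fine$facet_area)
  expect_lt(abs(a1 - a0) / a0, 0.01)
})

test_that("wall facets carry anatomical regions and extension flags", {
  m <- build_case_geometry(specs$preop)
  wall_regions <- unique(m$facet_region[m$facet_tag == "wall"])
  for (r in c("ascending", "arch", "descending", "aneurysm", "IA", "LCCA",
              "LSA", "RSA", "RCCA", "inlet_extension"))
    expect_true(r %in% wall_regions)
  expect_true(any(m$facet_extension))
  # extensions are never part of the anatomical trunk/branch labels
  expect_true(all(m$facet_region[m$facet_extension] %in%
                    c("inlet_extension", "descending_extension",
                      "IA", "RSA", "RCCA", "LCCA", "LSA")))
})

test_that("case specs serialize to YAML and back", {
  path <- tempfile(fileext = ".yaml")
  write_case_spec(specs$preop, path)
  back <- read_case_spec(path)
  expect_equal(back$arch_curvature_radius, specs$preop$arch_curvature_radius)
  expect_equal(back$branches$ostium_s, specs$preop$branches$ostium_s)
  expect_equal(back$aneurysm$bulge_radius, specs$preop$aneurysm$bulge_radius)
  unlink(path)
})

test_that("synthetic traction fixtures obey their closed forms", {
  const <- synthetic_wss_series("constant", offset = 2, n_timesteps = 16)
  expect_true(all(abs(sqrt(apply(const$traction^2, 3, sum)) - 2) < 1e-14))
  rev <- synthetic_wss_series("reversing", amplitude = 1, n_timesteps = 32)
  w <- archflow:::trapezoid_weights(rev$times, 1)
  expect_equal(sum(rev$traction[1, 1, ] * w), 0)
  osc <- synthetic_wss_series("offset_sinusoid", offset = 1, amplitude = 0.5,
                              n_timesteps = 2000)
  mag <- abs(osc$traction[1, 1, ])
  expect_equal(sum(mag * archflow:::trapezoid_weights(osc$times, 1)), 1,
               tolerance = 1e-6)
})

test_that("mesh files export in standard formats", {
  m <- mesh_channel_2d(0.01, 0.005, 0.002)
  v <- tempfile(fileext = ".vtu"); g <- tempfile(fileext = ".msh")
  write_mesh_vtu(m, v, point_data = list(speed = rep(0, nrow(m$nodes))))
  write_mesh_msh(m, g)
  lv <- readLines(v)
  expect_true(any(grepl("UnstructuredGrid", lv)))
  expect_true(any(grepl("speed", lv)))
  lg <- readLines(g)
  expect_true(any(grepl("\\$PhysicalNames", lg)))
  expect_equal(as.integer(lg[which(lg == "$Nodes") + 1]), nrow(m$nodes))
  unlink(c(v, g))
})

test_that("wall-surface and WSS exports write parseable files", {
  m <- mesh_channel_2d(0.01, 0.005, 0.002)
  N <- nrow(m$nodes)
  U <- array(0, dim = c(N, 2, 2))       # steady shear over one closed cycle
  U[, 1, 1] <- U[, 1, 2] <- 3 * m$nodes[, 2]
  f <- flow_field(c(0, 1), U, matrix(0, N, 2))
  wss <- compute_wss(f, m, blood)
  maps <- suppressWarnings(compute_index_maps(wss))
  v <- tempfile(fileext = ".vtu"); cc <- tempfile(fileext = ".csv")
  write_wall_vtu(m, maps, v)
  write_wss_csv(wss, cc)
  expect_true(any(grepl("tawss", readLines(v))))
  tab <- utils::read.csv(cc)
  expect_equal(nrow(tab), length(maps$tawss) * length(wss$times))
  unlink(c(v, cc))
})

test_that("centerline apex alignment is translation-only", {
  specs <- default_case_specs()
  cls <- lapply(specs[c("normal", "postop1w")], extract_centerline)
  al <- align_centerlines(cls)
  for (i in seq_along(al)) {
    expect_equal(max(al[[i]]$points[, 2]), 0)
    # shape preserved: pairwise spacing unchanged
    expect_equal(diff(al[[i]]$points[, 1]), diff(cls[[i]]$points[, 1]))
  }
})
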