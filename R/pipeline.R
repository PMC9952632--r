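#' Pipeline configuration
#'
#' Settings for a full geometry-to-report run over one or more arch cases.
#' Mesh resolution tiers map to target core element sizes: coarse 4 mm
#' (tests and desk-scale comparison), medium 2 mm, fine 1 mm.
#'
#' @param cases case labels to run (subset of the four presets) or a named
#'   list of [arch_case_spec()] objects.
#' @param tier \code{"coarse"}, \code{"medium"} or \code{"fine"}.
#' @param solver [solver_config()]; the default uses a 4 ms step and 2
#'   cycles at coarse tier.
#' @param props [fluid_properties()].
#' @param thresholds risk thresholds passed to [classify_risk_regions()].
#' @param out_dir output directory (created); NULL keeps results in memory
#'   only.
#' @param verbose progress messages.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(cases = c("normal", "preop", "postop1w", "postop6m"),
                            tier = c("coarse", "medium", "fine"),
                            solver = NULL,
                            props = fluid_properties(),
                            thresholds = c(tawss_low = 0.4, osi_high = 0.25,
                                           rrt_high = 5),
                            out_dir = NULL, verbose = FALSE) {
  tier <- match.arg(tier)
  mesh_size <- c(coarse = 0.004, medium = 0.002, fine = 0.001)[[tier]]
  if (is.null(solver))
    solver <- solver_config(time_step = if (tier == "coarse") 0.004 else 0.002,
                            n_cycles = 2, save_stride = 5)
  structure(list(cases = cases, tier = tier, mesh_size = mesh_size,
                 solver = solver, props = props, thresholds = thresholds,
                 out_dir = out_dir, verbose = verbose),
            class = "pipeline_config")
}

# tiny polynomial (djb2-style, 31-bit) string hash for the manifest
fnv1a <- function(s) {
  b <- utf8ToInt(s)
  h <- 5381
  for (x in b) h <- (h * 33 + x) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full hemodynamic pipeline
#'
#' For each requested case: build the lumen mesh, solve the pulsatile cycle,
#' extract wall shear stress, compute the TAWSS/OSI/RRT maps and risk-region
#' report, the per-outlet perfusion summary, the centerline morphometry, the
#' aneurysm-sac backflow probe, and the mass-conservation diagnostic; write
#' standard-format outputs (VTU/MSH mesh, CSV tables, YAML manifest) when
#' \code{out_dir} is set.
#'
#' @param config a [pipeline_config()].
#' @return named list of case bundles (class \code{arch_case_bundle}), each
#'   with elements \code{spec}, \code{mesh}, \code{field}, \code{wss},
#'   \code{maps}, \code{risk}, \code{perfusion}, \code{centerline},
#'   \code{diagnostics}, \code{manifest}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  specs <- if (is.list(config$cases) && inherits(config$cases[[1]], "arch_case_spec")) {
    config$cases
  } else {
    default_case_specs(mesh_size = config$mesh_size)[config$cases]
  }
  inlet <- inlet_velocity_waveform()
  outlet <- outlet_pressure_waveform()
  bundles <- list()
  for (nm in names(specs)) {
    stage <- "geometry"
    bundle <- tryCatch({
      spec <- specs[[nm]]
      if (config$verbose) message("[", nm, "] building geometry")
      mesh <- build_case_geometry(spec)
      stage <- "solve"
      if (config$verbose) message("[", nm, "] solving pulsatile cycle")
      field <- solve_pulsatile(mesh, inlet, outlet, config$props,
                               config$solver, verbose = config$verbose)
      stage <- "wss"
      wss <- compute_wss(field, mesh, config$props)
      stage <- "indices"
      maps <- compute_index_maps(wss)
      risk <- classify_risk_regions(maps, mesh, config$thresholds)
      stage <- "perfusion"
      perf <- outlet_flow_rates(field, mesh,
                                expected = c("RSA", "RCCA", "LCCA", "LSA",
                                             "descending"))
      stage <- "morphology"
      cl <- extract_centerline(spec)
      sb <- sac_backflow(field, mesh)
      diag <- list(
        mass_imbalance = check_mass_conservation(field, mesh),
        waveform_inlet = waveform_diagnostics(inlet),
        waveform_outlet = waveform_diagnostics(outlet),
        watertightness = watertightness(mesh),
        sac_backflow_min = sb$min_axial_velocity,
        sac_backflow_present = sb$backflow_present,
        n_nodes = nrow(mesh$nodes), n_cells = nrow(mesh$cells))
      manifest <- list(
        case = nm, tier = config$tier, mesh_size = config$mesh_size,
        config_hash = fnv1a(paste(deparse(config[c("tier", "mesh_size",
                                                   "thresholds")]),
                                  collapse = "")),
        solver = unclass(config$solver), props = unclass(config$props),
        outlets = sort(unique(mesh$facet_tag[startsWith(mesh$facet_tag,
                                                        "outlet:")])),
        mass_imbalance = diag$mass_imbalance,
        waveform_junction_max = max(diag$waveform_inlet$junctions$jump),
        package_version = as.character(utils::packageVersion("archflow")))
      structure(list(spec = spec, mesh = mesh, field = field, wss = wss,
                     maps = maps, risk = risk, perfusion = perf,
                     centerline = cl, diagnostics = diag,
                     manifest = manifest, tier = config$tier),
                class = "arch_case_bundle")
    }, error = function(e) {
      stop("pipeline stage '", stage, "' failed for case '", nm, "': ",
           conditionMessage(e))
    })
    if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
    bundles[[nm]] <- bundle
  }
  bundles
}

write_bundle <- function(bundle, out_dir) {
  dir <- file.path(out_dir, bundle$manifest$case)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mesh <- bundle$mesh
  # peak-systole nodal fields on the volume mesh
  pk <- which.max(wf_eval(inlet_velocity_waveform(), bundle$field$times))
  write_mesh_vtu(mesh, file.path(dir, "mesh.vtu"),
                 point_data = list(
                   velocity_peak = cbind(matrix(bundle$field$U[, , pk],
                                                ncol = mesh$dim),
                                         matrix(0, nrow(mesh$nodes),
                                                3 - mesh$dim)),
                   pressure_peak = bundle$field$P[, pk]))
  write_mesh_msh(mesh, file.path(dir, "mesh.msh"))
  write_case_spec(bundle$spec, file.path(dir, "spec.yaml"))
  utils::write.csv(bundle$risk$summary, file.path(dir, "risk_regions.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$risk$by_region,
                   file.path(dir, "risk_by_region.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$perfusion),
                   file.path(dir, "perfusion.csv"), row.names = FALSE)
  utils::write.csv(data.frame(x = bundle$centerline$points[, 1],
                              y = bundle$centerline$points[, 2],
                              s = bundle$centerline$s,
                              curvature_radius = bundle$centerline$curvature_radius),
                   file.path(dir, "centerline.csv"), row.names = FALSE)
  utils::write.csv(data.frame(facet = bundle$maps$facet_ids,
                              area = bundle$maps$facet_area,
                              tawss = bundle$maps$tawss,
                              tau_mean = bundle$maps$tau_mean,
                              osi = bundle$maps$osi,
                              rrt = bundle$maps$rrt),
                   file.path(dir, "index_maps.csv"), row.names = FALSE)
  yaml::write_yaml(bundle$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Aneurysm-sac backflow probe
#'
#' Minimum axial (centerline-tangent-aligned) velocity over the cells labeled
#' as the aneurysm sac at the peak-systole snapshot; a negative value means
#' retrograde flow inside the sac.
#'
#' @param field a [flow_field()].
#' @param mesh the case [labeled_mesh()] (planar mode, with sac cell labels).
#' @param threshold retrograde-velocity magnitude (m/s) that counts as
#'   backflow.
#' @return list(\code{min_axial_velocity}, \code{backflow_present},
#'   \code{n_sac_cells}); zero cells when the case has no sac.
#' @export
sac_backflow <- function(field, mesh, threshold = 1e-3) {
  sel <- which(mesh$cell_region == "aneurysm")
  if (!length(sel))
    return(list(min_axial_velocity = NA_real_, backflow_present = FALSE,
                n_sac_cells = 0L))
  spec <- mesh$meta$spec
  pk <- which.max(wf_eval(inlet_velocity_waveform(), field$times))
  U <- matrix(field$U[, , pk], ncol = mesh$dim)
  # axial direction = trunk tangent at the sac center (the pouch cells sit
  # off the trunk parametrization)
  tg <- as.numeric(trunk_frame(spec, spec$aneurysm$center_s)$tangent)
  uax <- vapply(seq_along(sel), function(i) {
    nd <- mesh$cells[sel[i], ]
    sum(colMeans(U[nd, , drop = FALSE]) * tg)
  }, 0)
  list(min_axial_velocity = min(uax),
       backflow_present = min(uax) < -threshold,
       n_sac_cells = length(sel))
}

#' Cross-case comparison table and qualitative ordering flags
#'
#' Builds one row per case with the headline metrics (risk areas, perfusion
#' fractions, minimum arch curvature radius, mass imbalance) and evaluates
#' the qualitative remodeling orderings: preoperative low-TAWSS area at
#' least the normal one, zero LSA perfusion after surgery, the arch
#' curvature radius dipping at 1 week and partially recovering by 6 months,
#' and retrograde flow inside the preoperative aneurysm sac at peak systole.
#'
#' @param bundles named list of bundles from [run_pipeline()], all from the
#'   same resolution tier (mixed tiers are refused).
#' @return object of class \code{arch_comparison}: list with \code{metrics}
#'   data.frame and \code{flags} (named logicals, NA where the needed cases
#'   are missing; equality counts as a tie and is reported in
#'   \code{ties}).
#' @export
compare_cases <- function(bundles) {
  stopifnot(length(bundles) >= 1)
  tiers <- unique(vapply(bundles, function(b) b$tier, ""))
  if (length(tiers) > 1)
    stop("mixed-tier comparison refused: ", paste(tiers, collapse = ", "))
  frac <- function(b, o) {
    i <- match(o, b$perfusion$outlet)
    if (is.na(i)) NA_real_ else b$perfusion$fraction[i]
  }
  risk_area <- function(b, cr)
    b$risk$summary$area_cm2[b$risk$summary$criterion == cr]
  metrics <- do.call(rbind, lapply(names(bundles), function(nm) {
    b <- bundles[[nm]]
    data.frame(
      case = nm,
      low_tawss_area_cm2 = risk_area(b, "tawss_low"),
      high_osi_area_cm2 = risk_area(b, "osi_high"),
      high_rrt_area_cm2 = risk_area(b, "rrt_high"),
      min_curvature_radius_mm = min_arch_curvature_radius(b$spec) * 1e3,
      lsa_fraction = frac(b, "LSA"),
      cerebral_fraction = sum(frac(b, "RCCA"), frac(b, "LCCA"), na.rm = TRUE),
      mass_imbalance = b$diagnostics$mass_imbalance,
      sac_backflow_min = b$diagnostics$sac_backflow_min)
  }))
  g <- function(nm) if (nm %in% metrics$case)
    metrics[metrics$case == nm, , drop = FALSE] else NULL
  nrm <- g("normal"); pre <- g("preop")
  p1 <- g("postop1w"); p6 <- g("postop6m")
  flags <- list(
    preop_low_tawss_ge_normal =
      if (!is.null(pre) && !is.null(nrm))
        pre$low_tawss_area_cm2 >= nrm$low_tawss_area_cm2 else NA,
    postop_lsa_zero =
      if (!is.null(p1) || !is.null(p6))
        all(c(p1$lsa_fraction, p6$lsa_fraction) == 0) else NA,
    curvature_order_1w_lt_6m =
      if (!is.null(p1) && !is.null(p6))
        p1$min_curvature_radius_mm < p6$min_curvature_radius_mm else NA,
    curvature_order_6m_le_normal =
      if (!is.null(p6) && !is.null(nrm))
        p6$min_curvature_radius_mm <= nrm$min_curvature_radius_mm else NA,
    preop_sac_backflow =
      if (!is.null(pre)) isTRUE(pre$sac_backflow_min < -1e-3) else NA)
  ties <- list(
    low_tawss = if (!is.null(pre) && !is.null(nrm))
      pre$low_tawss_area_cm2 == nrm$low_tawss_area_cm2 else NA,
    curvature = if (!is.null(p1) && !is.null(p6))
      p1$min_curvature_radius_mm == p6$min_curvature_radius_mm else NA)
  structure(list(metrics = metrics, flags = flags, ties = ties,
                 tier = tiers),
            class = "arch_comparison")
}

#' @export
print.arch_comparison <- function(x, ...) {
  cat("Cross-case comparison (tier: ", x$tier, ")\n", sep = "")
  print(x$metrics, row.names = FALSE, digits = 4)
  cat("ordering flags:\n")
  for (nm in names(x$flags))
    cat("  ", nm, ": ", format(x$flags[[nm]]), "\n", sep = "")
  invisible(x)
}
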