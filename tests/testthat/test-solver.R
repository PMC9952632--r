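# Verification problems with analytic oracles for the flow solver and the
# wall-shear extraction. Meshes are kept small; quantitative tolerances come
# from the closed forms.

test_that("steady plane Poiseuille flow is recovered", {
  H <- 0.01; L <- 0.03
  m <- mesh_channel_2d(L, H, 0.001)
  ubar <- 0.05
  f <- solve_steady(m, ubar * H, blood)
  # centerline peak of the parabolic profile
  umax <- max(sqrt(rowSums(f$U[, , 1]^2)))
  expect_equal(umax / ubar, 1.5, tolerance = 0.05)
  # wall shear 6*mu*ubar/H away from the ends
  wss <- compute_wss(f, m, blood)
  tw <- sqrt(rowSums(wss$traction[, , 1]^2))
  mid <- archflow:::facet_midpoints(m$nodes,
                                    m$facets[wss$facet_ids, , drop = FALSE])
  sel <- mid[, 1] > L / 4 & mid[, 1] < 3 * L / 4
  expect_equal(mean(tw[sel]), 6 * blood$dynamic_viscosity * ubar / H,
               tolerance = 0.04)
  # discrete global continuity holds to solver precision
  expect_lt(check_mass_conservation(f, m), 1e-6)
})

test_that("zero inflow yields the rest state", {
  m <- mesh_channel_2d(0.01, 0.005, 0.002)
  f <- solve_steady(m, 0, blood)
  expect_true(all(f$U == 0))
  expect_equal(diff(range(f$P)), 0)
})

test_that("the creeping-flow limit scales linearly with the flow rate", {
  m <- mesh_channel_2d(0.01, 0.004, 0.001)
  q0 <- 1e-7   # Re << 1
  f1 <- solve_steady(m, q0, blood)
  f2 <- solve_steady(m, 2 * q0, blood)
  err <- max(abs(f2$U[, , 1] - 2 * f1$U[, , 1])) / max(abs(f2$U[, , 1]))
  expect_lt(err, 0.01)
})

test_that("no-slip is exact on wall nodes and snapshots span one period", {
  m <- mesh_channel_2d(0.02, 0.008, 0.0012)
  cfg <- solver_config(time_step = 0.01, n_cycles = 2, save_stride = 20)
  f <- solve_pulsatile(m, inlet_velocity_waveform(),
                       outlet_pressure_waveform(), blood, cfg)
  wall <- archflow:::node_set(m, "^wall$")
  expect_true(all(f$U[wall, , ] == 0))
  expect_equal(diff(range(f$times)), 1.0)
  expect_true(all(diff(f$times) > 0))
  # the inlet-flux waveform of the stored cycle follows the prescribed signal
  infl <- vapply(seq_along(f$times), function(k)
    -archflow:::facet_flux(m, matrix(f$U[, , k], ncol = 2),
                           m$facet_tag == "inlet"), 0)
  area <- sum(m$facet_area[m$facet_tag == "inlet"])
  # Dirichlet inlet: flux follows the waveform shape exactly up to the
  # (constant) quadrature factor from the zeroed rim nodes
  v <- inlet_velocity(f$times)
  expect_equal(infl / infl[1], v / v[1], tolerance = 1e-6)
  expect_equal(infl / area, v, tolerance = 0.05)
  expect_lt(check_mass_conservation(f, m), 0.01)
})

test_that("plane Couette traction is exact for the cell-gradient reconstruction", {
  m <- mesh_channel_2d(0.01, 0.004, 0.001)
  gdot <- 7.3
  f <- couette_field(m, gdot)
  for (meth in c("cell", "patch")) {
    wss <- compute_wss(f, m, blood, method = meth)
    tw <- sqrt(rowSums(wss$traction[, , 1]^2))
    expect_lt(max(abs(tw - blood$dynamic_viscosity * gdot)), 1e-10)
  }
})

test_that("wall shear is linear in the velocity field and flips with orientation", {
  m <- mesh_channel_2d(0.01, 0.004, 0.001)
  f1 <- couette_field(m, 2.0)
  f3 <- couette_field(m, 6.0)
  w1 <- compute_wss(f1, m, blood)
  w3 <- compute_wss(f3, m, blood)
  expect_equal(w3$traction, 3 * w1$traction, tolerance = 1e-12)
  # flipping the wall normals flips the tangential traction sign
  m2 <- m
  m2$facet_normal <- -m2$facet_normal
  w2 <- compute_wss(f1, m2, blood)
  expect_equal(w2$traction, -w1$traction, tolerance = 1e-12)
})

test_that("traction vectors are tangent to their facets", {
  m <- mesh_channel_2d(0.015, 0.006, 0.001)
  f <- solve_steady(m, 0.03 * 0.006, blood)
  wss <- compute_wss(f, m, blood)
  tn <- abs(rowSums(wss$traction[, 1:2, 1] * wss$facet_normal[, 1:2]))
  mag <- sqrt(rowSums(wss$traction[, 1:2, 1]^2))
  expect_true(all(tn < 1e-8 * mag + 1e-12))
})

test_that("Poiseuille wall-shear error decreases monotonically under refinement", {
  H <- 0.008; L <- 0.02; ubar <- 0.04
  ana <- 6 * blood$dynamic_viscosity * ubar / H
  errs <- vapply(c(0.002, 0.001, 0.0005), function(h) {
    m <- mesh_channel_2d(L, H, h)
    f <- solve_steady(m, ubar * H, blood, tol = 1e-9)
    wss <- compute_wss(f, m, blood, method = "cell")
    tw <- sqrt(rowSums(wss$traction[, , 1]^2))
    mid <- archflow:::facet_midpoints(m$nodes,
                                      m$facets[wss$facet_ids, , drop = FALSE])
    sel <- mid[, 1] > L / 4 & mid[, 1] < 3 * L / 4
    abs(mean(tw[sel]) - ana) / ana
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("Womersley number follows its closed form and scalings", {
  expect_equal(womersley_number(0.0125), 17.2, tolerance = 0.005)
  a1 <- womersley_number(0.01)
  a2 <- womersley_number(0.01,
                         props = fluid_properties(dynamic_viscosity = 4 * 0.0035))
  expect_equal(a1 / a2, 2)
  expect_identical(womersley_number(0), 0)
})
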