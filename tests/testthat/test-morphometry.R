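test_that("circumscribed-circle curvature is exact on circles", {
  th <- seq(0, 2 * pi, length.out = 300)
  pts <- cbind(0.03 * cos(th), 0.03 * sin(th))
  cr <- curvature_radius_profile(pts)
  fin <- is.finite(cr) & !is.na(cr)
  expect_true(all(abs(cr[fin] - 0.03) / 0.03 < 0.005))
})

test_that("collinear points give undefined (infinite) curvature radius", {
  pts <- cbind(seq(0, 1, length.out = 50), 0.5)
  cr <- curvature_radius_profile(pts)
  expect_true(all(is.infinite(cr[!is.na(cr)])))
})

test_that("helix curvature is recovered within 2%", {
  r <- 0.01; cpitch <- 0.005
  t <- seq(0, 4 * pi, length.out = 500)
  pts <- cbind(r * cos(t), r * sin(t), cpitch * t)
  kappa <- r / (r^2 + cpitch^2)
  cr <- curvature_radius_profile(pts)
  fin <- !is.na(cr)
  expect_true(all(abs(cr[fin] - 1 / kappa) * kappa < 0.02))
})

test_that("curvature estimation is invariant to rigid motions", {
  th <- seq(0, pi, length.out = 120)
  pts <- cbind(0.02 * cos(th), 0.02 * sin(th))
  a <- 0.7
  rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  pts2 <- sweep(pts %*% rot, 2, c(1.3, -2.1), "+")
  c1 <- curvature_radius_profile(pts)
  c2 <- curvature_radius_profile(pts2)
  fin <- !is.na(c1)
  expect_equal(c1[fin], c2[fin], tolerance = 1e-9)
})

test_that("trunk centerlines reproduce the arch curvature radius", {
  specs <- default_case_specs()
  for (nm in c("normal", "postop1w", "postop6m")) {
    cl <- extract_centerline(specs[[nm]])
    expect_gte(nrow(cl$points), 200)
    expect_true(all(diff(cl$s) > 0))
    # interior of the arch span: triples straddling the straight/arc
    # junctions mix the two curvatures and are excluded
    La <- specs[[nm]]$ascending_length
    span <- pi * specs[[nm]]$arch_curvature_radius
    sel <- cl$arc_coord > La + 0.05 * span &
      cl$arc_coord < La + 0.95 * span & is.finite(cl$curvature_radius)
    expect_true(any(sel))
    expect_true(all(abs(cl$curvature_radius[sel] -
                          specs[[nm]]$arch_curvature_radius) /
                      specs[[nm]]$arch_curvature_radius < 0.01))
  }
  # straight-tube degenerate: no finite curvature anywhere
  tube <- arch_case_spec("tube", lumen_radius = 0.004,
                         ascending_length = 0.05, descending_length = 0,
                         arch_curvature_radius = Inf, extension_factor = 0)
  crt <- extract_centerline(tube)$curvature_radius
  expect_true(all(is.infinite(crt[!is.na(crt)])))
})

test_that("minimum arch curvature radius orders the postoperative stages", {
  specs <- default_case_specs()
  r1 <- min_arch_curvature_radius(specs$postop1w)
  r6 <- min_arch_curvature_radius(specs$postop6m)
  rn <- min_arch_curvature_radius(specs$normal)
  expect_lt(r1, r6)
  expect_lte(r6, rn)
})
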