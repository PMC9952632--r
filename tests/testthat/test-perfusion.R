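test_that("a single-outlet steady run conserves the outlet flux exactly", {
  m <- mesh_channel_2d(0.02, 0.008, 0.0012)
  q <- 0.04 * 0.008
  f <- solve_steady(m, q, blood)
  perf <- outlet_flow_rates(f, m)
  expect_equal(perf$mean_flow[perf$outlet == "descending"],
               attr(perf, "inlet_mean_flow"), tolerance = 1e-6)
  expect_equal(perf$fraction[perf$outlet == "descending"], 1,
               tolerance = 1e-6)
})

test_that("a symmetric bifurcation splits the flow 50/50", {
  m <- mesh_bifurcating_channel_2d(width = 0.008, trunk_length = 0.02,
                                   branch_length = 0.02, angle = 0.4,
                                   h = 0.0008)
  f <- solve_steady(m, 0.03 * 0.008, blood)
  perf <- outlet_flow_rates(f, m)
  fr <- perf$fraction[match(c("RSA", "RCCA"), perf$outlet)]
  expect_equal(fr[1], 0.5, tolerance = 0.02)
  expect_equal(fr[2], 0.5, tolerance = 0.02)
  expect_equal(sum(fr), 1, tolerance = 0.01)
})

test_that("absent outlets report zero flow with a note, not an error", {
  m <- mesh_channel_2d(0.015, 0.006, 0.0012)
  f <- solve_steady(m, 1e-4 * 0.006, blood)
  perf <- outlet_flow_rates(f, m, expected = c("LSA", "descending"))
  expect_true("LSA" %in% perf$outlet)
  expect_false(perf$present[perf$outlet == "LSA"])
  expect_identical(perf$mean_flow[perf$outlet == "LSA"], 0)
  expect_identical(perf$mean_flow_ml_min[perf$outlet == "LSA"], 0)
})
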