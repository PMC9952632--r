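test_that("inlet velocity waveform matches its printed closed form", {
  expect_equal(inlet_velocity(0), 0.295, tolerance = 1e-12)
  expect_equal(inlet_velocity(0.15), 1.06, tolerance = 1e-12)
  expect_equal(inlet_velocity(1.0), inlet_velocity(0), tolerance = 1e-12)
  # systolic piece: -0.3825*cos(20*pi/3 * t) + 0.6775
  t <- c(0.05, 0.1, 0.2, 0.28)
  expect_equal(inlet_velocity(t), -0.3825 * cos(20 * pi / 3 * t) + 0.6775)
})

test_that("inlet waveform is continuous at the piece junctions and periodic", {
  d <- waveform_diagnostics(inlet_velocity_waveform())
  expect_equal(d$junctions$time, c(0.3, 0.6))
  expect_lt(max(d$junctions$jump), 1e-12)
  expect_equal(d$junctions$left, c(0.295, 0.576), tolerance = 1e-12)
  expect_lt(d$period_gap, 1e-12)
  w <- inlet_velocity_waveform()
  t <- c(0.01, 0.12, 0.3, 0.45, 0.6, 0.77, 0.999)
  # periodic up to the rounding of (t + k) mod 1
  expect_lt(max(abs(wf_eval(w, t + 1) - wf_eval(w, t))), 1e-12)
  expect_lt(max(abs(wf_eval(w, t + 7) - wf_eval(w, t))), 1e-12)
})

test_that("outlet pressure waveform reproduces the systolic piece and stays physiological", {
  expect_equal(outlet_pressure(1e-12), 90, tolerance = 1e-9)
  expect_equal(outlet_pressure(0.25), 140, tolerance = 1e-12)
  expect_equal(outlet_pressure(0.35), -25 * cos(1.4 * pi) + 115,
               tolerance = 1e-12)
  p <- outlet_pressure(seq(0.0005, 1, by = 0.0005))
  expect_true(all(p >= 85 & p <= 145))
  # the adopted diastolic reading closes the cycle within 3% of diastole
  d <- waveform_diagnostics(outlet_pressure_waveform())
  expect_lt(d$period_gap / 90, 0.03)
})

test_that("mmHg-to-Pa conversion uses the standard factor", {
  expect_identical(to_pascals(0), 0)
  expect_equal(to_pascals(90), 90 * 133.322)
  expect_equal(to_pascals(140), 140 * 133.322)
  expect_equal(to_pascals(140), 18665.08, tolerance = 1e-6)
})

test_that("waveform diagnostics computes cycle means by quadrature", {
  const <- pc_waveform(data.frame(amplitude = 0, omega = 1, tshift = 0,
                                  phase = 0, offset = 3.2, t0 = 0, t1 = 1))
  expect_equal(waveform_diagnostics(const)$cycle_mean, 3.2, tolerance = 1e-8)
  d <- waveform_diagnostics(inlet_velocity_waveform())
  # cosines integrate to zero over their pieces: mean = weighted offsets
  expect_equal(d$cycle_mean, 0.6775 * 0.3 + 0.4355 * 0.7, tolerance = 1e-7)
  expect_gt(d$cycle_mean, 0.29)
  expect_lt(d$cycle_mean, 1.06)
})

test_that("waveform sampling covers one closed cycle", {
  s <- wf_sample(inlet_velocity_waveform(), 100)
  expect_equal(nrow(s), 101)
  expect_equal(s$value[1], s$value[101], tolerance = 1e-12)
})
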