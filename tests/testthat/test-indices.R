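test_that("index formulas are exact on the canonical synthetic fixtures", {
  const <- synthetic_wss_series("constant", offset = 2, n_timesteps = 40)
  expect_equal(compute_tawss(const), 2)
  expect_equal(compute_mean_shear(const), 2)
  m <- compute_index_maps(const)
  expect_equal(m$osi, 0)
  expect_equal(m$rrt, 0.5)

  rev <- synthetic_wss_series("reversing", amplitude = 1, n_timesteps = 40)
  expect_equal(compute_tawss(rev), 1)
  expect_equal(compute_mean_shear(rev), 0)
  m <- compute_index_maps(rev)
  expect_equal(m$osi, 0.5)
  expect_true(m$rrt_infinite)
  expect_equal(m$rrt, 1e6)   # capped sentinel

  osc <- synthetic_wss_series("offset_sinusoid", amplitude = 0.5, offset = 1,
                              n_timesteps = 1000)
  # integrand stays positive, so TAWSS = mean = offset
  expect_equal(compute_tawss(osc), 1, tolerance = 1e-6)
  expect_equal(compute_mean_shear(osc), 1, tolerance = 1e-6)
  m <- compute_index_maps(osc)
  expect_lt(abs(m$osi), 1e-9)
})

test_that("the three risk thresholds are mutually consistent under the RRT formula", {
  expect_identical(as.numeric(compute_rrt(0.4, 0.25)), 1 / (0.4 * 0.5))
  expect_equal(as.numeric(compute_rrt(0.4, 0.25)), 5.0)
})

test_that("trapezoid indices agree with a 100x-oversampled quadrature oracle", {
  worst <- 0
  for (seed in 1:100) {
    w <- make_fourier_wss(seed, n = 200)
    o <- make_fourier_wss(seed, n = 200, factor = 100)
    for (fn in list(compute_tawss, compute_mean_shear)) {
      a <- fn(w); b <- fn(o)
      worst <- max(worst, abs(a - b) / max(abs(b), 1e-12))
    }
    ma <- compute_index_maps(w); mb <- compute_index_maps(o)
    worst <- max(worst, abs(ma$osi - mb$osi) / max(mb$osi, 1e-3))
  }
  expect_lt(worst, 1e-4)
})

test_that("index bounds hold on random traction series", {
  for (seed in 1:100) {
    m <- compute_index_maps(make_fourier_wss(seed, n = 64))
    expect_gte(m$osi, 0); expect_lte(m$osi, 0.5)
    expect_lte(m$tau_mean, m$tawss + 1e-14)
    expect_gte(m$rrt, 1 / m$tawss - 1e-10)
  }
})

test_that("stored maps satisfy the defining identities bitwise", {
  for (seed in c(3, 17, 42)) {
    m <- compute_index_maps(make_fourier_wss(seed))
    osi2 <- suppressWarnings(compute_osi(m$tawss, m$tau_mean))
    expect_identical(m$osi, as.numeric(osi2))
    rrt2 <- compute_rrt(m$tawss, as.numeric(osi2))
    expect_identical(m$rrt, as.numeric(rrt2))
  }
})

test_that("degenerate traction series are guarded", {
  z <- synthetic_wss_series("constant", offset = 0, n_timesteps = 10)
  tw <- compute_tawss(z)
  expect_warning(osi <- compute_osi(tw, compute_mean_shear(z)),
                 "undefined")
  expect_equal(as.numeric(osi), 0)
  expect_equal(attr(osi, "n_undefined"), 1L)
  one <- wall_shear_field(array(1, c(1, 3, 2)), times = c(0, 1),
                          facet_area = 1)
  expect_error(compute_tawss(structure(list(times = 0.5), class = "wall_shear_field")))
})

test_that("risk-region classification reports exact masked areas", {
  mk <- function(tawss, osi = rep(0, length(tawss)), area = rep(1, length(tawss))) {
    rrt <- compute_rrt(tawss, osi)
    structure(list(tawss = tawss, tau_mean = tawss * (1 - 2 * osi),
                   osi = osi, rrt = as.numeric(rrt),
                   rrt_infinite = attr(rrt, "infinite"),
                   facet_area = area, facet_ids = seq_along(tawss)),
              class = "index_maps")
  }
  r <- classify_risk_regions(mk(rep(2, 10)))
  expect_equal(r$summary$area_cm2[r$summary$criterion == "tawss_low"], 0)

  r <- classify_risk_regions(mk(c(rep(0.2, 5), rep(1.0, 5))))
  expect_identical(r$summary$fraction[r$summary$criterion == "tawss_low"], 0.5)

  # fully reversing shear: OSI and RRT criteria cover the whole wall
  # (RRT flagged infinite counts as exceeding)
  r <- classify_risk_regions(mk(rep(1, 8), osi = rep(0.5, 8)))
  expect_identical(r$summary$fraction[r$summary$criterion == "osi_high"], 1)
  expect_identical(r$summary$fraction[r$summary$criterion == "rrt_high"], 1)
  expect_error(classify_risk_regions(mk(rep(1, 4)),
                                     thresholds = c(tawss_low = -1,
                                                    osi_high = 0.25,
                                                    rrt_high = 5)))
})
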