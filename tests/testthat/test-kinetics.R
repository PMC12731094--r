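# Reaction-parameter derivation, rate law, and unit conversions.

test_that("Henry's law conversions are exact inverses with the right scale", {
  expect_equal(henry_pressure(0), 0)
  # equilibrium dissolved O2 against the literature Henry constant
  expect_equal(henry_pressure(0.214, 932.4), 932.4 * 2.14e-4,
               tolerance = 1e-12)
  expect_equal(henry_pressure(0.214, 932.4), 0.19953, tolerance = 1e-4)
  cs <- c(0, 1e-4, 0.05, 0.214, 1.2)
  expect_equal(henry_concentration(henry_pressure(cs)), cs,
               tolerance = 1e-14)
  expect_error(henry_pressure(-1), "negative")
  expect_error(henry_concentration(-0.1), "negative")
})

test_that("Km converts from mmHg to concentration through Henry's law", {
  expect_equal(km_to_concentration(0), 0)
  expect_equal(km_to_concentration(5.6, 932.4), (5.6 / 760) / 932.4 * 1000,
               tolerance = 1e-14)
  expect_equal(km_to_concentration(5.6), 7.90e-3, tolerance = 1e-3)
  expect_equal(km_to_concentration(760), 1.0725, tolerance = 1e-4)
  # conversion round-trips through the pressure scale exactly
  km <- km_to_concentration(5.6)
  expect_equal(henry_pressure(km) * 760, 5.6, tolerance = 1e-12)
})

test_that("volumetric Vmax follows cells x rate / vessel volume", {
  p <- oxygen_params()
  expect_equal(volumetric_vmax(cell_loading("bulk", 11e6,
                                            vessel_volume = 110e-6), p),
               3.333e-6, tolerance = 1e-3)
  expect_equal(volumetric_vmax(cell_loading("bulk", 0), p), 0)
  expect_equal(volumetric_vmax(cell_loading("bulk", 1e6,
                                            vessel_volume = 1e-3), p),
               3.333e-8, tolerance = 1e-3)
  expect_error(volumetric_vmax(cell_loading("per_scaffold", 4e5), p),
               "bulk")
})

test_that("areal Vmax follows scaffold cells / total scaffold area", {
  p <- oxygen_params()
  expect_equal(areal_vmax(cell_loading("per_scaffold", 4e6,
                                       n_scaffolds = 12L,
                                       area_per_scaffold = 0.01), p),
               1.333e-8, tolerance = 1e-3)
  expect_equal(areal_vmax(cell_loading("per_scaffold", 4e5,
                                       n_scaffolds = 12L,
                                       area_per_scaffold = 0.01), p),
               1.333e-9, tolerance = 1e-3)
  expect_equal(areal_vmax(cell_loading("per_scaffold", 0), p), 0)
})

test_that("areal Vmax is independent of the scaffold count", {
  p <- oxygen_params()
  set.seed(7)
  for (r in 1:20) {
    cells <- 10^runif(1, 4, 7)
    area <- 10^runif(1, -3, -1)
    n1 <- sample(1:50, 1); n2 <- sample(1:50, 1)
    v1 <- areal_vmax(cell_loading("per_scaffold", cells, n1,
                                  area_per_scaffold = area), p)
    v2 <- areal_vmax(cell_loading("per_scaffold", cells, n2,
                                  area_per_scaffold = area), p)
    expect_equal(v1, v2, tolerance = 1e-14)
  }
})

test_that("Michaelis-Menten rate law matches its defining identities", {
  km <- km_to_concentration(5.6)
  expect_equal(mm_rate(0, 1e-6, km), 0)
  expect_equal(mm_rate(km, 1e-6, km), 5e-7, tolerance = 1e-14)
  # saturating evaluation at the interface concentration
  expect_equal(mm_rate(0.214, 3.33e-6, 7.90e-3), 3.21e-6,
               tolerance = 2e-3)
  # bounded below vmax, vectorized
  cs <- seq(0, 2, length.out = 11)
  r <- mm_rate(cs, 2e-6, km)
  expect_true(all(r >= 0 & r < 2e-6))
  expect_error(mm_rate(-1e-9, 1e-6, km), "negative")
  # zeroth-order limit
  expect_equal(mm_rate(c(0, 0.1), 1e-6, 0), c(0, 1e-6))
})

test_that("depletion time bound scales as c0 / vmax", {
  expect_equal(depletion_time_estimate(0.214, 3.33e-6), 6.426e4,
               tolerance = 1e-3)
  expect_equal(depletion_time_estimate(0.214, 2 * 3.33e-6),
               depletion_time_estimate(0.214, 3.33e-6) / 2)
  expect_equal(depletion_time_estimate(0, 1e-6), 0)
  expect_error(depletion_time_estimate(0.2, 0), "positive")
})

test_that("nmol/min per-cell rates round-trip to SI exactly", {
  r <- oxyflow:::per_cell_rate_si(2)
  expect_equal(r * 60 * 1e6 * 1e9, 2, tolerance = 1e-14)
  # 2 nmol/min per 1e6 cells x 11e6 cells = 3.667e-10 mol/s total
  expect_equal(r * 11e6, 2e-9 * 11 / 60, tolerance = 1e-14)
})
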