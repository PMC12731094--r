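# Scenario construction and serialization.

test_that("named scenarios carry the derived reaction parameters", {
  bulk <- bioreactor_scenario("bulk_11M")
  rx <- bulk$reactions[[1]]
  expect_equal(rx$mode, "volumetric")
  expect_equal(rx$vmax, 3.333e-6, tolerance = 1e-3)
  expect_equal(rx$km_c, km_to_concentration(5.6), tolerance = 1e-12)
  expect_equal(bulk$chamber$fill_volume, 110e-6)
  expect_equal(bulk$flow_rate, 80e-6 / 60)
  expect_null(bulk$scaffold)

  s4m <- bioreactor_scenario("scaffolds_4M")
  rx4 <- s4m$reactions[[1]]
  expect_equal(rx4$mode, "surface")
  expect_equal(rx4$vmax, 1.333e-8, tolerance = 1e-3)
  expect_equal(s4m$scaffold$variant, "strut_lattice")
  expect_equal(s4m$scaffold$target_porosity, 0.5)
  expect_equal(s4m$chamber$n_scaffolds, 12L)
  expect_true(s4m$chamber$quarter)

  s400k <- bioreactor_scenario("scaffolds_400k")
  expect_equal(s400k$reactions[[1]]$vmax, 1.333e-9, tolerance = 1e-3)
})

test_that("unknown scenario names fail listing the valid ones", {
  expect_error(bioreactor_scenario("bogus"), "bulk_11M")
})

test_that("scenario configs round-trip through YAML losslessly", {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  for (nm in c("bulk_11M", "scaffolds_4M")) {
    cfg <- bioreactor_scenario(nm, resolution = 4e-3, seed = 7L)
    config_to_yaml(cfg, tmp)
    back <- config_from_yaml(tmp)
    expect_equal(back$name, cfg$name)
    expect_equal(back$resolution, cfg$resolution)
    expect_equal(back$seed, cfg$seed)
    expect_equal(back$reactions[[1]]$vmax, cfg$reactions[[1]]$vmax,
                 tolerance = 1e-12)
    expect_equal(unclass(back$loading), unclass(cfg$loading))
    expect_equal(back$oxygen$Km_c, cfg$oxygen$Km_c, tolerance = 1e-12)
  }
})

test_that("inconsistent loading/scaffold combinations are rejected", {
  expect_error(
    scenario_config("x", chamber_spec(n_scaffolds = 0L), NULL,
                    cell_loading("per_scaffold", 4e5)),
    "scaffold")
  expect_error(
    scenario_config("x", chamber_spec(), scaffold_spec(),
                    cell_loading("bulk", 1e6)),
    "bulk")
})

test_that("analytic fixtures expose their references", {
  expect_error(analytic_fixture("nope"), "arg")
  slab <- analytic_fixture("slab_consumption")
  expect_true(is.function(slab$reference))
  # the stated closed form at the far wall
  L <- 1e-3
  expect_equal(slab$reference(L), 0.0473, tolerance = 1e-3)
  cb <- analytic_fixture("closed_box")
  expect_equal(cb$reference, 0.214)
  pipe <- analytic_fixture("poiseuille_pipe")
  expect_equal(pipe$mean_speed, 0.663, tolerance = 1e-3)
  expect_equal(pipe$tau_wall, 3.316, tolerance = 1e-3)
})

test_that("a tiny end-to-end scenario run is deterministic", {
  cfg <- bioreactor_scenario("bulk_11M", resolution = 5e-3)
  ctl_f <- flow_control(max_iter = 400L)
  r1 <- suppressWarnings(run_scenario(cfg, flow_ctrl = ctl_f))
  r2 <- suppressWarnings(run_scenario(cfg, flow_ctrl = ctl_f))
  expect_identical(r1$domain$labels, r2$domain$labels)
  expect_equal(r1$transport$cells, r2$transport$cells, tolerance = 1e-14)
  expect_s3_class(r1$summary, "summary_stats")
})
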