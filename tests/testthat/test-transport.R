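# Oxygen transport: equilibrium preservation, analytic oracles, bounds,
# monotonicity, conservation.

test_that("a sealed reaction-free box stays at equilibrium", {
  fix <- analytic_fixture("closed_box")
  steady <- solve_transport(fix$domain, NULL, fix$params)
  expect_equal(unname(steady$cells), rep(fix$reference,
                                         length(steady$cells)),
               tolerance = 1e-12)
  trans <- solve_transport(fix$domain, NULL, fix$params,
                           schedule = list(dt = 50, t_end = 500))
  expect_equal(unname(trans$cells), rep(fix$reference,
                                        length(trans$cells)),
               tolerance = 1e-12)
})

test_that("slab consumption matches the closed-form profile within 2%", {
  fix <- analytic_fixture("slab_consumption", n = 40L)
  sol <- solve_transport(fix$domain, NULL, fix$params, fix$reaction)
  ref <- fix$reference(fix$x)
  expect_lt(max(abs(sol$cells - ref) / ref), 0.02)
})

test_that("slab error shrinks at least 2x when the grid is halved", {
  err_of <- function(n) {
    fix <- analytic_fixture("slab_consumption", n = n)
    sol <- solve_transport(fix$domain, NULL, fix$params, fix$reaction)
    max(abs(sol$cells - fix$reference(fix$x)))
  }
  expect_gt(err_of(10L) / err_of(20L), 2)
})

test_that("well-mixed MM depletion tracks the ODE oracle within 0.5%", {
  skip_if_not_installed("deSolve")
  fix <- analytic_fixture("well_mixed_mm")
  t_end <- 3.6e4
  for (frac in c(0.25, 0.5, 1)) {
    sol <- solve_transport(fix$domain, NULL, fix$params, fix$reaction,
                           schedule = list(dt = 36, t_end = frac * t_end))
    ref <- fix$reference(c(0, frac * t_end))[2]
    expect_lt(abs(sol$cells - ref) / ref, 0.005)
  }
})

test_that("concentrations respect the maximum principle on random domains", {
  p <- oxygen_params()
  for (seed in 1:4) {
    dom <- duct_domain(nx = 4L, ny = 4L, nz = 6L, n_obstacles = 6L,
                       seed = seed, obstacle_label = SC)
    flow <- solve_steady_flow(dom, fluid_props(), 2e-9,
                              control = flow_control(max_iter = 1500L))
    set.seed(seed)
    rx <- list(reaction_spec("volumetric", 10^runif(1, -7, -5), p$Km_c),
               reaction_spec("surface", 10^runif(1, -9, -7), p$Km_c))
    sol <- solve_transport(dom, flow, p, rx)
    expect_gte(min(sol$cells), 0)
    expect_lte(max(sol$cells), p$C0 + 1e-12)
  }
})

test_that("raising Vmax never raises the steady concentration anywhere", {
  p <- oxygen_params()
  dom <- open_top_duct()
  base <- solve_transport(dom, NULL, p,
                          reaction_spec("volumetric", 1e-6, p$Km_c))
  for (vm in c(2e-6, 5e-6)) {
    hi <- solve_transport(dom, NULL, p,
                          reaction_spec("volumetric", vm, p$Km_c))
    expect_true(all(hi$cells <= base$cells + 1e-12))
    base <- hi
  }
})

test_that("a surface-reacting thin plate matches its volumetric homogenization", {
  # scaffold plate of one voxel thickness with areal sink sigma on both
  # faces, vs the same layer as fluid with volumetric vmax = 2 sigma / h;
  # symmetric oxygenation from interfaces above and below
  p <- oxygen_params()
  n <- c(4L, 4L, 9L)
  h <- 0.5e-3
  sigma <- 5e-9
  kmid <- 6L
  mk <- function(plate_solid) {
    lab <- array(WL, n + 2L)
    lab[2:(n[1] + 1L), 2:(n[2] + 1L), 2:(n[3] + 1L)] <- FL
    lab[2:(n[1] + 1L), 2:(n[2] + 1L), 1L] <- VOXEL_LABELS[["interface"]]
    lab[2:(n[1] + 1L), 2:(n[2] + 1L), n[3] + 2L] <-
      VOXEL_LABELS[["interface"]]
    if (plate_solid) lab[2:(n[1] + 1L), 2:(n[2] + 1L), kmid] <- SC
    voxel_domain(lab, h)
  }
  s_surf <- solve_transport(mk(TRUE), NULL, p,
                            reaction_spec("surface", sigma, p$Km_c))
  dom_v <- mk(FALSE)
  region <- array(FALSE, dim(dom_v$labels))
  region[, , kmid] <- TRUE
  s_vol <- solve_transport(dom_v, NULL, p,
                           reaction_spec("volumetric", 2 * sigma / h,
                                         p$Km_c, region = region))
  expect_lt(abs(s_surf$budget$consumed - s_vol$budget$consumed) /
              s_vol$budget$consumed, 0.10)
  # concentration depression at the plate-adjacent layers agrees within 10%
  dep_at <- function(sol, dom) {
    carr <- sol$c
    p$C0 - mean(carr[2:(n[1] + 1L), 2:(n[2] + 1L), c(kmid - 1L, kmid + 1L)],
                na.rm = TRUE)
  }
  dep_s <- dep_at(s_surf)
  dep_v <- dep_at(s_vol)
  expect_lt(abs(dep_s - dep_v) / dep_v, 0.10)
})

test_that("the steady oxygen budget closes", {
  p <- oxygen_params()
  dom <- open_top_duct()
  sol <- solve_transport(dom, NULL, p,
                         reaction_spec("volumetric", 2e-6, p$Km_c))
  b <- sol$budget
  expect_lt(abs(b$residual), 0.02 * max(b$consumed, 1e-30))
})

test_that("recirculation equalizes inlet and outlet concentrations", {
  p <- oxygen_params()
  # mini chamber: bottom inlet and outlet ports, air interface on top
  lab <- array(WL, c(6L, 6L, 8L))
  lab[2:5, 2:5, 2:7] <- FL
  lab[2:5, 2:5, 8L] <- VOXEL_LABELS[["interface"]]
  lab[2L, 2L, 1L] <- VOXEL_LABELS[["inlet"]]
  lab[5L, 5L, 1L] <- VOXEL_LABELS[["outlet"]]
  dom <- voxel_domain(lab, 1e-3)
  flow <- solve_steady_flow(dom, fluid_props(), 1e-9,
                            control = flow_control(max_iter = 1500L))
  sol <- solve_transport(dom, flow, p,
                         reaction_spec("volumetric", 1e-6, p$Km_c))
  # flux-weighted outlet mean equals the recirculated inlet value
  expect_false(is.na(sol$c_inlet))
  b <- sol$budget
  expect_equal(b$inlet_influx, b$outlet_outflux,
               tolerance = 1e-6 * max(b$outlet_outflux, 1e-30))
})

test_that("transient advection steps respect the CFL limit", {
  p <- oxygen_params()
  dom <- duct_domain(nx = 3L, ny = 3L, nz = 5L)
  flow <- solve_steady_flow(dom, fluid_props(), 1e-8,
                            control = flow_control(max_iter = 500L))
  expect_message(
    solve_transport(dom, flow, p, list(),
                    schedule = list(dt = 1e6, t_end = 2e6)),
    "CFL")
})
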