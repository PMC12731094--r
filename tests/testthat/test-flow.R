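# Staggered-grid flow solver: trivial limits, conservation, fixtures.

test_that("zero flow rate yields a null field immediately", {
  dom <- duct_domain()
  sol <- solve_steady_flow(dom, fluid_props(), 0)
  expect_equal(sol$iterations, 0L)
  expect_true(all(sol$u == 0) && all(sol$v == 0) && all(sol$w == 0))
  expect_equal(max_divergence(sol, dom), 0)
})

test_that("prescribed port fluxes balance exactly", {
  dom <- duct_domain()
  sol <- solve_steady_flow(dom, fluid_props(), 1e-8,
                           control = flow_control(max_iter = 200L))
  expect_equal(sol$mass_error, 0)
  expect_equal(sol$q_in, 1e-8, tolerance = 1e-12)
})

test_that("projection drives the discrete divergence to solver tolerance", {
  fix <- analytic_fixture("poiseuille_pipe", n = 8L)
  sol <- solve_steady_flow(fix$domain, fluid_props(), fix$flow_rate,
                           control = flow_control(max_iter = 2000L))
  h <- fix$domain$spacing
  u_scale <- fix$mean_speed / (1.6e-3)  # u_mean / d
  expect_lt(max_divergence(sol, fix$domain), 1e-4 * u_scale)
  # plug inflow speed equals Q over the voxelized port area
  n_in <- sum(fix$domain$labels == VOXEL_LABELS[["inlet"]])
  expect_equal(sol$inlet_speed, fix$flow_rate / (n_in * h^2),
               tolerance = 1e-12)
  expect_lt(abs(sol$inlet_speed - fix$mean_speed) / fix$mean_speed, 0.05)
})

test_that("velocity scales linearly with flow rate in the Stokes limit", {
  dom <- duct_domain(nx = 4L, ny = 4L, nz = 6L, n_obstacles = 4L,
                     seed = 3L)
  ctl <- flow_control(max_iter = 3000L, tol = 1e-9)
  s1 <- solve_steady_flow(dom, fluid_props(), 1e-10, control = ctl)
  s2 <- solve_steady_flow(dom, fluid_props(), 2e-10, control = ctl)
  sel <- abs(s1$w) > 1e-3 * max(abs(s1$w))
  expect_lt(max(abs(s2$w[sel] - 2 * s1$w[sel]) / max(abs(s1$w))), 0.01)
})

test_that("a mirrored domain yields the mirrored solution", {
  dom <- duct_domain(nx = 5L, ny = 4L, nz = 6L, n_obstacles = 5L,
                     seed = 11L)
  lab_m <- dom$labels[rev(seq_len(dim(dom$labels)[1])), , ]
  dom_m <- voxel_domain(lab_m, dom$spacing)
  ctl <- flow_control(max_iter = 2000L)
  s <- solve_steady_flow(dom, fluid_props(), 5e-9, control = ctl)
  sm <- solve_steady_flow(dom_m, fluid_props(), 5e-9, control = ctl)
  # w is even under the mirror, u odd
  expect_equal(sm$w[rev(seq_len(dim(sm$w)[1])), , ] + 0, s$w + 0,
               tolerance = 1e-6)
  expect_equal(sm$u[rev(seq_len(dim(sm$u)[1])), , ] + 0, -s$u + 0,
               tolerance = 1e-6)
})

test_that("developed pipe flow reproduces the Poiseuille profile", {
  fix <- analytic_fixture("poiseuille_pipe", n = 16L)
  sol <- solve_developed_flow(fix$domain_developed, fluid_props(),
                              flow_axis = 3L,
                              mean_velocity = fix$mean_speed)
  expect_equal(sol$mean, fix$mean_speed, tolerance = 1e-12)
  expect_lt(abs(sol$max / sol$mean - 2) / 2, 0.05)
})

test_that("pipe wall shear matches the Poiseuille closed form", {
  fix <- analytic_fixture("poiseuille_pipe", n = 16L)
  sol <- solve_developed_flow(fix$domain_developed, fluid_props(),
                              flow_axis = 3L,
                              mean_velocity = fix$mean_speed)
  wss <- wall_shear_stress(sol, fix$domain_developed)
  wss <- wss[wss$axis != 3L & wss$k == 2L, ]
  # total tangential force over the physical wetted area
  tau_drag <- sum(wss$tau * wss$area) /
    (2 * pi * fix$radius * fix$domain_developed$spacing)
  expect_lt(abs(tau_drag - fix$tau_wall) / fix$tau_wall, 0.10)
  expect_lt(abs(fix$tau_wall - 3.32) / 3.32, 0.01)
})

test_that("plane Couette flow gives a uniform shear stress", {
  fix <- analytic_fixture("couette")
  sol <- solve_developed_flow(fix$domain, fluid_props(), flow_axis = 1L,
                              pressure_gradient = 0,
                              wall_motion = fix$wall_motion)
  wss <- wall_shear_stress(sol, fix$domain, wall_motion = fix$wall_motion)
  wss <- wss[wss$axis == 3L, ]
  expect_true(all(abs(wss$tau - fix$tau) / fix$tau < 0.05))
})

test_that("zero-flow wall shear stress vanishes", {
  dom <- duct_domain()
  sol <- solve_steady_flow(dom, fluid_props(), 0)
  wss <- wall_shear_stress(sol, dom)
  expect_true(all(wss$tau == 0))
})

test_that("chamber flow is fastest at the ports and slow in the scaffold region", {
  cfg <- bioreactor_scenario("scaffolds_400k", resolution = 4e-3)
  blk <- generate_strut_scaffold(cfg$scaffold)
  dom <- suppressWarnings(
    build_chamber_domain(cfg$chamber, list(blk), resolution = 4e-3))
  sol <- solve_steady_flow(dom, cfg$fluid, cfg$flow_rate,
                           control = flow_control(max_iter = 4000L))
  lab <- dom$labels
  speed <- array(0, dom$shape)
  fl <- lab == FL
  idx <- which(fl)
  ijk <- arrayInd(idx, dom$shape)
  cc <- function(arr, shift_ax) {
    hi <- ijk; hi[, shift_ax] <- hi[, shift_ax] + 1L
    fd <- dim(arr)
    0.5 * (arr[hi[, 1] + fd[1] * (hi[, 2] - 1) + fd[1] * fd[2] * (hi[, 3] - 1)] +
             arr[ijk[, 1] + fd[1] * (ijk[, 2] - 1) +
                   fd[1] * fd[2] * (ijk[, 3] - 1)])
  }
  sp <- sqrt(cc(sol$u, 1)^2 + cc(sol$v, 2)^2 + cc(sol$w, 3)^2)
  # port-adjacent region holds the maximum speed
  port_mask <- fluid_near_label(dom, VOXEL_LABELS[["inlet"]], 1L) |
    fluid_near_label(dom, VOXEL_LABELS[["outlet"]], 1L)
  expect_true(max(sp[port_mask[idx]]) >= max(sp) * 0.999)
  # scaffold-region speed sits below the domain median
  scaf_mask <- fluid_near_label(dom, SC, 1L)
  expect_lt(mean(sp[scaf_mask[idx]]), median(sp))
})
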