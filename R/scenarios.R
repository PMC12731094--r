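# Scenario configuration: the three chamber simulation cases and the
# analytic verification fixtures.

#' Scenario configuration
#'
#' A fully specified runnable case: chamber geometry, scaffold design, cell
#' loading, fluid and oxygen parameters, flow rate, resolution and schedule.
#'
#' @param name identifier.
#' @param chamber a [chamber_spec()].
#' @param scaffold a [scaffold_spec()] or `NULL` (no scaffolds).
#' @param loading a [cell_loading()].
#' @param fluid a [fluid_props()].
#' @param oxygen an [oxygen_params()].
#' @param flow_rate m^3 s^-1 through the full chamber.
#' @param resolution chamber grid spacing, m.
#' @param seed RNG seed (used by sphere-subtraction scaffolds).
#' @param schedule `"steady"` or `list(dt =, t_end =)`.
#' @return Object of class `scenario_config`; `$reactions` holds the
#'   derived [reaction_spec()] (Vmax from the loading, Km converted to
#'   concentration units).
#' @export
scenario_config <- function(name, chamber, scaffold, loading,
                            fluid = fluid_props(), oxygen = oxygen_params(),
                            flow_rate = 80e-6 / 60, resolution = 2e-3,
                            seed = 1L, schedule = "steady") {
  if (loading$mode == "per_scaffold" && is.null(scaffold))
    stop("per-scaffold loading needs a scaffold spec")
  if (loading$mode == "bulk" && !is.null(scaffold))
    stop("bulk loading is defined without scaffolds")
  rx <- if (loading$mode == "bulk")
    reaction_spec("volumetric", volumetric_vmax(loading, oxygen),
                  oxygen$Km_c,
                  provenance = list(n_cells = loading$n_cells,
                                    vessel_volume = loading$vessel_volume))
  else
    reaction_spec("surface", areal_vmax(loading, oxygen), oxygen$Km_c,
                  provenance = list(cells_per_scaffold = loading$n_cells,
                                    n_scaffolds = loading$n_scaffolds,
                                    area_per_scaffold =
                                      loading$area_per_scaffold))
  structure(list(name = name, chamber = chamber, scaffold = scaffold,
                 loading = loading, fluid = fluid, oxygen = oxygen,
                 flow_rate = flow_rate, resolution = resolution,
                 seed = as.integer(seed), schedule = schedule,
                 reactions = list(rx)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  rx <- x$reactions[[1]]
  cat(sprintf("<scenario_config> %s\n", x$name))
  cat(sprintf("  chamber d=%.3g m, fill %.3g mL, %d scaffolds, %s\n",
              x$chamber$diameter, x$chamber$fill_volume * 1e6,
              x$chamber$n_scaffolds,
              if (x$chamber$quarter) "quarter domain" else "full domain"))
  cat(sprintf("  flow %.3g mL/min, grid %.3g mm\n", x$flow_rate * 6e7,
              x$resolution * 1e3))
  cat(sprintf("  %s Vmax %.4g %s, Km %.4g mol/m^3\n", rx$mode, rx$vmax,
              if (rx$mode == "volumetric") "mol/m^3/s" else "mol/m^2/s",
              rx$km_c))
  invisible(x)
}

#' Named chamber simulation scenarios
#'
#' The three simulated configurations of the 8 cm bioreactor at
#' 80 mL min^-1: `bulk_11M` (11e6 cells distributed through the 110 mL
#' vessel, volumetric sink, no scaffolds) and `scaffolds_400k` /
#' `scaffolds_4M` (12 strut-lattice scaffolds at ~50% porosity with
#' 4e5 or 4e6 adherent cells each, consumption as a surface reaction over
#' the nominal 0.01 m^2 per-scaffold area).
#'
#' @param name one of `"bulk_11M"`, `"scaffolds_400k"`, `"scaffolds_4M"`.
#' @param resolution chamber grid spacing, m (default 2 mm).
#' @param seed RNG seed.
#' @return A [scenario_config()].
#' @export
bioreactor_scenario <- function(name, resolution = 2e-3, seed = 1L) {
  valid <- c("bulk_11M", "scaffolds_400k", "scaffolds_4M")
  if (!name %in% valid)
    stop("unknown scenario '", name, "'; valid names: ",
         paste(valid, collapse = ", "))
  oxy <- oxygen_params()
  if (name == "bulk_11M") {
    scenario_config(name,
                    chamber_spec(n_scaffolds = 0L),
                    scaffold = NULL,
                    loading = cell_loading("bulk", 11e6,
                                           vessel_volume = 110e-6),
                    oxygen = oxy, resolution = resolution, seed = seed)
  } else {
    n_cells <- if (name == "scaffolds_400k") 4e5 else 4e6
    scenario_config(name,
                    chamber_spec(n_scaffolds = 12L),
                    scaffold = scaffold_spec(variant = "strut_lattice",
                                             target_porosity = 0.5,
                                             seed = seed),
                    loading = cell_loading("per_scaffold", n_cells,
                                           n_scaffolds = 12L,
                                           area_per_scaffold = 0.01),
                    oxygen = oxy, resolution = resolution, seed = seed)
  }
}

#' Run a scenario end to end
#'
#' Geometry, flow and transport in sequence, followed by region summaries.
#' Deterministic for a fixed config (including its seed).
#'
#' @param config a [scenario_config()].
#' @param flow_ctrl a [flow_control()].
#' @param transport_ctrl a [transport_control()].
#' @param verbose print stage progress.
#' @return Object of class `scenario_result` with elements `domain`,
#'   `flow`, `transport`, `summary` and `config`.
#' @export
run_scenario <- function(config, flow_ctrl = flow_control(),
                         transport_ctrl = transport_control(),
                         verbose = FALSE) {
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  blocks <- NULL
  if (!is.null(config$scaffold)) {
    say("generating scaffold block (%s)", config$scaffold$variant)
    blocks <- list(generate_scaffold(config$scaffold))
  }
  say("building chamber domain at %.3g mm", config$resolution * 1e3)
  domain <- build_chamber_domain(config$chamber, blocks,
                                 resolution = config$resolution)
  say("solving flow (%.3g mL/min)", config$flow_rate * 6e7)
  flow <- solve_steady_flow(domain, config$fluid, config$flow_rate,
                            control = flow_ctrl)
  say("solving oxygen transport")
  transport <- solve_transport(domain, flow, config$oxygen,
                               config$reactions, schedule = config$schedule,
                               control = transport_ctrl)
  summary <- summarize_field(transport, domain)
  structure(list(domain = domain, flow = flow, transport = transport,
                 summary = summary, config = config,
                 elapsed = as.numeric(difftime(Sys.time(), t0,
                                               units = "secs"))),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s (%.1f s)\n", x$config$name, x$elapsed))
  print(x$summary)
  invisible(x)
}

#' Analytic verification fixtures
#'
#' Small domains paired with closed-form (or independently integrated)
#' reference solutions, used as solver oracles:
#' * `slab_consumption`: 1-D diffusion against a uniform zeroth-order sink;
#'   steady profile `c(x) = C0 - (Vmax/D)(Lx - x^2/2)`.
#' * `poiseuille_pipe`: the 1.6 mm, 80 mL/min port pipe; mean speed `Q/A`,
#'   developed centreline/mean ratio 2 and wall shear `4 mu u_m / R`.
#' * `couette`: plane shear flow, uniform `tau = mu U / gap`.
#' * `well_mixed_mm`: single well-mixed cell with a Michaelis-Menten sink;
#'   reference by high-accuracy ODE integration (requires deSolve).
#' * `closed_box`: sealed, reaction-free box; concentration stays `C0`.
#'
#' @param kind fixture name.
#' @param n resolution knob: cells across the characteristic length.
#' @return List with the fixture's `domain`, parameters, and a `reference`
#'   function (or value) evaluable on the solver output grid.
#' @export
analytic_fixture <- function(kind = c("slab_consumption", "poiseuille_pipe",
                                      "couette", "well_mixed_mm",
                                      "closed_box"), n = NULL) {
  kind <- match.arg(kind)
  params <- oxygen_params()
  W <- VOXEL_LABELS[["wall"]]
  FL <- VOXEL_LABELS[["fluid"]]
  switch(kind,
    slab_consumption = {
      N <- if (is.null(n)) 40L else n
      L <- 1e-3
      h <- L / N
      lab <- array(W, c(3, 3, N + 2L))
      lab[2, 2, 1] <- VOXEL_LABELS[["interface"]]
      lab[2, 2, 2:(N + 1)] <- FL
      vmax <- 1e-3
      list(kind = kind, domain = voxel_domain(lab, h), params = params,
           reaction = reaction_spec("volumetric", vmax, 0),
           x = (seq_len(N) - 0.5) * h,
           reference = function(x)
             params$C0 - (vmax / params$D) * (L * x - x^2 / 2))
    },
    poiseuille_pipe = {
      nc <- if (is.null(n)) 12L else n
      d <- 1.6e-3; R <- d / 2; h <- d / nc
      L_over_d <- 20L
      nside <- nc + 2L
      nz <- as.integer(round(L_over_d * d / h)) + 2L
      xc <- (seq_len(nside) - 0.5) * h - h - R
      disk <- outer(xc, xc, function(a, b) a^2 + b^2) <= R^2
      lab <- array(W, c(nside, nside, nz))
      for (k in 2:(nz - 1)) lab[, , k][disk] <- FL
      lab[, , 1][disk] <- VOXEL_LABELS[["inlet"]]
      lab[, , nz][disk] <- VOXEL_LABELS[["outlet"]]
      dev_lab <- array(W, c(nside, nside, 3L))
      for (k in 1:3) dev_lab[, , k][disk] <- FL
      Q <- 80e-6 / 60
      list(kind = kind, domain = voxel_domain(lab, h),
           domain_developed = voxel_domain(dev_lab, h),
           flow_rate = Q, radius = R,
           mean_speed = Q / (pi * R^2),
           tau_wall = 4 * 1e-3 * Q / (pi * R^2) / R,
           ratio = 2)
    },
    couette = {
      ncz <- if (is.null(n)) 8L else n
      gap <- 1e-3; h <- gap / ncz
      U <- 0.01
      lab <- array(VOXEL_LABELS[["symmetry"]], c(4L, 4L, ncz + 2L))
      lab[, , 1] <- VOXEL_LABELS[["scaffold"]]   # stationary plate
      lab[, , ncz + 2L] <- W                      # moving plate
      lab[, , 2:(ncz + 1L)] <- FL
      list(kind = kind, domain = voxel_domain(lab, h), gap = gap,
           wall_motion = list(wall = c(U, 0, 0)), U = U,
           tau = 1e-3 * U / gap)
    },
    well_mixed_mm = {
      lab <- array(W, c(3L, 3L, 3L))
      lab[2, 2, 2] <- FL
      vmax <- 3.333e-6
      list(kind = kind, domain = voxel_domain(lab, 1e-3), params = params,
           reaction = reaction_spec("volumetric", vmax, params$Km_c),
           reference = function(times) {
             if (!requireNamespace("deSolve", quietly = TRUE))
               stop("the well-mixed reference requires deSolve")
             out <- deSolve::ode(y = c(c = params$C0), times = times,
                                 parms = NULL,
                                 func = function(t, y, p)
                                   list(-vmax * y / (y + params$Km_c)),
                                 rtol = 1e-10, atol = 1e-12)
             out[, 2]
           })
    },
    closed_box = {
      nb <- if (is.null(n)) 4L else n
      lab <- array(W, c(nb + 2L, nb + 2L, nb + 2L))
      lab[2:(nb + 1L), 2:(nb + 1L), 2:(nb + 1L)] <- FL
      list(kind = kind, domain = voxel_domain(lab, 1e-3), params = params,
           reference = params$C0)
    })
}
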