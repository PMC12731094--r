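# Dissolved-oxygen transport: advection + diffusion + Michaelis-Menten
# consumption on a voxel domain, using the staggered face velocities of a
# flow solution.
#
# Finite-volume, first-order upwind advection, central diffusion. The
# steady problem is solved directly (sparse LU) with Picard iteration on
# the Michaelis-Menten denominators and on the recirculation condition
# (inlet concentration = flux-weighted outlet mean). A transient mode
# (implicit diffusion/reaction, explicit upwind advection under a CFL
# limit) serves time-resolved runs and the ODE-comparison fixtures. The
# upwind M-matrix structure keeps concentrations within [0, C0] when
# boundary values are and sinks only consume.

#' Transport solver control settings
#'
#' @param max_picard Picard iteration cap for the steady solve.
#' @param tol_steady absolute convergence tolerance on the concentration
#'   update, mol m^-3.
#' @param steady_rate_tol transient steady-state declaration threshold on
#'   `max |dc| / dt`, mol m^-3 s^-1.
#' @param cfl advective CFL safety factor for transient steps.
#' @param verbose print iteration diagnostics.
#' @export
transport_control <- function(max_picard = 80L, tol_steady = 1e-9,
                              steady_rate_tol = 1e-9, cfl = 0.9,
                              verbose = FALSE) {
  list(max_picard = as.integer(max_picard), tol_steady = tol_steady,
       steady_rate_tol = steady_rate_tol, cfl = cfl, verbose = verbose)
}

# face-neighbour tables for the fluid cells of a domain
transport_setup <- function(domain, velocity) {
  lab <- domain$labels
  h <- domain$spacing
  dmn <- dim(lab)
  FLUID <- VOXEL_LABELS[["fluid"]]
  fc <- which(lab == FLUID)
  row_of <- array(NA_integer_, dmn)
  row_of[fc] <- seq_along(fc)
  ijk <- arrayInd(fc, dmn)
  N <- length(fc)

  sides <- list()
  for (ax in 1:3) for (dsgn in c(-1L, 1L)) {
    nb <- ijk; nb[, ax] <- nb[, ax] + dsgn
    code <- lab[vox_index(dmn, nb[, 1], nb[, 2], nb[, 3])]
    nb_row <- rep(NA_integer_, N)
    isf <- code == FLUID
    nb_row[isf] <- row_of[vox_index(dmn, nb[isf, 1], nb[isf, 2],
                                    nb[isf, 3])]
    q_out <- numeric(N)   # outward volumetric flux, m^3/s (positive = out)
    if (!is.null(velocity)) {
      va <- switch(ax, velocity$u, velocity$v, velocity$w)
      fdim <- dim(va)
      fidx <- ijk
      if (dsgn > 0) fidx[, ax] <- fidx[, ax] + 1L
      vals <- va[vox_index(fdim, fidx[, 1], fidx[, 2], fidx[, 3])]
      q_out <- dsgn * vals * h^2
    }
    sides[[length(sides) + 1L]] <- list(code = code, nb_row = nb_row,
                                        q_out = q_out)
  }
  list(fc = fc, row_of = row_of, ijk = ijk, N = N, h = h, sides = sides,
       dmn = dmn)
}

# constant (Picard-independent) operator pieces.
# Advection: A_adv (off-diagonal) + dg_adv (diagonal), inflow coupling
# b_in_coef * c_inlet; outflow coefficients out_q at outlet faces.
# Diffusion: A_diff + dg_diff, Dirichlet source b0 on interface faces.
transport_base <- function(setup, params, reactions) {
  N <- setup$N
  h <- setup$h
  A <- h^2
  V <- h^3
  D <- params$D
  C0 <- params$C0
  ia <- integer(0); ja <- integer(0); xa <- numeric(0)
  id <- integer(0); jd <- integer(0); xd <- numeric(0)
  dg_adv <- numeric(N); dg_diff <- numeric(N)
  b0 <- numeric(N)
  b_in_coef <- numeric(N)
  out_q <- numeric(N)
  surf_cnt <- numeric(N)
  IFACE <- VOXEL_LABELS[["interface"]]
  INLET <- VOXEL_LABELS[["inlet"]]
  OUTLET <- VOXEL_LABELS[["outlet"]]
  SCAF <- VOXEL_LABELS[["scaffold"]]

  surface_rx <- Filter(function(r) r$mode == "surface", reactions)
  vol_rx <- Filter(function(r) r$mode == "volumetric", reactions)
  # per-reaction fluid-cell masks for region-restricted volumetric sinks
  vol_rx <- lapply(vol_rx, function(r) {
    r$mask <- if (is.null(r$region)) rep(TRUE, N) else r$region[setup$fc]
    r
  })

  for (s in setup$sides) {
    isf <- !is.na(s$nb_row)
    q <- s$q_out
    qpos <- pmax(q, 0); qneg <- pmin(q, 0)
    sel <- which(isf)
    # upwind advection between fluid cells
    dg_adv <- dg_adv + ifelse(isf, qpos, 0)
    ia <- c(ia, sel); ja <- c(ja, s$nb_row[sel]); xa <- c(xa, qneg[sel])
    # central diffusion between fluid cells
    id <- c(id, sel); jd <- c(jd, s$nb_row[sel])
    xd <- c(xd, rep(-D * A / h, length(sel)))
    dg_diff <- dg_diff + ifelse(isf, D * A / h, 0)
    # Dirichlet C0 at the air-liquid interface (half-cell distance)
    bif <- s$code == IFACE
    dg_diff <- dg_diff + ifelse(bif, 2 * D * A / h, 0)
    b0 <- b0 + ifelse(bif, 2 * D * A / h * C0, 0)
    # ports
    bin <- s$code == INLET
    b_in_coef <- b_in_coef + ifelse(bin, -qneg, 0)
    bout <- s$code == OUTLET
    dg_adv <- dg_adv + ifelse(bout, qpos, 0)
    out_q <- out_q + ifelse(bout, qpos, 0)
    # reacting surface face counts
    if (length(surface_rx))
      surf_cnt <- surf_cnt + (s$code == SCAF)
  }
  A_adv <- Matrix::sparseMatrix(i = ia, j = ja, x = xa, dims = c(N, N))
  A_diff <- Matrix::sparseMatrix(i = id, j = jd, x = xd, dims = c(N, N))
  list(A_adv = A_adv, A_diff = A_diff, dg_adv = dg_adv, dg_diff = dg_diff,
       b0 = b0, b_in_coef = b_in_coef, out_q = out_q, surf_cnt = surf_cnt,
       surface_rx = surface_rx, vol_rx = vol_rx, A = A, V = V)
}

# Picard-linearized reaction contributions at iterate c_old
reaction_terms <- function(base, c_old) {
  N <- length(base$dg_adv)
  dg <- numeric(N); rhs <- numeric(N)
  for (r in base$vol_rx) {
    if (r$vmax == 0) next
    if (r$km_c == 0) rhs <- rhs - base$V * r$vmax * r$mask
    else dg <- dg + base$V * r$vmax * r$mask / (c_old + r$km_c)
  }
  for (r in base$surface_rx) {
    if (r$vmax == 0) next
    if (r$km_c == 0) rhs <- rhs - base$A * base$surf_cnt * r$vmax
    else dg <- dg + base$A * base$surf_cnt * r$vmax / (c_old + r$km_c)
  }
  list(dg = dg, rhs = rhs)
}

consumed_rate <- function(base, cvec) {
  tot <- 0
  for (r in base$vol_rx)
    tot <- tot + sum(base$V * mm_rate(pmax(cvec, 0), r$vmax, r$km_c) *
                       r$mask)
  for (r in base$surface_rx)
    tot <- tot + sum(base$A * base$surf_cnt *
                       mm_rate(pmax(cvec, 0), r$vmax, r$km_c))
  tot
}

mean_outlet <- function(base, cvec) {
  qt <- sum(base$out_q)
  if (qt <= 0) return(NA_real_)
  sum(base$out_q * cvec) / qt
}

#' Solve dissolved-oxygen transport
#'
#' Steady or transient oxygen transport with Michaelis-Menten sinks on a
#' flow solution's velocity field. Boundary conditions: Dirichlet `C0` on
#' `interface` labels (Henry equilibrium with the incubator atmosphere),
#' zero flux on walls and symmetry planes, advective outflow at `outlet`
#' faces, and a closed-loop recirculation condition setting the inlet
#' concentration to the flux-weighted outlet mean at every Picard
#' iteration / time step (medium returns through gas-impermeable-assumed
#' tubing instantaneously).
#'
#' @param domain a [voxel_domain()].
#' @param velocity a `flow_solution` on the same domain, or `NULL` for pure
#'   diffusion-reaction.
#' @param params an [oxygen_params()].
#' @param reactions a [reaction_spec()] or list of them (volumetric sinks
#'   act on all fluid cells; surface sinks on fluid faces adjacent to
#'   `scaffold` voxels).
#' @param schedule `"steady"` (default) or `list(dt = , t_end = )` for a
#'   transient run; `dt` is reduced to the advective CFL limit if needed.
#' @param c_init initial concentration, mol m^-3 (default `params$C0`: the
#'   medium starts equilibrated with the incubator atmosphere).
#' @param control a [transport_control()].
#' @return Object of class `transport_solution`: concentration array `c`
#'   (mol m^-3, `NA` outside fluid), the fluid-cell vector `cells`, steady
#'   flag, recirculated inlet concentration, per-step `history` and an
#'   oxygen `budget` (interface influx, port fluxes, consumption, residual;
#'   mol s^-1).
#' @export
solve_transport <- function(domain, velocity = NULL,
                            params = oxygen_params(), reactions = list(),
                            schedule = "steady", c_init = NULL,
                            control = transport_control()) {
  if (inherits(reactions, "reaction_spec")) reactions <- list(reactions)
  setup <- transport_setup(domain, velocity)
  base <- transport_base(setup, params, reactions)
  N <- setup$N
  V <- base$V
  c_init <- if (is.null(c_init)) params$C0 else c_init
  cvec <- rep(c_init, length.out = N)
  c_in <- mean_outlet(base, cvec)
  has_ports <- any(base$b_in_coef > 0)
  cin_or0 <- function() if (is.na(c_in)) 0 else c_in

  steady <- identical(schedule, "steady")
  history <- list()
  is_steady <- FALSE
  time <- 0
  undriven <- all(base$b0 == 0) && !has_ports &&
    length(base$vol_rx) == 0L && length(base$surface_rx) == 0L

  if (steady && undriven) {
    # sealed, reaction-free domain: any uniform field is steady, so the
    # initial equilibrium is preserved
    is_steady <- TRUE
    time <- Inf
  } else if (steady) {
    for (it in seq_len(control$max_picard)) {
      rx <- reaction_terms(base, cvec)
      Amat <- base$A_adv + base$A_diff +
        Matrix::Diagonal(N, base$dg_adv + base$dg_diff + rx$dg)
      if (has_ports) {
        # the recirculation condition c_in = outlet_mean(c) is solved
        # exactly: c = c_h + c_in * c_g is linear in c_in for fixed
        # Picard coefficients
        sols <- as.matrix(Matrix::solve(Amat, cbind(base$b0 + rx$rhs,
                                                    base$b_in_coef)))
        m_h <- mean_outlet(base, sols[, 1])
        m_g <- mean_outlet(base, sols[, 2])
        c_in <- if (m_g < 1) m_h / (1 - m_g) else m_h
        c_new <- sols[, 1] + c_in * sols[, 2]
      } else {
        c_new <- as.numeric(Matrix::solve(Amat, base$b0 + rx$rhs))
      }
      dmax <- max(abs(c_new - cvec))
      cvec <- c_new
      history[[it]] <- data.frame(step = it, time = NA_real_,
                                  mean = mean(cvec), min = min(cvec),
                                  max = max(cvec), dmax = dmax)
      if (control$verbose)
        message(sprintf("picard %3d  mean %.6g uM  dmax %.3g", it,
                        1e3 * mean(cvec), dmax))
      if (dmax < control$tol_steady) break
    }
    is_steady <- TRUE
    time <- Inf
  } else {
    dt <- schedule$dt
    t_end <- schedule$t_end
    if (is.null(dt) || is.null(t_end))
      stop("transient schedule needs dt and t_end")
    qmax <- max(vapply(setup$sides, function(s) max(abs(s$q_out)),
                       numeric(1)))
    if (qmax > 0) {
      dt_cfl <- control$cfl * V / qmax
      if (dt > dt_cfl) {
        message(sprintf(
          "dt reduced from %.3g to %.3g s (advective CFL limit)", dt,
          dt_cfl))
        dt <- dt_cfl
      }
    }
    nsteps <- ceiling(t_end / dt)
    every <- max(1L, nsteps %/% 200L)
    for (st in seq_len(nsteps)) {
      adv <- as.numeric(base$A_adv %*% cvec) + base$dg_adv * cvec -
        base$b_in_coef * cin_or0()
      cstar <- cvec - dt / V * adv
      rx <- reaction_terms(base, cvec)
      Amat <- base$A_diff +
        Matrix::Diagonal(N, V / dt + base$dg_diff + rx$dg)
      b <- V / dt * cstar + base$b0 + rx$rhs
      c_new <- as.numeric(Matrix::solve(Amat, b))
      dmax <- max(abs(c_new - cvec))
      cvec <- c_new
      time <- time + dt
      if (has_ports) c_in <- mean_outlet(base, cvec)
      if (st %% every == 0L || st == nsteps || dmax / dt <
            control$steady_rate_tol) {
        history[[length(history) + 1L]] <-
          data.frame(step = st, time = time, mean = mean(cvec),
                     min = min(cvec), max = max(cvec), dmax = dmax)
      }
      if (dmax / dt < control$steady_rate_tol) { is_steady <- TRUE; break }
    }
  }

  carr <- array(NA_real_, setup$dmn)
  carr[setup$fc] <- cvec
  budget <- transport_budget(base, setup, params, cvec, c_in)
  structure(list(c = carr, cells = cvec, steady = is_steady, time = time,
                 c_inlet = c_in,
                 history = do.call(rbind, history),
                 budget = budget, params = params, reactions = reactions,
                 spacing = setup$h),
            class = "transport_solution")
}

transport_budget <- function(base, setup, params, cvec, c_in) {
  h <- setup$h
  IFACE <- VOXEL_LABELS[["interface"]]
  iface_flux <- 0
  for (s in setup$sides) {
    bif <- s$code == IFACE
    if (any(bif))
      iface_flux <- iface_flux +
        sum(2 * params$D * h * (params$C0 - cvec[bif]))
  }
  inlet_in <- sum(base$b_in_coef) * if (is.na(c_in)) 0 else c_in
  outlet_out <- sum(base$out_q * cvec)
  consumed <- consumed_rate(base, cvec)
  list(interface_influx = iface_flux, inlet_influx = inlet_in,
       outlet_outflux = outlet_out, consumed = consumed,
       residual = iface_flux + inlet_in - outlet_out - consumed)
}

#' @export
print.transport_solution <- function(x, ...) {
  cat("<transport_solution>", if (x$steady) "steady" else
    sprintf("t = %.4g s", x$time), "\n")
  cat(sprintf("  concentration %.4g - %.4g uM (mean %.4g uM)\n",
              1e3 * min(x$cells), 1e3 * max(x$cells), 1e3 * mean(x$cells)))
  if (!is.na(x$c_inlet))
    cat(sprintf("  recirculated inlet %.4g uM\n", 1e3 * x$c_inlet))
  cat(sprintf("  O2 budget residual %.3g mol/s (consumed %.3g mol/s)\n",
              x$budget$residual, x$budget$consumed))
  invisible(x)
}
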