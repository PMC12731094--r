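# Steady incompressible laminar flow on a voxel domain.
#
# Finite-volume discretization on a staggered (MAC) grid: velocity components
# live on cell faces, pressure at cell centres. Steady state is approached by
# pseudo-time iteration: explicit first-order upwind advection + explicit
# viscous diffusion, followed by an exact pressure projection (sparse
# Cholesky, factorized once). No-slip on walls and scaffold solid, free-slip
# on the air-liquid interface and symmetry planes, prescribed plug velocities
# on inlet/outlet port faces.

#' Flow solver control settings
#'
#' @param max_iter pseudo-time iteration cap.
#' @param tol convergence tolerance on the relative momentum residual,
#'   the maximum per-step velocity change over the velocity scale.
#' @param safety CFL safety factor (advective and viscous limits).
#' @param check_every residual evaluation interval (steps).
#' @param verbose print residuals while iterating.
#' @export
flow_control <- function(max_iter = 10000L, tol = 1e-6, safety = 0.9,
                         check_every = 20L, verbose = FALSE) {
  list(max_iter = as.integer(max_iter), tol = tol, safety = safety,
       check_every = as.integer(check_every), verbose = verbose)
}

FREE_SLIP_LABELS <- c(4L, 7L)  # interface, symmetry

# Build the per-component staggered face tables used by the stepper.
# comp: 1 (u), 2 (v), 3 (w). Returns classification arrays plus index/ghost
# tables for the unknown faces.
face_setup <- function(lab, comp, q_in_speed, q_out_speed, wall_motion) {
  dmn <- dim(lab)
  fdim <- dmn; fdim[comp] <- fdim[comp] + 1L
  n_face <- prod(fdim)
  FLUID <- VOXEL_LABELS[["fluid"]]

  # adjacent cell labels for every face (0 outside the array)
  pad_lo <- function(a) {
    # label of cell on the low side of each face along `comp`
    out <- array(0L, fdim)
    idx_lo <- slice.index(out, comp) >= 2L
    out[idx_lo] <- a
    out
  }
  pad_hi <- function(a) {
    out <- array(0L, fdim)
    idx_hi <- slice.index(out, comp) <= dmn[comp]
    out[idx_hi] <- a
    out
  }
  lab_lo <- pad_lo(lab)
  lab_hi <- pad_hi(lab)

  type <- array(0L, fdim)   # 0 inactive, 1 unknown, 2 prescribed
  val <- array(0, fdim)
  both_fluid <- lab_lo == FLUID & lab_hi == FLUID
  one_fluid <- xor(lab_lo == FLUID, lab_hi == FLUID)
  type[both_fluid] <- 1L
  type[one_fluid] <- 2L
  other <- ifelse(lab_lo == FLUID, lab_hi, lab_lo)
  into_fluid <- ifelse(lab_lo == FLUID, -1, 1)  # sign of flow entering fluid
  is_in <- one_fluid & other == VOXEL_LABELS[["inlet"]]
  is_out <- one_fluid & other == VOXEL_LABELS[["outlet"]]
  val[is_in] <- into_fluid[is_in] * q_in_speed
  val[is_out] <- -into_fluid[is_out] * q_out_speed
  # moving no-slip boundaries contribute only tangentially; the normal
  # component at a wall face stays zero

  list(fdim = fdim, type = type, val = val,
       lab_lo = lab_lo, lab_hi = lab_hi)
}

# ghost classification for a missing tangential neighbour: looks at the two
# cells adjacent to the absent face; returns list(s, t)
ghost_for <- function(labA, labB, comp, wall_motion) {
  n <- length(labA)
  s <- rep(-1, n); t <- rep(0, n)
  free <- (labA %in% FREE_SLIP_LABELS | labA == 0L) &
          (labB %in% FREE_SLIP_LABELS | labB == 0L)
  s[free] <- 1
  if (!is.null(wall_motion)) {
    for (nm in names(wall_motion)) {
      code <- VOXEL_LABELS[[nm]]
      uw <- wall_motion[[nm]][comp]
      mov <- !free & (labA == code | labB == code)
      t[mov] <- 2 * uw
    }
  }
  list(s = s, t = t)
}

# linear indices with an axis shift, vectorized over a set of faces
shift_idx <- function(ijk, fdim, axis, by) {
  ijk2 <- ijk
  ijk2[, axis] <- ijk2[, axis] + by
  ok <- ijk2[, axis] >= 1L & ijk2[, axis] <= fdim[axis]
  idx <- rep(NA_integer_, nrow(ijk2))
  idx[ok] <- vox_index(fdim, ijk2[ok, 1], ijk2[ok, 2], ijk2[ok, 3])
  idx
}

build_component <- function(lab, comp, fs, wall_motion) {
  fdim <- fs$fdim
  unk <- which(fs$type == 1L)
  if (!length(unk))
    return(list(unk = integer(0)))
  ijk <- arrayInd(unk, fdim)
  axes <- 1:3
  tang <- setdiff(axes, comp)

  nb <- list(); act <- list(); gs <- list(); gt <- list()
  for (ax in axes) for (dsgn in c(-1L, 1L)) {
    key <- paste0(ax, ifelse(dsgn < 0, "m", "p"))
    idx <- shift_idx(ijk, fdim, ax, dsgn)
    a <- !is.na(idx) & fs$type[ifelse(is.na(idx), 1L, idx)] != 0L
    if (ax == comp) {
      # longitudinal neighbours of an unknown face are always active
      nb[[key]] <- idx
      act[[key]] <- rep(1, length(idx))
      gs[[key]] <- rep(0, length(idx)); gt[[key]] <- rep(0, length(idx))
    } else {
      idx_safe <- ifelse(a, idx, unk)
      # ghost from the two cells beside the missing neighbour face
      cell_dim <- dim(lab)
      cA <- ijk; cA[, ax] <- cA[, ax] + dsgn; cA[, comp] <- cA[, comp] - 1L
      cB <- ijk; cB[, ax] <- cB[, ax] + dsgn
      labAt <- function(cc) {
        ok <- cc[, 1] >= 1 & cc[, 1] <= cell_dim[1] &
              cc[, 2] >= 1 & cc[, 2] <= cell_dim[2] &
              cc[, 3] >= 1 & cc[, 3] <= cell_dim[3]
        out <- rep(0L, nrow(cc))
        out[ok] <- lab[vox_index(cell_dim, cc[ok, 1], cc[ok, 2], cc[ok, 3])]
        out
      }
      gh <- ghost_for(labAt(cA), labAt(cB), comp, wall_motion)
      nb[[key]] <- idx_safe
      act[[key]] <- as.numeric(a)
      gs[[key]] <- gh$s; gt[[key]] <- gh$t
    }
  }

  # transverse advecting velocities: 4 surrounding faces of the other
  # staggered components. For component `comp` face at ijk, the component
  # `oc` faces involved are at cell rows (comp-index -1, 0) x (oc-shift 0, +1).
  trans <- list()
  for (oc in tang) {
    ocdim <- dim(lab); ocdim[oc] <- ocdim[oc] + 1L
    mk <- function(d_comp, d_oc) {
      cc <- ijk
      cc[, comp] <- cc[, comp] + d_comp   # cell index on low/high side
      cc[, oc] <- cc[, oc] + d_oc
      cc[, 1] <- pmin(pmax(cc[, 1], 1L), ocdim[1])
      cc[, 2] <- pmin(pmax(cc[, 2], 1L), ocdim[2])
      cc[, 3] <- pmin(pmax(cc[, 3], 1L), ocdim[3])
      vox_index(ocdim, cc[, 1], cc[, 2], cc[, 3])
    }
    trans[[as.character(oc)]] <- list(i1 = mk(-1L, 0L), i2 = mk(0L, 0L),
                                      i3 = mk(-1L, 1L), i4 = mk(0L, 1L))
  }

  list(unk = unk, ijk = ijk, nb = nb, act = act, gs = gs, gt = gt,
       trans = trans)
}

#' Solve steady laminar flow on a voxel domain
#'
#' @param domain a [voxel_domain()] with at least one `inlet` and one
#'   `outlet` voxel (unless `flow_rate = 0`).
#' @param fluid a [fluid_props()].
#' @param flow_rate volumetric flow rate through the full chamber, m^3 s^-1;
#'   a quarter-symmetry domain receives `flow_rate / 4`.
#' @param control a [flow_control()].
#' @param wall_motion optional named list (label name -> length-3 velocity,
#'   m/s) giving tangential velocities of moving no-slip boundaries (used by
#'   the planar Couette fixture).
#' @return Object of class `flow_solution`: staggered velocity arrays
#'   `u`, `v`, `w` (m/s), cell pressure `p` (Pa), residual history,
#'   iteration count, convergence flag and inlet/outlet flux balance.
#' @export
solve_steady_flow <- function(domain, fluid = fluid_props(), flow_rate,
                              control = flow_control(), wall_motion = NULL) {
  lab <- domain$labels
  h <- domain$spacing
  nu <- fluid$viscosity / fluid$density
  if (flow_rate < 0) stop("flow_rate must be >= 0")
  q_dom <- if (isTRUE(domain$meta$quarter)) flow_rate / 4 else flow_rate

  FLUID <- VOXEL_LABELS[["fluid"]]
  dmn <- dim(lab)

  # port face counts (faces between fluid and inlet/outlet voxels)
  count_port_faces <- function(code) {
    n <- 0L
    for (comp in 1:3) {
      lo <- slice_pair(lab, comp)
      n <- n + sum(lo$a == FLUID & lo$b == code) +
        sum(lo$b == FLUID & lo$a == code)
    }
    n
  }
  n_in <- count_port_faces(VOXEL_LABELS[["inlet"]])
  n_out <- count_port_faces(VOXEL_LABELS[["outlet"]])
  if (q_dom > 0 && (n_in == 0L || n_out == 0L))
    stop("domain needs inlet and outlet faces adjacent to fluid")
  q_in_speed <- if (n_in > 0) q_dom / (n_in * h^2) else 0
  q_out_speed <- if (n_out > 0) q_dom / (n_out * h^2) else 0

  fs <- lapply(1:3, function(comp)
    face_setup(lab, comp, q_in_speed, q_out_speed, wall_motion))
  comp_tab <- lapply(1:3, function(comp)
    build_component(lab, comp, fs[[comp]], wall_motion))

  U <- fs[[1]]$val; V <- fs[[2]]$val; W <- fs[[3]]$val

  # pressure Poisson operator over fluid cells
  fc <- which(lab == FLUID)
  row_of <- array(NA_integer_, dmn)
  row_of[fc] <- seq_along(fc)
  ijk_c <- arrayInd(fc, dmn)
  ii <- integer(0); jj <- integer(0)
  diag_n <- numeric(length(fc))
  for (ax in 1:3) for (dsgn in c(-1L, 1L)) {
    cc <- ijk_c; cc[, ax] <- cc[, ax] + dsgn
    ok <- cc[, ax] >= 1L & cc[, ax] <= dmn[ax]
    nb_row <- rep(NA_integer_, nrow(cc))
    nb_row[ok] <- row_of[vox_index(dmn, cc[ok, 1], cc[ok, 2], cc[ok, 3])]
    link <- !is.na(nb_row)
    ii <- c(ii, which(link)); jj <- c(jj, nb_row[link])
    diag_n <- diag_n + link
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_along(fc)),
                            j = c(jj, seq_along(fc)),
                            x = c(rep(-1, length(ii)), diag_n + 1e-10),
                            dims = c(length(fc), length(fc))) / h^2
  A[1, 1] <- A[1, 1] + 1 / h^2   # ground the Neumann null space
  chol_A <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)

  # divergence face indices per fluid cell
  face_of <- function(comp, d) {
    fdim <- fs[[comp]]$fdim
    cc <- ijk_c
    if (d > 0) cc[, comp] <- cc[, comp] + 1L
    vox_index(fdim, cc[, 1], cc[, 2], cc[, 3])
  }
  fxm <- face_of(1, 0); fxp <- face_of(1, 1)
  fym <- face_of(2, 0); fyp <- face_of(2, 1)
  fzm <- face_of(3, 0); fzp <- face_of(3, 1)

  # gradient-correction rows for unknown faces
  grad_rows <- lapply(1:3, function(comp) {
    tab <- comp_tab[[comp]]
    if (!length(tab$unk)) return(NULL)
    cl <- tab$ijk; cl[, comp] <- cl[, comp] - 1L
    ch <- tab$ijk
    list(lo = row_of[vox_index(dmn, cl[, 1], cl[, 2], cl[, 3])],
         hi = row_of[vox_index(dmn, ch[, 1], ch[, 2], ch[, 3])])
  })

  flat <- list(U, V, W)
  zero_flow <- q_dom == 0 && is.null(wall_motion)
  iterations <- 0L
  res_hist <- numeric(0)
  converged <- zero_flow
  phi <- numeric(length(fc))
  uref0 <- max(q_in_speed, q_out_speed,
               if (length(wall_motion)) max(abs(unlist(wall_motion))) else 0)

  if (!zero_flow) {
    step_comp <- function(comp, flatU, vel_others, dt) {
      tab <- comp_tab[[comp]]
      if (!length(tab$unk)) return(flatU)
      u <- flatU[tab$unk]
      valn <- function(key) {
        a <- tab$act[[key]]
        a * flatU[tab$nb[[key]]] + (1 - a) * (tab$gs[[key]] * u +
                                                tab$gt[[key]])
      }
      keys <- c(paste0(1:3, "m"), paste0(1:3, "p"))
      vxm <- valn(paste0(1, "m")); vxp <- valn(paste0(1, "p"))
      vym <- valn(paste0(2, "m")); vyp <- valn(paste0(2, "p"))
      vzm <- valn(paste0(3, "m")); vzp <- valn(paste0(3, "p"))
      lap <- (vxm + vxp + vym + vyp + vzm + vzp - 6 * u) / h^2
      adv <- numeric(length(u))
      for (ax in 1:3) {
        if (ax == comp) {
          vel <- u
        } else {
          tr <- tab$trans[[as.character(ax)]]
          vo <- vel_others[[ax]]
          vel <- 0.25 * (vo[tr$i1] + vo[tr$i2] + vo[tr$i3] + vo[tr$i4])
        }
        vm <- switch(ax, vxm, vym, vzm)
        vp <- switch(ax, vxp, vyp, vzp)
        gradm <- (u - vm) / h
        gradp <- (vp - u) / h
        adv <- adv + ifelse(vel > 0, vel * gradm, vel * gradp)
      }
      flatU[tab$unk] <- u + dt * (nu * lap - adv)
      flatU
    }

    for (it in seq_len(control$max_iter)) {
      umax <- max(abs(flat[[1]]), abs(flat[[2]]), abs(flat[[3]]), uref0,
                  1e-12)
      dt <- control$safety * min(h / umax, h^2 / (6 * nu))
      prev <- flat
      vel_others <- flat
      for (comp in 1:3)
        flat[[comp]] <- step_comp(comp, flat[[comp]], vel_others, dt)
      # projection
      div <- (flat[[1]][fxp] - flat[[1]][fxm] +
                flat[[2]][fyp] - flat[[2]][fym] +
                flat[[3]][fzp] - flat[[3]][fzm]) / h
      phi <- as.numeric(Matrix::solve(chol_A, -div / dt))
      for (comp in 1:3) {
        gr <- grad_rows[[comp]]
        if (is.null(gr)) next
        tab <- comp_tab[[comp]]
        flat[[comp]][tab$unk] <- flat[[comp]][tab$unk] -
          dt * (phi[gr$hi] - phi[gr$lo]) / h
      }
      iterations <- it
      if (it %% control$check_every == 0L || it == control$max_iter) {
        dmax <- max(abs(flat[[1]] - prev[[1]]), abs(flat[[2]] - prev[[2]]),
                    abs(flat[[3]] - prev[[3]]))
        rel <- dmax / umax
        res_hist <- c(res_hist, rel)
        if (control$verbose)
          message(sprintf("iter %6d  dt %.3g  rel.res %.3g", it, dt, rel))
        if (rel < control$tol) { converged <- TRUE; break }
      }
    }
  }

  U <- array(flat[[1]], fs[[1]]$fdim)
  V <- array(flat[[2]], fs[[2]]$fdim)
  W <- array(flat[[3]], fs[[3]]$fdim)
  p <- array(NA_real_, dmn)
  p[fc] <- fluid$density * phi

  q_in_meas <- q_in_speed * n_in * h^2
  q_out_meas <- q_out_speed * n_out * h^2
  mass_err <- if (q_in_meas > 0) abs(q_in_meas - q_out_meas) / q_in_meas else 0

  structure(list(u = U, v = V, w = W, p = p,
                 iterations = iterations, converged = converged,
                 residuals = res_hist,
                 q_in = q_in_meas, q_out = q_out_meas,
                 mass_error = mass_err,
                 inlet_speed = q_in_speed, outlet_speed = q_out_speed,
                 fluid = fluid, spacing = h),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("<flow_solution>\n")
  cat(sprintf("  iterations %d (%s), final residual %.3g\n", x$iterations,
              if (x$converged) "converged" else "iteration cap",
              if (length(x$residuals)) x$residuals[length(x$residuals)] else 0))
  cat(sprintf("  Q_in %.4g mL/min, Q_out %.4g mL/min (imbalance %.2g%%)\n",
              x$q_in * 6e7, x$q_out * 6e7, 100 * x$mass_error))
  cat(sprintf("  max |u| %.4g m/s\n", max(abs(x$u), abs(x$v), abs(x$w))))
  invisible(x)
}

# paired low/high cell labels across faces along one axis
slice_pair <- function(lab, axis) {
  d <- dim(lab)
  idx <- seq_len(d[axis] - 1L)
  if (axis == 1) list(a = lab[idx, , , drop = FALSE],
                      b = lab[idx + 1L, , , drop = FALSE])
  else if (axis == 2) list(a = lab[, idx, , drop = FALSE],
                           b = lab[, idx + 1L, , drop = FALSE])
  else list(a = lab[, , idx, drop = FALSE],
            b = lab[, , idx + 1L, drop = FALSE])
}

#' Maximum discrete divergence over fluid cells
#'
#' Verifies the discrete continuity equation of a flow solution.
#'
#' @param sol a `flow_solution`.
#' @param domain the [voxel_domain()] it was solved on.
#' @return Maximum absolute divergence, s^-1.
#' @export
max_divergence <- function(sol, domain) {
  lab <- domain$labels
  h <- domain$spacing
  fc <- which(lab == VOXEL_LABELS[["fluid"]])
  ijk <- arrayInd(fc, dim(lab))
  fdimU <- dim(sol$u); fdimV <- dim(sol$v); fdimW <- dim(sol$w)
  ip <- ijk; ip[, 1] <- ip[, 1] + 1L
  jp <- ijk; jp[, 2] <- jp[, 2] + 1L
  kp <- ijk; kp[, 3] <- kp[, 3] + 1L
  div <- (sol$u[vox_index(fdimU, ip[, 1], ip[, 2], ip[, 3])] -
            sol$u[vox_index(fdimU, ijk[, 1], ijk[, 2], ijk[, 3])] +
            sol$v[vox_index(fdimV, jp[, 1], jp[, 2], jp[, 3])] -
            sol$v[vox_index(fdimV, ijk[, 1], ijk[, 2], ijk[, 3])] +
            sol$w[vox_index(fdimW, kp[, 1], kp[, 2], kp[, 3])] -
            sol$w[vox_index(fdimW, ijk[, 1], ijk[, 2], ijk[, 3])]) / h
  max(abs(div))
}

#' Wall shear stress on no-slip surfaces
#'
#' One-sided estimate on every fluid cell face adjacent to `wall` or
#' `scaffold` voxels: the tangential velocity at the adjacent cell centre
#' (minus any wall motion), a half-spacing away from the boundary, gives
#' `tau = mu * |u_t| / (h/2)`.
#'
#' @param sol a `flow_solution`.
#' @param domain the [voxel_domain()] it was solved on.
#' @param fluid a [fluid_props()].
#' @param labels solid labels to include (default wall and scaffold).
#' @param wall_motion optional named list of moving-wall velocities, as in
#'   [solve_steady_flow()].
#' @return Data frame with one row per surface face: voxel indices `i, j, k`
#'   of the fluid cell, outward direction `axis` (1-3) and `side` (-1/+1),
#'   solid `label`, face `area` (m^2) and `tau` (Pa).
#' @export
wall_shear_stress <- function(sol, domain, fluid = fluid_props(),
                              labels = c("wall", "scaffold"),
                              wall_motion = NULL) {
  lab <- domain$labels
  h <- domain$spacing
  dmn <- dim(lab)
  codes <- VOXEL_LABELS[labels]
  fc_mask <- lab == VOXEL_LABELS[["fluid"]]
  out <- list()
  fdimU <- dim(sol$u); fdimV <- dim(sol$v); fdimW <- dim(sol$w)
  center_vel <- function(comp, ijk) {
    fd <- switch(comp, fdimU, fdimV, fdimW)
    arr <- switch(comp, sol$u, sol$v, sol$w)
    hi <- ijk; hi[, comp] <- hi[, comp] + 1L
    0.5 * (arr[vox_index(fd, ijk[, 1], ijk[, 2], ijk[, 3])] +
             arr[vox_index(fd, hi[, 1], hi[, 2], hi[, 3])])
  }
  for (ax in 1:3) for (dsgn in c(-1L, 1L)) {
    fcells <- which(fc_mask)
    ijk <- arrayInd(fcells, dmn)
    nb <- ijk; nb[, ax] <- nb[, ax] + dsgn
    ok <- nb[, ax] >= 1L & nb[, ax] <= dmn[ax]
    nb_lab <- rep(0L, nrow(nb))
    nb_lab[ok] <- lab[vox_index(dmn, nb[ok, 1], nb[ok, 2], nb[ok, 3])]
    sel <- nb_lab %in% codes
    if (!any(sel)) next
    ijk_s <- ijk[sel, , drop = FALSE]
    tang <- setdiff(1:3, ax)
    ut1 <- center_vel(tang[1], ijk_s)
    ut2 <- center_vel(tang[2], ijk_s)
    if (!is.null(wall_motion)) {
      nmv <- names(VOXEL_LABELS)[match(nb_lab[sel], VOXEL_LABELS)]
      for (nm in names(wall_motion)) {
        hit <- nmv == nm
        if (any(hit)) {
          ut1[hit] <- ut1[hit] - wall_motion[[nm]][tang[1]]
          ut2[hit] <- ut2[hit] - wall_motion[[nm]][tang[2]]
        }
      }
    }
    tau <- fluid$viscosity * sqrt(ut1^2 + ut2^2) / (h / 2)
    out[[length(out) + 1L]] <- data.frame(
      i = ijk_s[, 1], j = ijk_s[, 2], k = ijk_s[, 3],
      axis = ax, side = dsgn,
      label = names(VOXEL_LABELS)[match(nb_lab[sel], VOXEL_LABELS)],
      area = h^2, tau = tau)
  }
  if (!length(out))
    stop("no wall or scaffold surface faces in this domain")
  do.call(rbind, out)
}

#' Summarize wall shear stress over a surface
#'
#' @param wss data frame from [wall_shear_stress()].
#' @param reference_area optional physical wetted area, m^2. The voxel
#'   staircase overestimates surface area, so for smooth surfaces the
#'   unbiased mean stress is the total tangential force divided by the true
#'   area; the raw face-average is reported alongside.
#' @return List with `mean_face` (Pa), `total_force` (N) and, when a
#'   reference area is given, `mean_drag = total_force / reference_area`.
#' @export
wss_summary <- function(wss, reference_area = NULL) {
  force <- sum(wss$tau * wss$area)
  out <- list(mean_face = sum(wss$tau * wss$area) / sum(wss$area),
              max = max(wss$tau), total_force = force)
  if (!is.null(reference_area)) out$mean_drag <- force / reference_area
  out
}

#' Solve fully developed unidirectional flow
#'
#' Steady laminar flow that is invariant along one axis (a long straight
#' duct far from its entrance, or plane Couette flow) reduces to a Poisson
#' problem for the streamwise velocity over the duct cross-section:
#' `-mu * lap(u_s) = G` with no-slip walls (optionally moving) and
#' free-slip on `interface`/`symmetry` labels. This is solved exactly
#' (sparse direct) on the voxelized cross-section taken at the mid-slice of
#' `domain` along `flow_axis`, and replicated into a full staggered
#' [solve_steady_flow()]-compatible solution.
#'
#' @param domain a [voxel_domain()] whose labels are invariant along
#'   `flow_axis` (inlet/outlet layers at the ends are ignored).
#' @param fluid a [fluid_props()].
#' @param flow_axis streamwise axis, 1-3 (default 3).
#' @param pressure_gradient driving force `G = -dp/ds`, Pa/m; ignored when
#'   `mean_velocity` is given.
#' @param mean_velocity target cross-section mean streamwise velocity, m/s;
#'   the linear solution is rescaled to it (only without wall motion).
#' @param wall_motion optional named list (label -> length-3 velocity) for
#'   moving no-slip boundaries.
#' @return A `flow_solution` whose `$profile` holds the cross-section
#'   velocity matrix and `$mean`, `$max` its statistics.
#' @export
solve_developed_flow <- function(domain, fluid = fluid_props(),
                                 flow_axis = 3L, pressure_gradient = 1,
                                 mean_velocity = NULL, wall_motion = NULL) {
  lab <- domain$labels
  h <- domain$spacing
  mu <- fluid$viscosity
  dmn <- dim(lab)
  cross <- setdiff(1:3, flow_axis)
  mid <- max(2L, dmn[flow_axis] %/% 2L)
  slice <- switch(flow_axis,
                  lab[mid, , ], lab[, mid, ], lab[, , mid])
  sdim <- dim(slice)
  FLUID <- VOXEL_LABELS[["fluid"]]
  fcells <- which(slice == FLUID)
  if (!length(fcells)) stop("cross-section has no fluid cells")
  row_of <- array(NA_integer_, sdim)
  row_of[fcells] <- seq_along(fcells)
  ij <- arrayInd(fcells, sdim)
  N <- length(fcells)
  ii <- integer(0); jj <- integer(0)
  dg <- numeric(N); rhs <- rep(pressure_gradient / mu * h^2, N)
  if (!is.null(mean_velocity)) rhs <- rep(1, N)  # unit forcing, rescaled
  uw_of <- function(code) {
    if (is.null(wall_motion)) return(0)
    nm <- names(VOXEL_LABELS)[match(code, VOXEL_LABELS)]
    if (!is.null(wall_motion[[nm]])) wall_motion[[nm]][flow_axis] else 0
  }
  for (ax in 1:2) for (dsgn in c(-1L, 1L)) {
    nb <- ij; nb[, ax] <- nb[, ax] + dsgn
    ok <- nb[, ax] >= 1L & nb[, ax] <= sdim[ax]
    code <- rep(0L, N)
    code[ok] <- slice[cbind(nb[ok, 1], nb[ok, 2])]
    is_fluid <- code == FLUID
    ii <- c(ii, which(is_fluid))
    jj <- c(jj, row_of[cbind(nb[is_fluid, 1], nb[is_fluid, 2])])
    dg <- dg + is_fluid
    free <- code %in% c(FREE_SLIP_LABELS, 0L)
    noslip <- !is_fluid & !free
    dg <- dg + 2 * noslip
    if (any(noslip) && !is.null(wall_motion)) {
      for (code_i in unique(code[noslip])) {
        uw <- uw_of(code_i)
        if (uw != 0) {
          sel <- noslip & code == code_i
          rhs[sel] <- rhs[sel] + 2 * uw
        }
      }
    }
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(N)), j = c(jj, seq_len(N)),
                            x = c(rep(-1, length(ii)), dg + 1e-12),
                            dims = c(N, N))
  us <- as.numeric(Matrix::solve(A, rhs))
  if (!is.null(mean_velocity)) {
    if (!is.null(wall_motion))
      stop("mean_velocity rescaling requires stationary walls")
    us <- us * mean_velocity / mean(us)
  }
  prof <- array(NA_real_, sdim)
  prof[fcells] <- us

  # replicate into staggered arrays
  fdims <- lapply(1:3, function(comp) {
    fd <- dmn; fd[comp] <- fd[comp] + 1L; fd
  })
  arrs <- lapply(fdims, function(fd) array(0, fd))
  full <- array(0, dmn)
  full[slice.index(full, flow_axis) > 0] <- 0
  sl <- prof; sl[is.na(sl)] <- 0
  for (pos in seq_len(dmn[flow_axis] + 1L)) {
    if (flow_axis == 1) arrs[[1]][pos, , ] <- sl
    else if (flow_axis == 2) arrs[[2]][, pos, ] <- sl
    else arrs[[3]][, , pos] <- sl
  }
  structure(list(u = arrs[[1]], v = arrs[[2]], w = arrs[[3]],
                 p = array(0, dmn),
                 iterations = 1L, converged = TRUE, residuals = numeric(0),
                 q_in = mean(us) * N * h^2, q_out = mean(us) * N * h^2,
                 mass_error = 0,
                 profile = prof, mean = mean(us), max = max(abs(us)),
                 fluid = fluid, spacing = h),
            class = "flow_solution")
}
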