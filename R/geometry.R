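# Scaffold generation (sphere-subtraction and strut-lattice variants) and
# chamber domain construction.

#' Scaffold specification
#'
#' @param dims block dimensions in metres, length-3 (default 10 x 10 x 3 mm).
#' @param pore_diameter pore (sphere/strut pitch) diameter, m (default 700 um).
#' @param pore_spacing center-to-center spacing, m (default 700 um).
#' @param target_porosity desired void fraction in `[0, 1)`.
#' @param variant `"sphere_subtraction"` (random cluster of spheres removed
#'   from a solid block, as fabricated) or `"strut_lattice"` (regular
#'   orthogonal struts, as simulated).
#' @param seed RNG seed for the random sphere cluster.
#' @param spacing voxel edge length, m; must not exceed `pore_diameter / 4`.
#' @return Object of class `scaffold_spec`.
#' @export
scaffold_spec <- function(dims = c(10e-3, 10e-3, 3e-3),
                          pore_diameter = 700e-6, pore_spacing = 700e-6,
                          target_porosity = 0.525,
                          variant = c("sphere_subtraction", "strut_lattice"),
                          seed = 1L, spacing = pore_diameter / 8) {
  variant <- match.arg(variant)
  if (any(dims <= 0)) stop("scaffold dims must be positive")
  if (target_porosity < 0 || target_porosity >= 1)
    stop("target_porosity must be in [0, 1)")
  if (spacing > pore_diameter / 4 + 1e-12)
    stop("voxel spacing must be <= pore_diameter / 4")
  structure(list(dims = dims, pore_diameter = pore_diameter,
                 pore_spacing = pore_spacing,
                 target_porosity = target_porosity, variant = variant,
                 seed = as.integer(seed), spacing = spacing),
            class = "scaffold_spec")
}

block_grid <- function(spec) {
  n <- pmax(1L, as.integer(round(spec$dims / spec$spacing)))
  centers <- lapply(1:3, function(a) (seq_len(n[a]) - 0.5) * spec$spacing)
  list(n = n, centers = centers)
}

#' Generate a sphere-subtraction scaffold block
#'
#' Voxelizes a solid block and subtracts a random cluster of spheres
#' (uniformly placed centres, diameter = pore size). The sphere count is
#' tuned by bisection so the measured void fraction lands within
#' `tol` of `target_porosity`; because the cluster for `N` spheres is the
#' prefix of a fixed seeded sequence, porosity is monotone in `N` and the
#' tuning is exact up to the one-sphere granularity.
#'
#' @param spec a [scaffold_spec()] with `variant = "sphere_subtraction"`.
#' @param tol acceptable |porosity - target|, default 0.005 (0.5 pp).
#' @param max_iter bisection iteration cap.
#' @return A [voxel_domain()] block of `fluid`/`scaffold` labels with
#'   attributes `porosity` and `n_spheres` in `$meta`.
#' @export
generate_sphere_subtracted_scaffold <- function(spec, tol = 0.005,
                                                max_iter = 40L) {
  if (spec$variant != "sphere_subtraction")
    stop("spec variant must be sphere_subtraction")
  g <- block_grid(spec)
  r <- spec$pore_diameter / 2
  vol_block <- prod(spec$dims)
  vol_sphere <- 4 / 3 * pi * r^3
  target <- spec$target_porosity

  if (target == 0) {
    lab <- array(VOXEL_LABELS[["scaffold"]], g$n)
    # keep at least the domain constructor happy: porosity-0 block is all solid
    dom <- structure(
      list(labels = lab, shape = g$n, spacing = spec$spacing,
           origin = c(0, 0, 0),
           meta = list(porosity = 0, n_spheres = 0L, spec = spec)),
      class = "voxel_domain")
    return(dom)
  }

  # Boolean-model estimate of the needed sphere count, with generous headroom
  n_est <- -log(1 - target) * vol_block / vol_sphere
  n_max <- max(16L, ceiling(3 * n_est))

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  cx <- stats::runif(n_max) * spec$dims[1]
  cy <- stats::runif(n_max) * spec$dims[2]
  cz <- stats::runif(n_max) * spec$dims[3]

  # first_hit[v]: smallest sphere index that covers voxel v (Inf if none);
  # porosity of the N-sphere prefix is then mean(first_hit <= N)
  first_hit <- array(Inf, g$n)
  xc <- g$centers[[1]]; yc <- g$centers[[2]]; zc <- g$centers[[3]]
  r2 <- r^2
  for (s in seq_len(n_max)) {
    ix <- which(abs(xc - cx[s]) <= r)
    iy <- which(abs(yc - cy[s]) <= r)
    iz <- which(abs(zc - cz[s]) <= r)
    if (!length(ix) || !length(iy) || !length(iz)) next
    d2 <- outer(outer((xc[ix] - cx[s])^2, (yc[iy] - cy[s])^2, "+"),
                (zc[iz] - cz[s])^2, "+")
    sub <- first_hit[ix, iy, iz]
    hit <- d2 <= r2 & sub > s
    if (any(hit)) {
      sub[hit] <- s
      first_hit[ix, iy, iz] <- sub
    }
  }

  porosity_of <- function(N) mean(first_hit <= N)
  if (porosity_of(n_max) < target - tol)
    stop(sprintf(
      "target porosity %.3f unreachable: %.3f achieved with %d spheres",
      target, porosity_of(n_max), n_max))

  lo <- 0L; hi <- n_max
  for (it in seq_len(max_iter)) {
    if (hi - lo <= 1L) break
    mid <- (lo + hi) %/% 2L
    if (porosity_of(mid) < target) lo <- mid else hi <- mid
  }
  n_sph <- if (abs(porosity_of(lo) - target) <= abs(porosity_of(hi) - target))
    lo else hi
  por <- porosity_of(n_sph)
  if (abs(por - target) > tol)
    stop(sprintf(
      "porosity tuning did not converge: achieved %.4f for target %.4f",
      por, target))

  lab <- array(VOXEL_LABELS[["scaffold"]], g$n)
  lab[first_hit <= n_sph] <- VOXEL_LABELS[["fluid"]]
  voxel_domain(lab, spec$spacing,
               meta = list(porosity = por, n_spheres = n_sph, spec = spec))
}

# Integer strut-column mask along one axis: m struts at pitch `s`, total
# solid column count K distributed as evenly as possible (widths k or k+1).
strut_column_mask <- function(centers_idx, n, K, m) {
  mask <- logical(n)
  if (K <= 0) return(mask)
  base_w <- K %/% m
  extra <- K %% m
  widths <- rep(base_w, m)
  if (extra > 0) widths[round(seq(1, m, length.out = extra))] <-
      widths[round(seq(1, m, length.out = extra))] + 1L
  for (j in seq_len(m)) {
    w <- widths[j]
    if (w <= 0) next
    ctr <- centers_idx[j]
    lo <- ctr - (w - 1) / 2
    cols <- round(seq(lo, lo + w - 1))
    cols <- cols[cols >= 1 & cols <= n]
    mask[cols] <- TRUE
  }
  mask
}

#' Generate a regular strut-lattice scaffold block
#'
#' Deterministic lattice of orthogonal struts (extruded along z): a voxel is
#' solid when its (x, y) column intersects an x-direction or y-direction
#' strut. For strut width `w` and pitch `s` the solid fraction is
#' `2(w/s) - (w/s)^2`, so the width solving the target porosity is
#' `w/s = 1 - sqrt(porosity)`. Integer voxel widths are dithered across
#' struts, and the per-direction solid column counts are chosen so the
#' measured porosity `px * py` lands within `tol` of the target.
#'
#' @param spec a [scaffold_spec()] with `variant = "strut_lattice"`.
#' @param tol acceptable |porosity - target|, default 0.005.
#' @param strut_width optional explicit strut width (m) overriding the
#'   porosity tuning; `0` yields an empty (all-fluid) block. Must be below
#'   the pitch.
#' @return A [voxel_domain()] block with `porosity` in `$meta`.
#' @export
generate_strut_scaffold <- function(spec, tol = 0.005, strut_width = NULL) {
  if (spec$variant != "strut_lattice")
    stop("spec variant must be strut_lattice")
  g <- block_grid(spec)
  s <- spec$pore_spacing
  h <- spec$spacing
  n <- g$n
  m <- max(1L, floor(spec$dims[1] / s))
  # strut centres (as fractional voxel indices), lattice centred in the block
  offset <- (spec$dims[1] - (m - 1) * s) / 2
  centers_idx <- (offset + (seq_len(m) - 1) * s) / h + 0.5

  if (!is.null(strut_width)) {
    if (strut_width >= s) stop("strut width must be below the pitch")
    K <- round(m * strut_width / h)
    sx <- strut_column_mask(centers_idx, n[1], K, m)
    sy <- strut_column_mask(centers_idx, n[2], K, m)
  } else {
    target <- spec$target_porosity
    w_over_s <- 1 - sqrt(target)
    if (w_over_s >= 1) stop("strut width would exceed the pitch")
    # columns available per direction limited by pitch: K <= m * (s/h)
    k_cap <- min(n[1], floor(m * s / h))
    px_of <- function(K) 1 - sum(strut_column_mask(centers_idx, n[1], K, m)) / n[1]
    Kx <- round(n[1] * (1 - sqrt(target)))
    px <- px_of(Kx)
    # pick Ky (and small Kx perturbations) minimizing |px*py - target|
    best <- NULL
    for (dKx in -2:2) {
      Kxi <- min(max(Kx + dKx, 0L), k_cap)
      pxi <- px_of(Kxi)
      if (pxi <= 0) next
      Ky0 <- round(n[2] * (1 - target / pxi))
      for (dKy in -2:2) {
        Kyi <- min(max(Ky0 + dKy, 0L), k_cap)
        pyi <- 1 - sum(strut_column_mask(centers_idx, n[2], Kyi, m)) / n[2]
        err <- abs(pxi * pyi - target)
        if (is.null(best) || err < best$err)
          best <- list(Kx = Kxi, Ky = Kyi, err = err)
      }
    }
    if (best$err > tol)
      stop(sprintf(
        "strut porosity tuning missed target %.3f by %.4f at this resolution",
        target, best$err))
    sx <- strut_column_mask(centers_idx, n[1], best$Kx, m)
    sy <- strut_column_mask(centers_idx, n[2], best$Ky, m)
  }

  solid_xy <- outer(sx, sy, "|")
  lab <- array(ifelse(rep(solid_xy, n[3]), VOXEL_LABELS[["scaffold"]],
                      VOXEL_LABELS[["fluid"]]), dim = n)
  por <- measure_porosity(lab)
  if (is.null(strut_width) && abs(por - spec$target_porosity) > tol)
    stop("strut scaffold porosity off target after voxelization")
  if (!any(lab == VOXEL_LABELS[["fluid"]]))
    stop("strut scaffold has no void space")
  voxel_domain(lab, h, meta = list(porosity = por, spec = spec))
}

#' Generate a scaffold block from its specification
#' @param spec a [scaffold_spec()]; dispatches on `spec$variant`.
#' @param ... passed to the variant generator.
#' @return A [voxel_domain()] block.
#' @export
generate_scaffold <- function(spec, ...) {
  switch(spec$variant,
         sphere_subtraction = generate_sphere_subtracted_scaffold(spec, ...),
         strut_lattice = generate_strut_scaffold(spec, ...))
}

# --- chamber construction ---------------------------------------------------

# default placement of scaffolds: one ring, vertical plates tangential to the
# ring (long axes tangential + vertical, 3 mm thickness radial)
default_placement <- function(chamber, scaffold_dims,
                              ring_radius = 0.025, stand_height = 0.004) {
  n <- chamber$n_scaffolds
  if (n == 0L) return(list())
  angles <- (seq_len(n) - 0.5) * 2 * pi / n
  lapply(angles, function(a) {
    list(center = c(ring_radius * cos(a), ring_radius * sin(a),
                    stand_height + scaffold_dims[2] / 2),
         angle = a, dims = scaffold_dims)
  })
}

# world point(s) -> scaffold-local coordinates. Local frame: x1 tangential
# (block x, 10 mm), x2 vertical (block y, 10 mm), x3 radial (block z, 3 mm).
world_to_scaffold <- function(px, py, pz, box) {
  dx <- px - box$center[1]; dy <- py - box$center[2]; dz <- pz - box$center[3]
  ca <- cos(box$angle); sa <- sin(box$angle)
  radial <- dx * ca + dy * sa
  tangential <- -dx * sa + dy * ca
  cbind(tangential, dz, radial)
}

#' Test points against a scaffold placement box
#'
#' @param px,py,pz point coordinates, m (vectorized).
#' @param box a placement box (`center`, `angle`, `dims`) as stored in a
#'   chamber domain's `meta$scaffold_boxes`.
#' @param shrink margin subtracted from the box half-dimensions, m
#'   (negative values grow the box).
#' @return Logical vector.
#' @export
in_scaffold_box <- function(px, py, pz, box, shrink = 0) {
  loc <- world_to_scaffold(px, py, pz, box)
  half <- box$dims / 2 - shrink
  abs(loc[, 1]) <= half[1] & abs(loc[, 2]) <= half[2] & abs(loc[, 3]) <= half[3]
}

# sample a scaffold block's labels at world points inside its box
sample_block_label <- function(px, py, pz, box, block) {
  loc <- world_to_scaffold(px, py, pz, box)
  h <- block$spacing
  n <- block$shape
  idx <- cbind(ceiling((loc[, 1] + box$dims[1] / 2) / h),
               ceiling((loc[, 2] + box$dims[2] / 2) / h),
               ceiling((loc[, 3] + box$dims[3] / 2) / h))
  idx[, 1] <- pmin(pmax(idx[, 1], 1L), n[1])
  idx[, 2] <- pmin(pmax(idx[, 2], 1L), n[2])
  idx[, 3] <- pmin(pmax(idx[, 3], 1L), n[3])
  block$labels[vox_index(n, idx[, 1], idx[, 2], idx[, 3])]
}

#' Build a voxelized chamber domain
#'
#' Constructs the (quarter or full) cylindrical chamber: no-slip walls on the
#' shell and base, a flat air-liquid interface at the fill height, vertical
#' inlet/outlet port voxels in the base, and scaffolds embedded at ring
#' positions on the stand plane. Scaffold blocks are resampled at chamber
#' cell centres (nearest fine voxel), so sub-resolution pore structure
#' degrades gracefully to the envelope occupancy pattern.
#'
#' @param chamber a [chamber_spec()].
#' @param scaffold_blocks list of scaffold [voxel_domain()] blocks (recycled
#'   across positions), or `NULL` for an empty chamber.
#' @param resolution chamber voxel edge, m (default 2 mm).
#' @param placement list of placement boxes (`center`, `angle`, `dims`), or
#'   `NULL` for the default one-ring stand layout.
#' @param inlet_angle angular position (rad) of the inlet port on the base
#'   periphery; the outlet sits at the base centre.
#' @param inlet_radius radial position (m) of the inlet port centre.
#' @param volume_tol acceptable relative error of the voxelized fluid volume
#'   against the nominal fill volume.
#' @return A [voxel_domain()]; `$meta` records quarter symmetry, fluid
#'   volume, scaffold boxes and resolved scaffold surface area.
#' @export
build_chamber_domain <- function(chamber, scaffold_blocks = NULL,
                                 resolution = 2e-3, placement = NULL,
                                 inlet_angle = pi / 4, inlet_radius = 0.036,
                                 volume_tol = 0.03) {
  R <- chamber$diameter / 2
  h <- resolution
  quarter <- isTRUE(chamber$quarter)
  nz <- max(2L, as.integer(round(chamber$fill_height / h)))
  nr <- as.integer(round(R / h))

  if (quarter) {
    nx <- ny <- nr + 2L   # +1 symmetry layer (low side), +1 wall layer (high)
    x0 <- y0 <- -h        # first layer spans [-h, 0): symmetry plane at 0
  } else {
    nx <- ny <- 2L * nr + 2L
    x0 <- y0 <- -R - h
  }
  nzz <- nz + 2L          # +1 base wall layer, +1 interface layer
  z0 <- -h
  shape <- c(nx, ny, nzz)
  xc <- x0 + (seq_len(nx) - 0.5) * h
  yc <- y0 + (seq_len(ny) - 0.5) * h
  zc <- z0 + (seq_len(nzz) - 0.5) * h

  lab <- array(VOXEL_LABELS[["wall"]], shape)
  cx <- array(rep(xc, times = ny * nzz), shape)
  cy <- array(rep(rep(yc, each = nx), times = nzz), shape)
  cz <- array(rep(zc, each = nx * ny), shape)
  rad <- sqrt(cx^2 + cy^2)

  inside <- rad <= R
  fluid_k <- cz > 0 & cz < nz * h
  lab[inside & fluid_k] <- VOXEL_LABELS[["fluid"]]
  lab[inside & cz > nz * h] <- VOXEL_LABELS[["interface"]]
  if (quarter) {
    # one-voxel symmetry layers on the x = 0 and y = 0 planes, next to fluid
    i0 <- which(xc < 0)
    lay <- array(VOXEL_LABELS[["wall"]], c(length(i0), ny, nzz))
    lay[lab[i0 + 1L, , , drop = FALSE] == VOXEL_LABELS[["fluid"]]] <-
      VOXEL_LABELS[["symmetry"]]
    lab[i0, , ] <- lay
    j0 <- which(yc < 0)
    lay <- array(VOXEL_LABELS[["wall"]], c(nx, length(j0), nzz))
    lay[lab[, j0 + 1L, , drop = FALSE] == VOXEL_LABELS[["fluid"]]] <-
      VOXEL_LABELS[["symmetry"]]
    lab[, j0, ] <- lay
  }

  # ports: vertical circular ports in the base layer (k = 1), snapped to at
  # least one voxel each
  base_k <- 1L
  port_r <- chamber$port_diameter / 2
  mark_port <- function(lab, px, py, code) {
    best_i <- which.min(abs(xc - px)); best_j <- which.min(abs(yc - py))
    ii <- which(abs(xc - px) <= max(port_r, h / 2 + 1e-12))
    jj <- which(abs(yc - py) <= max(port_r, h / 2 + 1e-12))
    marked <- FALSE
    for (i in ii) for (j in jj) {
      if ((xc[i] - px)^2 + (yc[j] - py)^2 <= max(port_r, h / 2)^2 &&
          lab[i, j, base_k + 1L] == VOXEL_LABELS[["fluid"]]) {
        lab[i, j, base_k] <- code; marked <- TRUE
      }
    }
    if (!marked) {
      if (lab[best_i, best_j, base_k + 1L] != VOXEL_LABELS[["fluid"]])
        stop("port position is not under fluid")
      lab[best_i, best_j, base_k] <- code
    }
    lab
  }
  in_x <- inlet_radius * cos(inlet_angle)
  in_y <- inlet_radius * sin(inlet_angle)
  if (inlet_radius + port_r > R) stop("inlet port outside chamber")
  lab <- mark_port(lab, in_x, in_y, VOXEL_LABELS[["inlet"]])
  out_xy <- if (quarter) c(h / 2, h / 2) else c(0, 0)
  lab <- mark_port(lab, out_xy[1], out_xy[2], VOXEL_LABELS[["outlet"]])

  # scaffolds
  boxes <- list()
  if (!is.null(scaffold_blocks) && chamber$n_scaffolds > 0L) {
    if (!is.list(scaffold_blocks) || inherits(scaffold_blocks, "voxel_domain"))
      scaffold_blocks <- list(scaffold_blocks)
    dims0 <- scaffold_blocks[[1]]$shape * scaffold_blocks[[1]]$spacing
    if (is.null(placement))
      placement <- default_placement(chamber, dims0)
    keep <- if (quarter)
      vapply(placement, function(b) {
        a <- b$angle %% (2 * pi); a >= 0 && a <= pi / 2
      }, logical(1))
    else rep(TRUE, length(placement))
    placement <- placement[keep]
    fl <- which(lab == VOXEL_LABELS[["fluid"]])
    pxv <- cx[fl]; pyv <- cy[fl]; pzv <- cz[fl]
    for (b_i in seq_along(placement)) {
      box <- placement[[b_i]]
      blk <- scaffold_blocks[[((b_i - 1L) %% length(scaffold_blocks)) + 1L]]
      half_diag <- sqrt(sum((box$dims / 2)^2))
      rmax <- sqrt(sum(box$center[1:2]^2)) +
        sqrt(sum((box$dims[c(1, 3)] / 2)^2))
      if (rmax > R || box$center[3] + box$dims[2] / 2 > nz * h ||
          box$center[3] - box$dims[2] / 2 < 0)
        stop("scaffold placement protrudes beyond the chamber fluid region")
      inbox <- in_scaffold_box(pxv, pyv, pzv, box)
      if (any(inbox)) {
        labs <- sample_block_label(pxv[inbox], pyv[inbox], pzv[inbox],
                                   box, blk)
        tgt <- fl[inbox][labs == VOXEL_LABELS[["scaffold"]]]
        lab[tgt] <- VOXEL_LABELS[["scaffold"]]
      }
      boxes[[length(boxes) + 1L]] <- box
    }
    # overlapping scaffolds check
    if (length(boxes) > 1L) {
      for (a in seq_along(boxes)) for (b in seq_along(boxes)) {
        if (a < b) {
          d <- sqrt(sum((boxes[[a]]$center - boxes[[b]]$center)^2))
          if (d < max(boxes[[a]]$dims) / 2) stop("overlapping scaffolds")
        }
      }
    }
  }

  nominal <- if (quarter) chamber$fill_volume / 4 else chamber$fill_volume
  n_fluid <- sum(lab == VOXEL_LABELS[["fluid"]])
  n_occupied <- n_fluid + sum(lab == VOXEL_LABELS[["scaffold"]])
  vol <- n_occupied * h^3   # scaffold displacement is part of the fill
  if (abs(vol - nominal) / nominal > volume_tol)
    warning(sprintf("voxelized fill volume %.3g m^3 deviates %.1f%% from nominal",
                    vol, 100 * abs(vol - nominal) / nominal))

  # resolved scaffold surface area (fluid faces adjacent to scaffold voxels)
  area_resolved <- count_scaffold_faces(lab) * h^2

  voxel_domain(lab, h, origin = c(x0, y0, z0),
               meta = list(quarter = quarter, chamber = chamber,
                           fluid_volume = n_fluid * h^3,
                           occupied_volume = vol,
                           nominal_volume = nominal,
                           scaffold_boxes = boxes,
                           scaffold_area_resolved = area_resolved))
}

count_scaffold_faces <- function(lab) {
  f <- lab == VOXEL_LABELS[["fluid"]]
  s <- lab == VOXEL_LABELS[["scaffold"]]
  d <- dim(lab)
  cnt <- 0L
  cnt <- cnt + sum(f[-d[1], , ] & s[-1, , ]) + sum(s[-d[1], , ] & f[-1, , ])
  cnt <- cnt + sum(f[, -d[2], ] & s[, -1, ]) + sum(s[, -d[2], ] & f[, -1, ])
  cnt <- cnt + sum(f[, , -d[3]] & s[, , -1]) + sum(s[, , -d[3]] & f[, , -1])
  cnt
}
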