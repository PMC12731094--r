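# Region summaries of oxygen fields and plane extraction.

#' Summarize an oxygen field over named regions
#'
#' Volume-weighted statistics over the fluid, plus the regions the chamber
#' results are reported on: the fluid shell within two voxel layers of the
#' air-liquid interface, the shell within two layers of chamber walls, and
#' the fluid cells face-adjacent to scaffold solid (split into external
#' faces, outside the scaffold envelope boxes, and internal pore faces).
#' Empty regions are reported as `NA`, not zero.
#'
#' @param field a `transport_solution` or a concentration array (mol m^-3)
#'   matching the domain shape.
#' @param domain the [voxel_domain()] the field lives on.
#' @param shell_width region shell width in voxel layers (default 2).
#' @return Object of class `summary_stats`; concentrations in uM
#'   (1 mol m^-3 = 1000 uM).
#' @export
summarize_field <- function(field, domain, shell_width = 2L) {
  carr <- if (inherits(field, "transport_solution")) field$c else field
  if (!all(dim(carr) == domain$shape))
    stop("field shape does not match the domain")
  lab <- domain$labels
  fl <- lab == VOXEL_LABELS[["fluid"]]
  cf <- carr[fl]
  if (any(!is.finite(cf))) stop("field undefined on some fluid cells")
  uM <- 1e3

  reg_mean <- function(mask) {
    m <- mask & fl
    if (!any(m)) return(NA_real_)
    mean(carr[m]) * uM
  }
  reg_min <- function(mask) {
    m <- mask & fl
    if (!any(m)) return(NA_real_)
    min(carr[m]) * uM
  }

  iface <- fluid_near_label(domain, VOXEL_LABELS[["interface"]],
                            shell_width)
  nwall <- fluid_near_label(domain, VOXEL_LABELS[["wall"]], shell_width)
  scad <- fluid_adjacent_to(domain, VOXEL_LABELS[["scaffold"]])

  scaffold_external <- scaffold_internal <- NA_real_
  boxes <- domain$meta$scaffold_boxes
  if (any(scad) && length(boxes)) {
    idx <- which(scad)
    ijk <- arrayInd(idx, domain$shape)
    px <- domain$origin[1] + (ijk[, 1] - 0.5) * domain$spacing
    py <- domain$origin[2] + (ijk[, 2] - 0.5) * domain$spacing
    pz <- domain$origin[3] + (ijk[, 3] - 0.5) * domain$spacing
    inside <- rep(FALSE, length(idx))
    for (b in boxes)
      inside <- inside | in_scaffold_box(px, py, pz, b)
    if (any(!inside)) scaffold_external <- mean(carr[idx[!inside]]) * uM
    if (any(inside)) scaffold_internal <- mean(carr[idx[inside]]) * uM
  }

  # mean concentration per horizontal layer (profile along z)
  ksum <- apply(ifelse(fl, carr, 0), 3, sum)
  kcnt <- apply(fl, 3, sum)
  prof_z <- data.frame(z = cell_centers(domain, 3),
                       mean_uM = ifelse(kcnt > 0, ksum / kcnt * uM, NA))

  structure(list(
    mean = mean(cf) * uM, min = min(cf) * uM, max = max(cf) * uM,
    n_fluid = sum(fl),
    interface_mean = reg_mean(iface),
    near_wall_min = reg_min(nwall),
    near_wall_mean = reg_mean(nwall),
    scaffold_surface_mean = reg_mean(scad),
    scaffold_surface_external_mean = scaffold_external,
    scaffold_surface_internal_mean = scaffold_internal,
    profile_z = prof_z[kcnt > 0, ],
    shell_width = shell_width),
    class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("<summary_stats> (uM)\n")
  cat(sprintf("  fluid mean %.1f  [%.1f, %.1f]  (n = %d cells)\n",
              x$mean, x$min, x$max, x$n_fluid))
  if (!is.na(x$interface_mean))
    cat(sprintf("  interface region mean   %.1f\n", x$interface_mean))
  if (!is.na(x$near_wall_min))
    cat(sprintf("  near-wall min / mean    %.1f / %.1f\n",
                x$near_wall_min, x$near_wall_mean))
  if (!is.na(x$scaffold_surface_mean))
    cat(sprintf("  scaffold surface mean   %.1f (external %.1f, internal %.1f)\n",
                x$scaffold_surface_mean, x$scaffold_surface_external_mean,
                x$scaffold_surface_internal_mean))
  invisible(x)
}

#' Extract a coordinate plane from a field
#'
#' Cell-centred values on the plane `axis = coord`, e.g. a ZX-slice at a
#' given y. Non-fluid cells are `NA`.
#'
#' @param field array (or `transport_solution`) on `domain`.
#' @param domain the [voxel_domain()].
#' @param axis plane normal: 1 (x), 2 (y) or 3 (z).
#' @param coord position along `axis` in metres (snapped to the nearest
#'   cell layer); must intersect the domain.
#' @return List with the 2-D `values` matrix and the two in-plane
#'   coordinate vectors `coords`.
#' @export
slice_extract <- function(field, domain, axis, coord) {
  carr <- if (inherits(field, "transport_solution")) field$c else field
  cc <- cell_centers(domain, axis)
  h <- domain$spacing
  if (coord < cc[1] - h / 2 || coord > cc[length(cc)] + h / 2)
    stop("plane lies outside the domain")
  k <- which.min(abs(cc - coord))
  vals <- switch(axis, carr[k, , ], carr[, k, ], carr[, , k])
  other <- setdiff(1:3, axis)
  list(values = vals,
       coords = list(cell_centers(domain, other[1]),
                     cell_centers(domain, other[2])),
       axis = axis, coord = cc[k])
}

#' Plot a horizontal mid-plane of a scenario result
#'
#' Base-graphics image of the oxygen concentration (uM) on a z-plane.
#'
#' @param x a `scenario_result`.
#' @param z plane height, m (default mid fill height).
#' @param ... passed to [graphics::image()].
#' @export
plot.scenario_result <- function(x, z = NULL, ...) {
  dom <- x$domain
  if (is.null(z)) z <- mean(range(cell_centers(dom, 3)))
  sl <- slice_extract(x$transport, dom, 3, z)
  graphics::image(sl$coords[[1]] * 1e3, sl$coords[[2]] * 1e3,
                  sl$values * 1e3,
                  xlab = "x [mm]", ylab = "y [mm]",
                  main = sprintf("%s: O2 [uM] at z = %.1f mm",
                                 x$config$name, sl$coord * 1e3), ...)
  invisible(x)
}
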