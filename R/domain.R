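# Voxel domain: labeled structured grid shared by the geometry, flow and
# transport stages.

#' Voxel label codes
#'
#' Integer codes used in the `labels` array of a [voxel_domain()]. Each voxel
#' carries exactly one label. `fluid` voxels hold the unknowns; all other
#' labels are boundary material: `wall` (no-slip, impermeable), `scaffold`
#' (no-slip solid that may carry a surface reaction), `interface` (flat
#' air-liquid surface, free-slip with a Dirichlet oxygen condition), `inlet` /
#' `outlet` (port voxels in the base through which medium enters/leaves) and
#' `symmetry` (free-slip, zero-flux planes bounding a quarter domain).
#'
#' @format Named integer vector.
#' @export
VOXEL_LABELS <- c(
  fluid = 1L, wall = 2L, scaffold = 3L, interface = 4L,
  inlet = 5L, outlet = 6L, symmetry = 7L
)

#' Construct a voxel domain
#'
#' @param labels 3-D integer array of [VOXEL_LABELS] codes (one per voxel).
#' @param spacing isotropic voxel edge length in metres.
#' @param origin coordinates (m) of the corner of voxel `[1,1,1]`; cell
#'   centres sit at `origin + (index - 1/2) * spacing`.
#' @param meta optional list of extra metadata (e.g. scaffold placement boxes,
#'   quarter-symmetry flag, nominal fill volume).
#' @return An object of class `voxel_domain`.
#' @export
voxel_domain <- function(labels, spacing, origin = c(0, 0, 0), meta = list()) {
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("`spacing` must be a single positive length in metres")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), unname(VOXEL_LABELS))
  if (length(bad))
    stop("unknown label codes: ", paste(bad, collapse = ", "))
  if (!any(labels == VOXEL_LABELS[["fluid"]]))
    stop("domain has no fluid voxels")
  structure(
    list(labels = labels, shape = dim(labels), spacing = spacing,
         origin = as.numeric(origin), meta = meta),
    class = "voxel_domain")
}

#' @export
print.voxel_domain <- function(x, ...) {
  cat("<voxel_domain> ", paste(x$shape, collapse = " x "),
      sprintf(" voxels @ %.4g mm", x$spacing * 1e3), "\n", sep = "")
  tab <- table(factor(as.vector(x$labels), levels = VOXEL_LABELS,
                      labels = names(VOXEL_LABELS)))
  tab <- tab[tab > 0]
  for (nm in names(tab))
    cat(sprintf("  %-10s %d\n", nm, tab[[nm]]))
  if (isTRUE(x$meta$quarter)) cat("  quarter-symmetry domain\n")
  invisible(x)
}

#' Cell-centre coordinates along one axis
#' @param domain a [voxel_domain()].
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of cell-centre coordinates in metres.
#' @export
cell_centers <- function(domain, axis) {
  n <- domain$shape[axis]
  domain$origin[axis] + (seq_len(n) - 0.5) * domain$spacing
}

# linear index into the label array for integer voxel indices (vectorized)
vox_index <- function(shape, i, j, k) {
  i + shape[1] * (j - 1L) + shape[1] * shape[2] * (k - 1L)
}

#' Measure porosity of a scaffold block
#'
#' Void fraction of a voxelized block: fluid voxels over total voxels within
#' the block envelope. For blocks produced by the scaffold generators the
#' envelope is the whole array.
#'
#' @param block a [voxel_domain()] whose voxels are `fluid` or `scaffold`.
#' @return Fraction in `[0, 1]`.
#' @export
measure_porosity <- function(block) {
  lab <- if (inherits(block, "voxel_domain")) block$labels else block
  n <- length(lab)
  if (n == 0L) stop("empty block")
  sum(lab == VOXEL_LABELS[["fluid"]]) / n
}

#' Fluid cells near a boundary label
#'
#' Logical mask of fluid cells within `dist` voxel layers (6-connectivity
#' dilation) of any voxel carrying `label_code`; used to define the
#' reporting regions (interface shell, near-wall shell, scaffold surface).
#'
#' @param domain a [voxel_domain()].
#' @param label_code one of [VOXEL_LABELS].
#' @param dist shell width in voxel layers.
#' @return Logical array of the domain shape.
#' @export
fluid_near_label <- function(domain, label_code, dist = 2L) {
  lab <- domain$labels
  mask <- lab == label_code
  if (!any(mask)) return(array(FALSE, dim(lab)))
  for (step in seq_len(dist)) {
    grown <- mask
    d <- dim(mask)
    grown[-1, , ] <- grown[-1, , ] | mask[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | mask[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | mask[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | mask[, -1, ]
    grown[, , -1] <- grown[, , -1] | mask[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | mask[, , -1]
    mask <- grown
  }
  mask & (lab == VOXEL_LABELS[["fluid"]])
}

# fluid cells face-adjacent to a given label (distance 1 shell)
fluid_adjacent_to <- function(domain, label_code) {
  fluid_near_label(domain, label_code, dist = 1L)
}
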