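# Reaction-parameter derivation from cell loadings, and the consumption
# rate law itself.

#' Cell loading of a bioreactor run
#'
#' @param mode `"bulk"` (cells suspended/distributed through the vessel,
#'   volumetric sink) or `"per_scaffold"` (adherent cells, surface sink).
#' @param n_cells total cells (bulk mode) or cells per scaffold.
#' @param n_scaffolds number of scaffolds (per-scaffold mode).
#' @param vessel_volume medium volume, m^3 (bulk mode).
#' @param area_per_scaffold nominal scaffold surface area, m^2. The stated
#'   design area (0.01 m^2 per scaffold, including internal pore surface) is
#'   used for the Vmax derivation; the voxel model's resolved area is
#'   resolution-dependent and is reported separately by the domain builder.
#' @return Object of class `cell_loading`.
#' @export
cell_loading <- function(mode = c("bulk", "per_scaffold"), n_cells,
                         n_scaffolds = 12L, vessel_volume = 110e-6,
                         area_per_scaffold = 0.01) {
  mode <- match.arg(mode)
  if (n_cells < 0) stop("cell count must be >= 0")
  if (mode == "bulk" && vessel_volume <= 0) stop("vessel volume must be positive")
  if (mode == "per_scaffold" && (area_per_scaffold <= 0 || n_scaffolds < 1))
    stop("per-scaffold loading needs positive area and >= 1 scaffold")
  structure(list(mode = mode, n_cells = n_cells,
                 n_scaffolds = as.integer(n_scaffolds),
                 vessel_volume = vessel_volume,
                 area_per_scaffold = area_per_scaffold),
            class = "cell_loading")
}

# nmol/min per 1e6 cells -> mol/s per cell
per_cell_rate_si <- function(rate_nmol_min_per_1e6) {
  rate_nmol_min_per_1e6 * 1e-9 / 60 / 1e6
}

#' Volumetric maximal consumption rate
#'
#' Cell-normalized uptake rate times the number of cells in the vessel,
#' divided by the medium volume.
#'
#' @param loading a [cell_loading()] with `mode = "bulk"`.
#' @param params an [oxygen_params()].
#' @return Vmax in mol m^-3 s^-1.
#' @export
volumetric_vmax <- function(loading, params = oxygen_params()) {
  if (loading$mode != "bulk") stop("volumetric_vmax needs a bulk loading")
  per_cell_rate_si(params$per_cell_rate) * loading$n_cells /
    loading$vessel_volume
}

#' Areal maximal consumption rate
#'
#' Total uptake of all scaffold-adherent cells (scaffold count times cells
#' per scaffold) divided by the total scaffold surface area; the scaffold
#' count cancels algebraically but the formula is kept in this form to match
#' its derivation from the experimental loadings.
#'
#' @param loading a [cell_loading()] with `mode = "per_scaffold"`.
#' @param params an [oxygen_params()].
#' @return Vmax in mol m^-2 s^-1.
#' @export
areal_vmax <- function(loading, params = oxygen_params()) {
  if (loading$mode != "per_scaffold")
    stop("areal_vmax needs a per-scaffold loading")
  total_rate <- per_cell_rate_si(params$per_cell_rate) *
    loading$n_scaffolds * loading$n_cells
  total_area <- loading$n_scaffolds * loading$area_per_scaffold
  total_rate / total_area
}

#' Michaelis-Menten consumption rate
#'
#' `R = vmax * c / (c + km_c)`. With `km_c = 0` the law degenerates to a
#' zeroth-order sink (`R = vmax` wherever `c > 0`), which is the limit the
#' analytic slab fixture uses.
#'
#' @param c concentration, mol m^-3 (>= 0; vectorized).
#' @param vmax maximal rate (volumetric mol m^-3 s^-1 or areal
#'   mol m^-2 s^-1; the result carries the same units).
#' @param km_c half-saturation concentration, mol m^-3 (>= 0).
#' @return Consumption rate, same units as `vmax`.
#' @export
mm_rate <- function(c, vmax, km_c) {
  if (any(c < 0)) stop("negative concentration in mm_rate")
  if (vmax < 0 || km_c < 0) stop("vmax and km_c must be >= 0")
  if (km_c == 0) return(ifelse(c > 0, vmax, 0))
  vmax * c / (c + km_c)
}

#' Reaction specification
#'
#' A Michaelis-Menten oxygen sink, applied either volumetrically over fluid
#' cells or as a flux on fluid faces adjacent to scaffold solid.
#'
#' @param mode `"volumetric"` or `"surface"`.
#' @param vmax maximal rate (mol m^-3 s^-1 volumetric, mol m^-2 s^-1 surface).
#' @param km_c half-saturation concentration, mol m^-3 (> 0, or 0 for the
#'   zeroth-order limit).
#' @param provenance optional list recording the cell counts/areas the rate
#'   was derived from.
#' @param region optional logical array (domain shape) restricting a
#'   volumetric sink to part of the fluid; `NULL` applies it everywhere.
#' @return Object of class `reaction_spec`.
#' @export
reaction_spec <- function(mode = c("volumetric", "surface"), vmax, km_c,
                          provenance = NULL, region = NULL) {
  mode <- match.arg(mode)
  if (vmax < 0) stop("vmax must be >= 0")
  if (km_c < 0) stop("km_c must be >= 0")
  structure(list(mode = mode, vmax = vmax, km_c = km_c,
                 provenance = provenance, region = region),
            class = "reaction_spec")
}

#' Zeroth-order depletion time bound
#'
#' Time to exhaust an initial concentration at the maximal (unthrottled)
#' volumetric rate; a scale for choosing transient schedules.
#'
#' @param c0 initial concentration, mol m^-3.
#' @param vmax_volumetric volumetric Vmax, mol m^-3 s^-1 (> 0).
#' @return Time in seconds.
#' @export
depletion_time_estimate <- function(c0, vmax_volumetric) {
  if (vmax_volumetric <= 0) stop("vmax must be positive")
  c0 / vmax_volumetric
}
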