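# Physical parameter containers and unit conversions.

#' Fluid properties
#'
#' Culture medium is modelled as water at incubator temperature.
#'
#' @param density kg m^-3 (default 1000).
#' @param viscosity dynamic viscosity, Pa s (default 0.001).
#' @return Object of class `fluid_props`.
#' @export
fluid_props <- function(density = 1000, viscosity = 0.001) {
  if (density <= 0 || viscosity <= 0)
    stop("density and viscosity must be positive")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_props")
}

#' Dissolved-oxygen parameters
#'
#' Literature constants governing oxygen transport and cellular uptake.
#' `Km_mmHg` is quoted as a partial pressure and converted to concentration
#' with Henry's law (see [km_to_concentration()]); the converted value is
#' stored in `Km_c` (mol m^-3).
#'
#' @param D oxygen diffusion coefficient in aqueous media, m^2 s^-1.
#' @param Km_mmHg Michaelis-Menten half-saturation constant, mmHg.
#' @param C0 dissolved-oxygen concentration at the air-liquid interface,
#'   mol m^-3 (equilibrium with the incubator atmosphere).
#' @param K_O2 Henry's-law constant, atm L mol^-1.
#' @param per_cell_rate cell-normalized consumption rate,
#'   nmol min^-1 per 10^6 cells.
#' @return Object of class `oxygen_params`.
#' @export
oxygen_params <- function(D = 3e-9, Km_mmHg = 5.6, C0 = 0.214,
                          K_O2 = 932.4, per_cell_rate = 2) {
  vals <- c(D = D, Km_mmHg = Km_mmHg, C0 = C0, K_O2 = K_O2,
            per_cell_rate = per_cell_rate)
  if (any(vals <= 0))
    stop("all oxygen parameters must be positive")
  structure(list(D = D, Km_mmHg = Km_mmHg, C0 = C0, K_O2 = K_O2,
                 per_cell_rate = per_cell_rate,
                 Km_c = km_to_concentration(Km_mmHg, K_O2)),
            class = "oxygen_params")
}

#' @export
print.oxygen_params <- function(x, ...) {
  cat("<oxygen_params>\n")
  cat(sprintf("  D            %.3g m^2/s\n", x$D))
  cat(sprintf("  Km           %.3g mmHg = %.3g mol/m^3\n", x$Km_mmHg, x$Km_c))
  cat(sprintf("  C0           %.3g mol/m^3 (%.0f uM)\n", x$C0, x$C0 * 1e3))
  cat(sprintf("  K_O2         %.4g atm L/mol\n", x$K_O2))
  cat(sprintf("  uptake rate  %.3g nmol/min per 1e6 cells\n", x$per_cell_rate))
  invisible(x)
}

#' Henry's law: dissolved concentration to partial pressure
#'
#' `P = K_O2 * c`, with `c` expressed per litre.
#'
#' @param c dissolved concentration, mol m^-3 (>= 0).
#' @param K_O2 Henry's-law constant, atm L mol^-1.
#' @return Partial pressure in atm.
#' @export
henry_pressure <- function(c, K_O2 = 932.4) {
  if (any(c < 0) || K_O2 <= 0) stop("negative input to henry_pressure")
  K_O2 * (c / 1000)
}

#' Henry's law: partial pressure to dissolved concentration
#' @param P partial pressure, atm (>= 0).
#' @inheritParams henry_pressure
#' @return Concentration in mol m^-3. Exact inverse of [henry_pressure()].
#' @export
henry_concentration <- function(P, K_O2 = 932.4) {
  if (any(P < 0) || K_O2 <= 0) stop("negative input to henry_concentration")
  P / K_O2 * 1000
}

#' Convert a partial-pressure Km to concentration units
#'
#' The half-saturation constant for cellular oxygen uptake is quoted in mmHg;
#' the consumption rate law operates on concentration, so the value is
#' converted through Henry's law: `km/760` atm divided by `K_O2` gives
#' mol L^-1, times 1000 gives mol m^-3.
#'
#' @param km_mmHg Km in mmHg (>= 0).
#' @inheritParams henry_pressure
#' @return Km in mol m^-3.
#' @export
km_to_concentration <- function(km_mmHg, K_O2 = 932.4) {
  if (any(km_mmHg < 0)) stop("negative Km")
  henry_concentration(km_mmHg / 760, K_O2)
}

#' Chamber specification
#'
#' @param diameter chamber internal diameter, m.
#' @param fill_volume medium volume, m^3.
#' @param n_scaffolds number of scaffolds on the stand.
#' @param port_diameter internal diameter of inlet/outlet ports, m.
#' @param quarter simulate one quarter of the chamber using its symmetry.
#' @return Object of class `chamber_spec`. The fill height implied by
#'   `fill_volume` and `diameter` is stored in `$fill_height`.
#' @export
chamber_spec <- function(diameter = 0.08, fill_volume = 110e-6,
                         n_scaffolds = 12L, port_diameter = 1.6e-3,
                         quarter = TRUE) {
  if (diameter <= 0 || fill_volume <= 0 || port_diameter <= 0)
    stop("chamber dimensions must be positive")
  fill_height <- fill_volume / (pi * (diameter / 2)^2)
  structure(list(diameter = diameter, fill_volume = fill_volume,
                 n_scaffolds = as.integer(n_scaffolds),
                 port_diameter = port_diameter, quarter = quarter,
                 fill_height = fill_height),
            class = "chamber_spec")
}
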