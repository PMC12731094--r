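---
title: "Modelling flow and oxygen transport in a perfusion bioreactor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling flow and oxygen transport in a perfusion bioreactor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxyflow)
```

## The system

`oxyflow` simulates dissolved-oxygen transport in a cylindrical perfusion
bioreactor (8 cm diameter, 110 mL of culture medium) in which medium is
recirculated at 80 mL/min through 1.6 mm ports in the base while
osteoblast-like cells consume oxygen — either suspended/distributed through
the vessel or adherent on twelve porous PLA scaffolds (10 x 10 x 3 mm)
held on a stand. Oxygen enters the medium only at the flat air–liquid
interface at the top of the chamber, where the medium is in Henry-law
equilibrium with the incubator atmosphere; the recirculation loop is
closed, so medium re-enters the inlet with the outlet's solute
concentration.

Three chamber scenarios are built in (`bioreactor_scenario()`):

* `bulk_11M` — 11 million cells distributed through the 110 mL vessel;
  consumption is a volumetric sink over the whole fluid.
* `scaffolds_400k`, `scaffolds_4M` — 12 strut-lattice scaffolds (~50 %
  porosity) seeded with 4x10^5 or 4x10^6 cells each; consumption is a
  surface reaction on scaffold-adjacent fluid faces.

## Governing equations

Flow is steady, incompressible and laminar:

$$\rho\,(u \cdot \nabla) u = -\nabla p + \mu \nabla^2 u,
  \qquad \nabla \cdot u = 0,$$

with water-like properties ($\rho$ = 1000 kg m^-3, $\mu$ = 0.001 Pa s);
body forces are absorbed into the pressure (no buoyancy, isothermal).
Oxygen is transported by advection and diffusion with a Michaelis–Menten
(MM) sink:

$$\frac{\partial c}{\partial t} + u \cdot \nabla c
  = D \nabla^2 c - R(c), \qquad
  R(c) = \frac{V_{max}\, c}{c + K_m},$$

with $D$ = 3x10^-9 m^2 s^-1. The MM law models cellular uptake, not
growth: cell numbers are fixed, and $V_{max}$ is derived from them
(`volumetric_vmax()`, `areal_vmax()`):

* volumetric: per-cell rate (2 nmol min^-1 per 10^6 cells) x cell count /
  vessel volume -> 3.33x10^-6 mol m^-3 s^-1 for 11x10^6 cells in 110 mL;
* areal: per-cell rate x (scaffold count x cells per scaffold) / total
  scaffold area, using the design area of 0.01 m^2 per scaffold (which
  includes internal pore surface) -> 1.333x10^-8 mol m^-2 s^-1 at
  4x10^6 cells per scaffold.

$K_m$ is quoted as a partial pressure (5.6 mmHg) and converted to
concentration units with Henry's law ($P = K_{O_2} c$,
$K_{O_2}$ = 932.4 atm L mol^-1): 7.90x10^-3 mol m^-3
(`km_to_concentration()`). The interface concentration $C_0$ =
0.214 mol m^-3 (214 uM) is taken as given rather than recomputed from an
assumed atmospheric pO2 — back-converting it through $K_{O_2}$ gives
~152 mmHg rather than the 159.6 mmHg of dry air at 21 %, consistent with
a humidified-atmosphere correction, and the stated value is used verbatim.

## Discretization and solvers

All stages share a labelled isotropic voxel grid (`voxel_domain()`):
each voxel is fluid, wall, scaffold solid, air interface, inlet, outlet
or symmetry plane. The chamber is built as a quarter cylinder (two
symmetry planes) at 2 mm spacing by default; scaffold blocks are
generated at their own finer spacing (pore/8 = 87.5 um) and resampled at
chamber cell centres when embedded.

**Flow** (`solve_steady_flow()`) uses a staggered (MAC) finite-volume
grid: first-order upwind advection and explicit viscous diffusion in
pseudo-time, followed by an exact pressure projection (the fluid-cell
Poisson operator is factorized once with a sparse Cholesky and its
Neumann null space grounded at one cell). Boundary conditions: no-slip
on walls and scaffold solid, free-slip on the air interface (flat rigid
lid — free-surface dynamics are not modelled) and on symmetry planes,
and uniform plug velocities on port faces with inflow and outflow rates
balanced exactly. The time step obeys both the advective CFL and the
viscous stability limit (safety 0.9); iteration stops when the maximum
per-step velocity change drops below 10^-6 of the velocity scale, or at
10^4 steps.

The inlet and outlet are realized as vertical circular ports at the base
(periphery and centre respectively), snapped to at least one voxel face;
positions are configurable because the base's internal channels and
baffles are not dimensioned.

**Oxygen transport** (`solve_transport()`) uses finite-volume upwind
advection on the staggered face velocities and central diffusion, which
gives an M-matrix: with consuming sinks and boundary values at or below
$C_0$, concentrations stay in $[0, C_0]$ (verified as a property test).
The steady problem is solved directly (sparse LU) with Picard iteration
on the MM denominators; because the discrete system is linear for frozen
denominators, the closed-loop recirculation condition
$c_{in} = \overline{c}_{out}$ is solved *exactly* at each iteration by
superposing the field response to a unit inlet concentration — iterating
the condition instead converges at the physical recirculation rate
(one vessel turnover per pass, ~80 s each) and would need thousands of
passes. Convergence is declared when the maximum concentration update
falls below 10^-9 mol m^-3. The transient mode steps implicit
diffusion/reaction with explicit upwind advection at CFL 0.9 and declares
steady state below 10^-9 mol m^-3 s^-1. A sealed, reaction-free,
port-free domain is recognized as trivially steady and keeps its initial
equilibrium exactly.

Surface reactions are applied as MM fluxes on fluid faces adjacent to
scaffold voxels, with the face-count area estimate. At chamber
resolution the resolved scaffold surface (a few cm^2 per scaffold) is
necessarily far below the 0.01 m^2 design area that includes the
internal pore surface; the domain records both
(`meta$scaffold_area_resolved`) for transparency. The oxygen budget
(interface influx + inlet − outlet − consumption) is closed to solver
precision at steady state and reported with every solution.

## Scaffold geometry

`generate_sphere_subtracted_scaffold()` mimics the fabricated design: a
solid 10 x 10 x 3 mm block minus a random cluster of 700 um spheres
(uniformly placed centres — the only stated constraints are the pore
size/spacing and the porosity). The sphere count is tuned by bisection:
the cluster for *N* spheres is the prefix of one seeded sequence, so
porosity is monotone in *N* and the search lands within 0.5 pp of the
52.5 % target (one-sphere granularity is ~0.06 pp). Results are
reproducible per seed.

`generate_strut_scaffold()` mimics the simplified simulated design:
orthogonal x- and y-direction struts extruded in z at 700 um pitch. For
width/pitch ratio $a = w/s$ the solid fraction of the two-direction grid
is $2a - a^2$, so the target porosity $\phi$ fixes $a = 1 - \sqrt\phi$
(0.2929 for $\phi = 0.5$). Because voxelization quantizes strut widths,
integer column counts are dithered across struts and chosen per
direction so the measured porosity $p_x p_y$ lands within 0.5 pp of the
target; at the default 87.5 um spacing the residual granularity is
~0.3 pp.

Twelve scaffolds are placed on one ring (radius 25 mm, 30 degrees apart,
stand height 4 mm) as vertical plates tangential to the ring; the
stand's exact shape is not dimensioned and only scaffold placement
affects transport.

## Verification fixtures

`analytic_fixture()` pairs small domains with independent references:

* **slab_consumption** — steady 1-D diffusion against a uniform
  zeroth-order sink (the $c \gg K_m$ limit, realized as `km_c = 0`):
  $c(x) = C_0 - (V_{max}/D)(Lx - x^2/2)$. With $V_{max}$ = 10^-3
  mol m^-3 s^-1 over L = 1 mm the far-wall value is 0.0473 mol m^-3;
  the solver matches the profile to ~10^-3 relative, and halving the
  spacing shrinks the error ~4x.
* **poiseuille_pipe** — the 1.6 mm port at 80 mL/min (mean speed
  $Q/A$ = 0.663 m s^-1). At this Reynolds number (~10^3) the entrance
  length is ~64 diameters, so a short pipe is genuinely undeveloped;
  the developed-profile checks (centreline/mean = 2, wall shear
  $\tau_w = 4\mu u_m/R$ = 3.32 Pa) therefore use
  `solve_developed_flow()`, a streamwise-invariant steady solve of the
  same momentum balance on the voxelized cross-section — the standard
  realization of the fully developed limit. The 3-D solver is checked on
  the same pipe for mean speed, mass balance and divergence.
* **couette** — plane shear between a stationary and a moving plate;
  $\tau = \mu U/h$ is uniform and exact on this grid.
* **well_mixed_mm** — a single fluid cell with an MM sink against
  high-accuracy ODE integration (deSolve), within 0.5 % at backward-Euler
  steps of 36 s over 10 h.
* **closed_box** — equilibrium preservation, exact.

Wall shear stress (`wall_shear_stress()`) is a one-sided estimate
$\mu |u_t| / (h/2)$ per boundary face. On curved walls the voxel
staircase inflates surface area by ~4/pi, biasing the *face-average*
stress low; `wss_summary()` therefore also reports the drag-based mean
(total tangential force / physical wetted area), which is unbiased and
is what the pipe check uses.

## Resolution, accuracy and known limitations

The reference chamber grid is 2 mm (quarter domain, ~3.5x10^3 fluid
cells), chosen so a full scenario — geometry, flow to steady state,
steady transport — completes in well under a minute on one core; the
acceptance suite runs all three scenarios plus the fixtures in tens of
seconds. First-order upwinding adds numerical diffusion of order
$|u|h/2$, which at this spacing exceeds molecular oxygen diffusivity
wherever the local speed exceeds ~3 um/s. Consequences to keep in mind:

* Volume-averaged quantities are robust: the bulk steady oxygen level is
  set by the balance between total consumption and interface influx and
  changes by only a few uM across very different port models and
  resolutions.
* Boundary *films* are not resolved. The air-interface equilibrium layer
  and near-wall/corner depletion zones seen in fine-mesh simulations of
  this vessel are sub-voxel features here: a wall value tens of uM below
  the bulk requires a quasi-stagnant layer of several mm, whose
  isolation numerical diffusion destroys at h = 2 mm. Shell statistics
  ("within two voxels of the interface/wall") therefore read values
  close to the mixed bulk.
* Scaffold pore-scale transport is not resolved at chamber scale;
  scaffold consumption acts through the resolved envelope faces with the
  stated areal rate, so surface oxygen depressions are milder than a
  pore-resolving model would give.

Also out of scope by design: free-surface deformation, cell
proliferation or any coupling of cell number to time, CO2/pH chemistry,
glucose transport, tubing gas exchange (the loop simply equates inlet
and outlet concentrations), and turbulence (the flow is laminar
throughout; port Reynolds number ~10^3 is transitional in a pipe, and
the laminar assumption follows the observed flow regime).

The synthetic scenarios emulate the *stated* operating conditions —
geometry, loadings, flow rate, literature transport constants. They do
not emulate biological variability, cell redistribution, or measured
cell counts; passing tests therefore validate the transport model and
its numerics, not predictions about any particular culture.

## Worked example

```{r example, eval = FALSE}
cfg <- bioreactor_scenario("bulk_11M")          # 2 mm quarter grid
res <- run_scenario(cfg)
print(res$summary)
#> <summary_stats> (uM)
#>   fluid mean 190.5  [190.4, 190.7]  (n = 3476 cells)
#>   interface region mean   190.5
#>   near-wall min / mean    190.4 / 190.5
```

```{r porosity, eval = FALSE}
blk <- generate_sphere_subtracted_scaffold(
  scaffold_spec(target_porosity = 0.525, seed = 1, spacing = 0.175e-3))
blk$meta$porosity
#> [1] 0.5249964
```
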