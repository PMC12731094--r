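Package: oxyflow
Title: Flow and Dissolved-Oxygen Transport Simulation for Perfusion Bioreactors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-based simulation of steady laminar flow and dissolved-oxygen
    transport in cylindrical perfusion bioreactors holding porous bone-mimicking
    scaffolds. Generates sphere-subtraction and strut-lattice scaffold geometries
    with porosity control, solves the incompressible Navier-Stokes equations on a
    staggered voxel grid, transports oxygen by advection and diffusion with
    Michaelis-Menten cellular consumption applied volumetrically or as a surface
    reaction on scaffold walls, derives reaction parameters from cell loadings via
    Henry's-law unit conversions, and summarizes oxygen fields over named regions.
    Includes relative gene-expression quantification (2^-ddCt) for companion qPCR
    assays, analytic fixtures for solver verification, and VTK/STL/CSV export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
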