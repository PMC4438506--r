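Package: smolsph
Title: Smoluchowski Diffusion and Ligand Binding Rates by Smoothed Particle Hydrodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Meshless solver for the time-dependent Smoluchowski drift-diffusion
    equation around reactive targets, using a smoothed particle hydrodynamics
    (SPH) discretization on a uniform cubic lattice. Reactive (Robin) boundary
    conditions are imposed through a continuum surface reaction formulation in
    which the boundary flux becomes a volumetric sink localized by a smoothed
    surface delta function built from a color function. Includes absorbing
    (Dirichlet) boundaries, flux-based association rate (k_on) computation,
    potentials of mean force from analytic radial forms or OpenDX scalar grids
    with trilinear interpolation, closed-form spherical reference solutions for
    verification, and Debye-Hueckel limiting-law fitting of rate versus ionic
    strength.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
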