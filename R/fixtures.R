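#' Deterministic verification fixtures
#'
#' Builds the named benchmark setup together with a manifest of the analytic
#' quantities tests assert against. Fixtures are deterministic: the same
#' `name` (and `seed`, reserved for optional perturbations) always produces
#' the identical object.
#'
#' Available fixtures:
#' * `sphere_transient`: pure diffusion into a sphere (`R1 = 0`, outer
#'   Dirichlet at `R2`), compared against the series solution.
#' * `sphere_dirichlet`: absorbing inner sphere `R1`, Coulombic PMF,
#'   compared against the closed-form steady profile and rate.
#' * `sphere_robin`: same shell with a reactive Robin inner boundary
#'   (`alpha = 1e3` by default).
#' * `plane_interface`: lattice slab with a planar reactive half-space, for
#'   surface-delta/area and normal-direction checks; the manifest carries the
#'   exact window area used by those tests.
#' * `toy_gorge`: spherical obstacle (radius 20 A) with a gorge-axis
#'   sphere-union reactive patch at reduced scale.
#'
#' @param name fixture name (see above).
#' @param seed integer, reserved for perturbed variants (unused by the
#'   deterministic defaults).
#' @param dx lattice spacing override, Angstrom.
#' @param R2 outer radius override, Angstrom.
#' @param alpha Robin coefficient override (sphere_robin), Angstrom/us.
#' @param D diffusion coefficient, Angstrom^2/us.
#' @param Q Coulomb strength for the shell fixtures, Angstrom.
#' @return List with `system` (a `particle_system`), `pmf`, `config` (where
#'   applicable), `problem` (the matching [radial_problem()], if any) and
#'   `manifest` (named list of analytic reference quantities).
#' @export
make_fixture <- function(name = c("sphere_transient", "sphere_dirichlet",
                                  "sphere_robin", "plane_interface",
                                  "toy_gorge"),
                         seed = 1L, dx = 8, R2 = 125, alpha = 1e3,
                         D = 78000, Q = bjerrum_length()) {
  name <- match.arg(name)
  switch(name,
    sphere_transient = {
      sys <- build_particles(domain_spec(dx = dx, R2 = R2))
      pmf <- zero_pmf(sys)
      cfg <- solver_config(D = D, bc_mode = "dirichlet")
      prob <- radial_problem(R1 = 0, R2 = R2, D = D)
      list(system = sys, pmf = pmf, config = cfg, problem = prob,
           manifest = list(times_dimless = c(0.02, 0.05, 0.1, 0.2)))
    },
    sphere_dirichlet = {
      sys <- build_particles(domain_spec(dx = dx, R2 = R2, R1 = 50))
      pmf <- coulomb_pmf(sys, Q = Q)
      cfg <- solver_config(D = D, bc_mode = "dirichlet")
      prob <- radial_problem(R1 = 50, R2 = R2, D = D,
                             betaW = radial_coulomb(Q))
      list(system = sys, pmf = pmf, config = cfg, problem = prob,
           manifest = list(k_analytic = steady_rate(prob)))
    },
    sphere_robin = {
      sys <- build_particles(domain_spec(dx = dx, R2 = R2, R1 = 50))
      sys <- compute_color_normals(sys)
      pmf <- coulomb_pmf(sys, Q = Q)
      cfg <- solver_config(D = D, alpha = alpha, bc_mode = "robin")
      prob <- radial_problem(R1 = 50, R2 = R2, D = D,
                             betaW = radial_coulomb(Q),
                             inner_bc = "robin", alpha = alpha)
      list(system = sys, pmf = pmf, config = cfg, problem = prob,
           manifest = list(k_analytic = steady_rate(prob)))
    },
    plane_interface = {
      fix <- plane_interface_fixture(dx = 1)
      fix
    },
    toy_gorge = {
      sys <- build_particles(domain_spec(dx = 1.5, R2 = 32, R1 = 20,
                                         reactive = "none"))
      patch <- gorge_patch_spheres(4, origin = c(0, 0, 20 - 1.6),
                                   axis = c(0, 0, 1))
      sys <- build_reactive_patch(sys, patch$centers, patch$radii)
      sys <- compute_color_normals(sys)
      list(system = sys, pmf = zero_pmf(sys), config = NULL, problem = NULL,
           manifest = list(patch = patch))
    })
}

#' Planar-interface lattice fixture
#'
#' A lattice slab, laterally `L x L` and spanning `z` in `(-zmax, zmax)`,
#' with the half-space `z > 0` labeled reactive and `z < 0` solvent. The
#' surface-delta identity is asserted over an interior window (margin
#' `>= 2h` from the lateral faces, where sink sums are complete): summing
#' `s_i / d_i` over solvent particles in the window approximates the window
#' area.
#'
#' @param dx lattice spacing, Angstrom.
#' @param nL lateral extent in lattice cells.
#' @param margin_cells interior-window margin in lattice cells (at least
#'   `2h/dx`).
#' @return List with `system`, and `manifest` containing `window_area`
#'   (Angstrom^2) and `window` (logical mask of window solvent particles).
#' @export
plane_interface_fixture <- function(dx = 1, nL = 20L, margin_cells = 4L) {
  ks <- kernel_spec(dx)
  zmax <- 3 * ks$h
  nz <- ceiling(zmax / dx)
  ax <- (seq_len(nL) - 0.5) * dx
  az <- (seq.int(-nz, nz - 1L) + 0.5) * dx
  pos <- as.matrix(expand.grid(x = ax, y = ax, z = az))
  dimnames(pos) <- NULL
  region <- factor(ifelse(pos[, 3] > 0, "reactive", "solvent"),
                   levels = REGIONS)
  spec <- structure(list(dx = dx, R1 = NA, R2 = NA, reactive = "plane",
                         kernel = ks), class = "domain_spec")
  sys <- new_particle_system(pos, region, spec)
  lo <- margin_cells * dx
  hi <- nL * dx - margin_cells * dx
  window <- region == "solvent" &
    pos[, 1] > lo & pos[, 1] < hi & pos[, 2] > lo & pos[, 2] < hi
  list(system = sys, pmf = zero_pmf(sys), config = NULL, problem = NULL,
       manifest = list(window_area = (hi - lo)^2, window = window))
}
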