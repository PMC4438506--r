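#' Bjerrum length
#'
#' Distance at which the Coulomb energy of two unit charges equals the thermal
#' energy k_B T, \eqn{l_B = e^2 / (4 \pi \epsilon_0 \epsilon_r k_B T)}. This
#' is the natural prefactor for the dimensionless Coulomb potential of mean
#' force `beta W(r) = Q / r` of two +1 e charges.
#'
#' @param temperature kinetic temperature, K.
#' @param epsilon relative solvent dielectric constant.
#' @return Bjerrum length, Angstrom (about 7.14 A for water at 298.15 K).
#' @export
bjerrum_length <- function(temperature = 298.15, epsilon = 78.54) {
  e2_4pieps0 <- 14.399645  # e^2/(4 pi eps0), eV * Angstrom
  kB <- 8.617333262e-5     # eV / K
  e2_4pieps0 / (kB * temperature * epsilon)
}

new_pmf_field <- function(W, provider, parameters) {
  structure(list(W = W, provider = provider, parameters = parameters),
            class = "pmf_field")
}

#' @export
print.pmf_field <- function(x, ...) {
  cat(sprintf("PMF field (%s): %d particles, betaW range [%.4g, %.4g] kBT\n",
              x$provider, length(x$W), min(x$W), max(x$W)))
  invisible(x)
}

#' Coulombic potential of mean force
#'
#' Radial PMF `beta W(r) = Q / r` in thermal units. `Q > 0` is repulsive
#' (like charges), `Q < 0` attractive. For two +1 e charges in water the
#' physical prefactor is the Bjerrum length, [bjerrum_length()].
#'
#' @param points N x 3 coordinate matrix or a `particle_system` (Angstrom).
#' @param Q Coulomb strength, Angstrom (energy prefactor in k_B T * Angstrom).
#' @return A `pmf_field` whose `$W` holds beta W per particle (k_B T units).
#' @export
coulomb_pmf <- function(points, Q = bjerrum_length()) {
  screened_coulomb_pmf(points, Q = Q, kappa_dh = 0)
}

#' Screened (Debye-Hueckel) Coulombic potential of mean force
#'
#' `beta W(r) = (Q / r) exp(-kappa_dh * r)`: a Yukawa-screened Coulomb form
#' emulating ionic-strength screening; reduces to [coulomb_pmf()] at
#' `kappa_dh = 0`.
#'
#' @inheritParams coulomb_pmf
#' @param kappa_dh inverse screening length, Angstrom^-1 (non-negative).
#' @return A `pmf_field` (beta W in k_B T units).
#' @export
screened_coulomb_pmf <- function(points, Q = bjerrum_length(), kappa_dh = 0) {
  pos <- if (inherits(points, "particle_system")) points$positions else points
  stopifnot(is.matrix(pos), ncol(pos) == 3L, kappa_dh >= 0)
  r <- sqrt(rowSums(pos^2))
  if (any(r == 0))
    stop("Coulombic PMF is singular at the origin", call. = FALSE)
  W <- Q / r * exp(-kappa_dh * r)
  new_pmf_field(W, if (kappa_dh == 0) "coulomb" else "screened_coulomb",
                list(Q = Q, kappa_dh = kappa_dh))
}

#' Zero potential of mean force
#'
#' @inheritParams coulomb_pmf
#' @return A `pmf_field` with beta W identically zero (pure diffusion).
#' @export
zero_pmf <- function(points) {
  pos <- if (inherits(points, "particle_system")) points$positions else points
  new_pmf_field(numeric(nrow(pos)), "zero", list())
}

#' Potential of mean force from a gridded potential
#'
#' Samples a scalar grid (typically an electrostatic potential from a
#' Poisson-Boltzmann solver, read with [read_dx_grid()]) onto particles by
#' trilinear interpolation and scales by the ligand charge. Grid values are
#' assumed to be in k_B T / e units (the convention of APBS output), so
#' `beta W = charge * value`.
#'
#' @inheritParams coulomb_pmf
#' @param grid a `scalar_grid` (see [read_dx_grid()]).
#' @param charge ligand charge in units of e.
#' @param out_of_box `"error"` or `"clamp"` (clamp to the nearest grid face;
#'   the number of clamped points is reported via a message).
#' @return A `pmf_field` (beta W in k_B T units).
#' @export
grid_pmf <- function(points, grid, charge = 1, out_of_box = c("error", "clamp")) {
  pos <- if (inherits(points, "particle_system")) points$positions else points
  vals <- trilinear_sample(grid, pos, out_of_box = match.arg(out_of_box))
  new_pmf_field(charge * vals, "grid",
                list(charge = charge, origin = grid$origin,
                     spacing = grid$spacing, shape = grid$shape))
}
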