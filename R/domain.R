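#' Region labels
#'
#' Every particle carries exactly one region label:
#' * `solvent` -- the problem domain Omega where the concentration evolves;
#' * `reactive` -- the reactive-boundary extension Omega_a behind the reactive
#'   surface Gamma_a (pinned to 0 in Dirichlet mode; excluded from diffusion
#'   sums and carrying the color function phi = 1 in Robin mode);
#' * `outer` -- the bulk-boundary extension Omega_b outside Gamma_b, pinned to
#'   the bulk concentration;
#' * `molecule` -- non-reactive obstacle particles, excluded from every sum
#'   (reflective Neumann boundary by exclusion).
#'
#' @format Character vector of the four labels, in code order.
#' @export
REGIONS <- c("solvent", "reactive", "outer", "molecule")

#' Specify a particle-discretized domain
#'
#' Describes the geometry to be discretized by [build_particles()]: a spherical
#' outer boundary of radius `R2`, an optional inner spherical body of radius
#' `R1` that is either fully reactive (`reactive = "inner_sphere"`) or a
#' non-reactive obstacle (`reactive = "none"`), and the lattice spacing. A
#' reactive surface patch carved out of an obstacle (a union of spheres
#' intersected with the obstacle surface, as used for active-site gorges) is
#' applied afterwards with [build_reactive_patch()].
#'
#' @param dx lattice spacing, Angstrom.
#' @param R2 outer boundary radius, Angstrom.
#' @param R1 inner body radius, Angstrom; 0 for no inner body.
#' @param reactive `"inner_sphere"` to make the whole inner body reactive,
#'   `"none"` for no reactive region (or an obstacle to be patched later).
#' @param kernel optional [kernel_spec()]; defaults to `kernel_spec(dx)`.
#' @return An object of class `domain_spec`.
#' @export
domain_spec <- function(dx, R2, R1 = 0, reactive = c("inner_sphere", "none"),
                        kernel = kernel_spec(dx)) {
  reactive <- match.arg(reactive)
  stopifnot(dx > 0, R2 > R1, R1 >= 0)
  if (R1 == 0) reactive <- "none"
  structure(list(dx = dx, R1 = R1, R2 = R2, reactive = reactive,
                 kernel = kernel),
            class = "domain_spec")
}

#' Build the particle discretization of a domain
#'
#' Generates a uniform cubic lattice with points at `(i + 1/2, j + 1/2,
#' k + 1/2) * dx` relative to the domain center (no particle sits exactly at
#' the origin or on an analytic surface), classifies each point into a region
#' (see [REGIONS]), and discards points that can never contribute: farther
#' than `2h` outside the outer boundary or deeper than `2h` inside the inner
#' body. The boundary extensions are exactly `2h` thick -- the kernel support
#' radius -- so kernel sums near the boundaries are never truncated.
#'
#' Classification for a point at radius r:
#' * `outer` if `R2 < r <= R2 + 2h`;
#' * `solvent` if `R1 < r <= R2`;
#' * `reactive` (or `molecule` when the inner body is non-reactive) if
#'   `R1 - 2h < r <= R1`.
#'
#' The number density is uniform, `d = 1/dx^3`.
#'
#' @param spec a [domain_spec()].
#' @return An object of class `particle_system`: a list with `positions`
#'   (N x 3 matrix, Angstrom), `region` (factor with levels [REGIONS]), `d`
#'   (number density per particle, Angstrom^-3), `kernel`, and slots for the
#'   lazily computed neighbor structure and surface normals.
#' @export
build_particles <- function(spec) {
  stopifnot(inherits(spec, "domain_spec"))
  ks <- spec$kernel
  h2 <- 2 * ks$h
  rmax <- spec$R2 + h2
  nmax <- ceiling(rmax / spec$dx + 0.5)
  ax <- seq.int(-nmax, nmax - 1L) + 0.5
  pos <- as.matrix(expand.grid(x = ax, y = ax, z = ax)) * spec$dx
  dimnames(pos) <- NULL
  r <- sqrt(rowSums(pos^2))
  keep <- r <= rmax & r > (spec$R1 - h2)
  pos <- pos[keep, , drop = FALSE]
  r <- r[keep]
  region <- rep.int(1L, length(r))
  region[r > spec$R2] <- 3L
  if (spec$R1 > 0) {
    inner <- r <= spec$R1
    region[inner] <- if (spec$reactive == "inner_sphere") 2L else 4L
  }
  region <- factor(REGIONS[region], levels = REGIONS)
  if (!any(region == "solvent"))
    stop("degenerate domain: no solvent particles", call. = FALSE)
  new_particle_system(pos, region, spec)
}

new_particle_system <- function(positions, region, spec) {
  structure(list(positions = positions,
                 region = region,
                 d = rep.int(1 / spec$dx^3, nrow(positions)),
                 kernel = spec$kernel,
                 spec = spec,
                 pairs = NULL,
                 normals = NULL,
                 has_normal = NULL),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("SPH particle system: %d particles (dx = %g A, h = %g A)\n",
              nrow(x$positions), x$kernel$dx, x$kernel$h))
  print(table(x$region))
  if (!is.null(x$pairs))
    cat(sprintf("neighbor pairs: %d (cutoff %g A)\n",
                length(x$pairs$i), x$pairs$cutoff))
  if (!is.null(x$normals))
    cat(sprintf("normals: %d particles flagged with a surface normal\n",
                sum(x$has_normal)))
  invisible(x)
}

#' Carve a reactive surface patch out of an obstacle
#'
#' Relabels `molecule` particles that fall inside the union of the given
#' spheres as `reactive`. The resulting reactive boundary Gamma_a is the part
#' of the obstacle surface covered by the sphere union -- the construction
#' used to define nested active-site boundaries along a binding gorge (probe
#' spheres placed along the gorge axis, intersected with the molecular body).
#'
#' @param system a [build_particles()] result containing `molecule` particles.
#' @param centers numeric 3-vector or n x 3 matrix of sphere centers, Angstrom.
#' @param radii numeric vector of sphere radii (recycled to the number of
#'   centers), Angstrom.
#' @return The system with relabeled regions (normals are invalidated and
#'   must be recomputed).
#' @export
build_reactive_patch <- function(system, centers, radii) {
  stopifnot(inherits(system, "particle_system"))
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 3L, byrow = TRUE)
  stopifnot(ncol(centers) == 3L, all(radii > 0))
  radii <- rep_len(radii, nrow(centers))
  mol <- which(system$region == "molecule")
  if (!length(mol))
    stop("no obstacle ('molecule') particles to carve a patch from", call. = FALSE)
  inside <- rep(FALSE, length(mol))
  for (s in seq_len(nrow(centers))) {
    dd <- sweep(system$positions[mol, , drop = FALSE], 2L, centers[s, ])
    inside <- inside | rowSums(dd^2) <= radii[s]^2
  }
  if (!any(inside))
    stop("empty reactive patch: no obstacle particle lies inside the sphere union",
         call. = FALSE)
  system$region[mol[inside]] <- "reactive"
  system$normals <- NULL
  system$has_normal <- NULL
  system
}

#' Gorge-axis reactive patch recipe
#'
#' Centers and radii for nested reactive boundaries built from probe spheres
#' placed along a gorge axis: spheres 1-6 sit at 16.6, 13.6, 10.6, 7.6, 4.6
#' and 1.6 Angstrom along the axis from its origin, with radii 12, 9, 6, 6, 6
#' and 6 Angstrom. Reactive boundary `n` uses spheres `n` through 6.
#'
#' @param n index of the reactive boundary (1 = outermost).
#' @param origin 3-vector, axis origin (Angstrom).
#' @param axis 3-vector, gorge axis direction (normalized internally).
#' @return List with `centers` (matrix) and `radii` suitable for
#'   [build_reactive_patch()].
#' @export
gorge_patch_spheres <- function(n = 1, origin = c(0, 0, 0), axis = c(0, 0, 1)) {
  stopifnot(n >= 1, n <= 6)
  dist <- c(16.6, 13.6, 10.6, 7.6, 4.6, 1.6)
  radii <- c(12, 9, 6, 6, 6, 6)
  axis <- axis / sqrt(sum(axis^2))
  sel <- n:6
  centers <- outer(dist[sel], axis) +
    matrix(origin, length(sel), 3L, byrow = TRUE)
  list(centers = centers, radii = radii[sel])
}
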