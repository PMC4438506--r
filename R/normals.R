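#' Surface normals from the color-function gradient
#'
#' Defines the sharp color function phi = 1 on `reactive` particles (the
#' sub-domain Omega_a behind the reactive surface) and phi = 0 on `solvent`
#' particles, and estimates the unit normal at each particle as the normalized
#' SPH gradient of phi,
#' \deqn{\mathbf{n}_i = \frac{\sum_{j} (\phi_j - \phi_i)\, \nabla_i w(\mathbf{r}_{ij}, h_r) / d_j}
#'                           {\left|\sum_{j} (\phi_j - \phi_i)\, \nabla_i w(\mathbf{r}_{ij}, h_r) / d_j\right|},}
#' with the sum over solvent and reactive particles. Normals therefore point
#' from the solvent into the reactive body. Particles whose raw gradient
#' magnitude falls below `floor` (no interface within kernel range, or only
#' marginal support overlap) are flagged as having no normal and are excluded
#' from every surface-delta sum.
#'
#' @param system a `particle_system` containing reactive particles.
#' @param floor minimum raw gradient magnitude (Angstrom^-1) for a normal to
#'   be defined.
#' @return The system with `$normals` (N x 3, unit rows where defined, zero
#'   elsewhere) and `$has_normal` (logical) populated.
#' @export
compute_color_normals <- function(system, floor = 1e-8) {
  stopifnot(inherits(system, "particle_system"))
  if (!any(system$region == "reactive"))
    stop("no reactive particles: cannot build a color function", call. = FALSE)
  system <- ensure_neighbors(system)
  pr <- system$pairs
  h_r <- system$kernel$h_r
  n <- nrow(system$positions)
  phi <- as.numeric(system$region == "reactive")
  eligible <- system$region %in% c("solvent", "reactive")
  ## only cross pairs (phi_i != phi_j) contribute to the gradient
  sub <- eligible[pr$i] & eligible[pr$j] & (phi[pr$i] != phi[pr$j]) &
    pr$r <= system$kernel$kappa * h_r
  i <- pr$i[sub]; j <- pr$j[sub]; r <- pr$r[sub]
  grad <- matrix(0, n, 3L)
  if (length(i)) {
    coef <- (phi[j] - phi[i]) / system$d[j] *
      kernel_radial_derivative(r, h_r) / r
    for (ax in 1:3) {
      acc <- rowsum(coef * (system$positions[i, ax] - system$positions[j, ax]),
                    i, reorder = FALSE)
      grad[as.integer(rownames(acc)), ax] <- acc
    }
  }
  gnorm <- sqrt(rowSums(grad^2))
  has <- gnorm > floor
  if (!any(has))
    warning("no interface within kernel range of any particle: empty normal set")
  normals <- matrix(0, n, 3L)
  normals[has, ] <- grad[has, , drop = FALSE] / gnorm[has]
  system$normals <- normals
  system$has_normal <- has
  system
}

#' Surface-delta (Robin sink) coefficients
#'
#' The geometric coefficient of the continuum-surface-reaction sink,
#' \deqn{s_i = \sum_{k \in \Omega_a,\, r_{ik} \le 2 h_r}
#'    \frac{(\mathbf{n}_i + \mathbf{n}_k)\cdot \mathbf{r}_{ik}}{d_k\, r_{ik}}
#'    \frac{dw(r_{ik}, h_r)}{dr},}
#' a discrete Riemann sum of the smoothed surface delta function. It vanishes
#' for particles farther than `2 h_r` from the reactive surface, is
#' non-negative up to quadrature noise, and depends only on the geometry
#' (never on the reactive coefficient alpha). Its volume sum
#' \eqn{\sum_i s_i / d_i} over the solvent approximates the area of the
#' reactive surface.
#'
#' @param system a `particle_system` with normals (see
#'   [compute_color_normals()]).
#' @return Numeric vector of per-particle sink coefficients (Angstrom^-1),
#'   nonzero only on solvent particles near the reactive surface.
#' @export
robin_sink_coefficients <- function(system) {
  stopifnot(inherits(system, "particle_system"))
  if (is.null(system$normals))
    stop("normals not computed: call compute_color_normals() first", call. = FALSE)
  system <- ensure_neighbors(system)
  pr <- system$pairs
  h_r <- system$kernel$h_r
  n <- nrow(system$positions)
  sub <- system$region[pr$i] == "solvent" & system$region[pr$j] == "reactive" &
    system$has_normal[pr$i] & system$has_normal[pr$j] &
    pr$r <= system$kernel$kappa * h_r
  s <- numeric(n)
  if (!any(sub)) return(s)
  i <- pr$i[sub]; j <- pr$j[sub]; r <- pr$r[sub]
  rvec <- system$positions[i, , drop = FALSE] - system$positions[j, , drop = FALSE]
  dots <- rowSums((system$normals[i, , drop = FALSE] +
                   system$normals[j, , drop = FALSE]) * rvec) / r
  contrib <- dots * kernel_radial_derivative(r, h_r) / system$d[j]
  acc <- rowsum(contrib, i, reorder = FALSE)
  s[as.integer(rownames(acc))] <- acc
  s
}
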