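## Independent oracles used by the tests. These deliberately avoid the
## package's own code paths (brute-force scans, finite differences,
## quadrature) so that agreement is evidence, not tautology.

## O(N^2) all-pairs neighbor scan
brute_neighbors <- function(positions, cutoff) {
  d <- as.matrix(dist(positions))
  hit <- which(d <= cutoff & d > 0, arr.ind = TRUE)
  ord <- order(hit[, 1], hit[, 2])
  list(i = unname(hit[ord, 1]), j = unname(hit[ord, 2]))
}

## 1-D finite-difference steady solution of the radial Smoluchowski problem
## (conservative flux form on a uniform grid, tridiagonal solve)
fd_radial_steady <- function(problem, nr = 800) {
  R1 <- problem$R1; R2 <- problem$R2; D <- problem$D
  dr <- (R2 - R1) / (nr - 1)
  r <- seq(R1, R2, length.out = nr)
  rf <- r[-nr] + dr / 2                      # faces
  bWf <- problem$betaW(rf)
  dbW <- (problem$betaW(r[-1]) - problem$betaW(r[-nr])) / dr
  ## face flux F = D[(p_{k+1}-p_k)/dr + dbW * (p_k+p_{k+1})/2]
  a_lo <- D * (-1 / dr + dbW / 2) * rf^2     # coefficient of p_k in r^2 F
  a_hi <- D * (1 / dr + dbW / 2) * rf^2      # coefficient of p_{k+1}
  A <- matrix(0, nr, nr)
  b <- numeric(nr)
  for (k in 2:(nr - 1)) {
    ## r^2F(k+1/2) - r^2F(k-1/2) = 0
    A[k, k - 1] <- -a_lo[k - 1]
    A[k, k]     <- a_lo[k] - a_hi[k - 1]
    A[k, k + 1] <- a_hi[k]
  }
  if (problem$inner_bc == "dirichlet") {
    A[1, 1] <- 1; b[1] <- 0
  } else {
    ## flux balance at R1: r^2 F(1+1/2) = R1^2 alpha p_1
    A[1, 1] <- a_lo[1] - problem$alpha * R1^2
    A[1, 2] <- a_hi[1]
    b[1] <- 0
  }
  A[nr, nr] <- 1; b[nr] <- problem$p_bulk
  p <- solve(A, b)
  list(r = r, p = p)
}

## 1-D finite-difference transient diffusion into a sphere via u = r p
## (u_t = D u_rr, u(0)=0, u(R)=R p_bulk, u(.,0)=0)
fd_sphere_transient <- function(problem, t_end, nr = 600) {
  R <- problem$R2; D <- problem$D
  dr <- R / (nr - 1)
  r <- seq(0, R, length.out = nr)
  u <- numeric(nr); u[nr] <- R * problem$p_bulk
  dt <- 0.25 * dr^2 / D
  nst <- ceiling(t_end / dt); dt <- t_end / nst
  lam <- D * dt / dr^2
  for (s in seq_len(nst)) {
    u[2:(nr - 1)] <- u[2:(nr - 1)] +
      lam * (u[3:nr] - 2 * u[2:(nr - 1)] + u[1:(nr - 2)])
  }
  p <- c(NA, u[-1] / r[-1])
  p[1] <- p[2]  # r -> 0 limit, adequate for interpolation use
  list(r = r, p = p)
}

## adaptive quadrature of the 3-D kernel normalization integral
kernel_norm_quadrature <- function(h) {
  4 * pi * stats::integrate(function(r) kernel_value(r, h) * r^2,
                            0, 2 * h, rel.tol = 1e-12, abs.tol = 0)$value
}

## small all-solvent periodic-free box for conservation tests (no pinned
## particles; kernel sums are truncated at the faces, which conservation
## does not care about because the pairwise terms are antisymmetric)
closed_box_system <- function(n_cells = 8L, dx = 1) {
  sys <- build_particles(domain_spec(dx = dx, R2 = n_cells * dx / 2))
  sys$region[] <- "solvent"
  sys$normals <- NULL
  sys$has_normal <- NULL
  sys
}
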