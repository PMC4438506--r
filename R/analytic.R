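#' Radial reference problem
#'
#' Spherically symmetric Smoluchowski problem used for verification: solvent
#' shell between an inner reactive sphere of radius `R1` (absent when
#' `R1 = 0`) and an outer bulk boundary at `R2` held at `p_bulk`, with a
#' radial potential of mean force.
#'
#' @param R1 inner sphere radius, Angstrom (0 = none).
#' @param R2 outer boundary radius, Angstrom.
#' @param D diffusion coefficient, Angstrom^2/us.
#' @param betaW radial PMF in thermal units: a function of r, or the result
#'   of [radial_coulomb()]. Default zero.
#' @param inner_bc `"dirichlet"` (absorbing) or `"robin"` (reactive with
#'   coefficient `alpha`).
#' @param alpha Robin reactive coefficient, Angstrom/us.
#' @param p_bulk outer boundary concentration.
#' @return Object of class `radial_problem`.
#' @export
radial_problem <- function(R1, R2, D = 78000, betaW = NULL,
                           inner_bc = c("dirichlet", "robin"), alpha = 0,
                           p_bulk = 1) {
  inner_bc <- match.arg(inner_bc)
  stopifnot(R2 > R1, R1 >= 0, D > 0, alpha >= 0, p_bulk > 0)
  if (is.null(betaW)) betaW <- radial_coulomb(0)  # zero PMF, closed-form path
  structure(list(R1 = R1, R2 = R2, D = D, betaW = betaW,
                 inner_bc = inner_bc, alpha = alpha, p_bulk = p_bulk),
            class = "radial_problem")
}

#' Radial Coulomb PMF for reference problems
#'
#' `betaW(r) = Q / r` with a closed-form antiderivative of
#' `exp(betaW(s)) / s^2` used by [steady_profile()] and [steady_rate()]
#' (avoiding numerical quadrature).
#'
#' @param Q Coulomb strength, Angstrom (see [bjerrum_length()]).
#' @return A function of r carrying the closed-form machinery.
#' @export
radial_coulomb <- function(Q) {
  f <- function(r) Q / r
  attr(f, "coulomb_Q") <- Q
  f
}

## integral of exp(betaW(s)) / s^2 over [a, b] (a <= b), vectorized over b
shell_integral <- function(problem, a, b) {
  Q <- attr(problem$betaW, "coulomb_Q")
  if (!is.null(Q)) {
    if (Q == 0) return(1 / a - 1 / b)
    return((exp(Q / a) - exp(Q / b)) / Q)
  }
  f <- function(s) exp(problem$betaW(s)) / s^2
  vapply(b, function(bb) {
    if (bb <= a) return(0)
    stats::integrate(f, a, bb, rel.tol = 1e-10, abs.tol = 0)$value
  }, numeric(1))
}

#' Steady concentration profile of the radial problem
#'
#' Closed construction of the steady Smoluchowski solution in a shell: with
#' \eqn{I(a,b) = \int_a^b e^{\beta W(s)} s^{-2} ds},
#' the absorbing (Dirichlet) profile is
#' \deqn{p(r) = p_\mathrm{bulk}\, e^{\beta W(R_2) - \beta W(r)}
#'       \frac{I(R_1, r)}{I(R_1, R_2)},}
#' and the Robin profile replaces the zero boundary value by the flux balance
#' \eqn{D\,[p' + \beta W' p] = \alpha p} at `R1` (normal pointing from the
#' reactive sphere into the solvent). The Robin profile tends to the
#' Dirichlet one as `alpha -> Inf` and to the flat bulk profile as
#' `alpha -> 0`.
#'
#' @param r radii, Angstrom (in `[R1, R2]`).
#' @param problem a [radial_problem()] with `R1 > 0`.
#' @return Concentration p(r) (units of `p_bulk`).
#' @export
steady_profile <- function(r, problem) {
  stopifnot(inherits(problem, "radial_problem"), problem$R1 > 0)
  if (any(r < problem$R1 - 1e-9) || any(r > problem$R2 + 1e-9))
    stop("radius outside [R1, R2]", call. = FALSE)
  r <- pmin(pmax(r, problem$R1), problem$R2)
  bW <- problem$betaW
  Itot <- shell_integral(problem, problem$R1, problem$R2)
  Ir <- shell_integral(problem, problem$R1, r)
  eW2 <- exp(bW(problem$R2))
  if (problem$inner_bc == "dirichlet") {
    problem$p_bulk * exp(-bW(r)) * eW2 * Ir / Itot
  } else {
    a <- problem$alpha
    p1 <- problem$p_bulk * eW2 /
      (exp(bW(problem$R1)) + a * problem$R1^2 * Itot / problem$D)
    exp(-bW(r)) * (exp(bW(problem$R1)) * p1 +
                     (a * problem$R1^2 * p1 / problem$D) * Ir)
  }
}

#' Analytic steady-state on-rate of the radial problem
#'
#' Bulk-normalized steady flux into the inner sphere:
#' \deqn{k_\mathrm{Dirichlet} = \frac{4 \pi D\, e^{\beta W(R_2)}}{I(R_1, R_2)}, \qquad
#'       k_\mathrm{Robin} = \frac{4 \pi R_1^2\, \alpha\, e^{\beta W(R_2)}}
#'       {e^{\beta W(R_1)} + \alpha R_1^2 I(R_1, R_2)/D}.}
#' With `betaW = 0` and `R2 -> Inf` the Dirichlet rate reduces to the
#' classical Smoluchowski rate `4 pi D R1`; the Robin rate tends to the
#' Dirichlet rate as `alpha -> Inf` and vanishes linearly in `alpha` as
#' `alpha -> 0`.
#'
#' @param problem a [radial_problem()] with `R1 > 0`.
#' @return Rate constant, Angstrom^3/us.
#' @export
steady_rate <- function(problem) {
  stopifnot(inherits(problem, "radial_problem"), problem$R1 > 0)
  bW <- problem$betaW
  Itot <- shell_integral(problem, problem$R1, problem$R2)
  eW2 <- exp(bW(problem$R2))
  if (problem$inner_bc == "dirichlet") {
    4 * pi * problem$D * eW2 / Itot
  } else {
    a <- problem$alpha
    4 * pi * problem$R1^2 * a * eW2 /
      (exp(bW(problem$R1)) + a * problem$R1^2 * Itot / problem$D)
  }
}

#' Transient diffusion profile in a sphere
#'
#' Series solution for pure diffusion into a sphere of radius `R2` with zero
#' initial concentration and surface concentration `p_bulk` (the `R1 = 0`,
#' `betaW = 0` reference case):
#' \deqn{\frac{p(r,t)}{p_\mathrm{bulk}} = 1 + \frac{2 R}{\pi r} \sum_{n\ge1}
#'   \frac{(-1)^n}{n} \sin\frac{n \pi r}{R}\,
#'   e^{-D n^2 \pi^2 t / R^2},}
#' with the r -> 0 limit \eqn{1 + 2\sum (-1)^n e^{-D n^2 \pi^2 t/R^2}}. The
#' series is truncated once the next term bound falls below `tol`.
#'
#' @param r radii, Angstrom (`0 <= r <= R2`).
#' @param t time, microseconds (non-negative scalar).
#' @param problem a [radial_problem()] with `R1 = 0` (only `R2`, `D`,
#'   `p_bulk` are used).
#' @param tol series truncation tolerance.
#' @return Concentration p(r, t).
#' @export
transient_sphere_profile <- function(r, t, problem, tol = 1e-12) {
  stopifnot(inherits(problem, "radial_problem"), t >= 0, length(t) == 1L)
  if (any(r < 0) || any(r > problem$R2 + 1e-9))
    stop("radius outside [0, R2]", call. = FALSE)
  R <- problem$R2
  if (t == 0) {
    out <- numeric(length(r))
    out[r >= R] <- problem$p_bulk
    return(out)
  }
  tau <- problem$D * pi^2 * t / R^2
  out <- rep(1, length(r))
  small <- r < 1e-9 * R
  x <- pi * r[!small] / R
  pref <- 2 / x  # = 2R/(pi r)
  nmax <- max(1, ceiling(sqrt(log(max(2 * max(c(pref, 2)), 4) / tol) / tau)))
  for (n in seq_len(nmax)) {
    e <- exp(-n^2 * tau)
    if (any(!small))
      out[!small] <- out[!small] + pref * ((-1)^n / n) * sin(n * x) * e
    if (any(small)) out[small] <- out[small] + 2 * (-1)^n * e
    if (2 * e / n < tol * 1e-2) break
  }
  problem$p_bulk * pmax(out, 0)
}

#' Relative L2 error between two particle fields
#'
#' \eqn{\|p_\mathrm{num} - p_\mathrm{ref}\|_2 / \|p_\mathrm{ref}\|_2} over the
#' masked particles (on a uniform lattice the volume weights cancel, making
#' this proportional to the continuous relative L2 norm).
#'
#' @param p_num numeric vector, numerical field.
#' @param p_ref numeric vector, reference field (same length).
#' @param mask logical or integer index of particles to include (default
#'   all).
#' @return Relative L2 error (scalar).
#' @export
l2_error <- function(p_num, p_ref, mask = NULL) {
  stopifnot(length(p_num) == length(p_ref))
  if (!is.null(mask)) {
    p_num <- p_num[mask]
    p_ref <- p_ref[mask]
  }
  if (!length(p_num)) stop("empty mask", call. = FALSE)
  nref <- sqrt(sum(p_ref^2))
  if (nref == 0) stop("reference field has zero norm: metric undefined",
                      call. = FALSE)
  sqrt(sum((p_num - p_ref)^2)) / nref
}
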