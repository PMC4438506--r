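#' Run one spherical benchmark case
#'
#' End-to-end run of a single verification case at one resolution:
#' discretize, integrate, and compare against the analytic reference.
#'
#' * `"transient"`: pure diffusion into the sphere (`R1 = 0`, `betaW = 0`);
#'   the SPH field is compared with the series solution at the dimensionless
#'   times `times_dimless = D t / R2^2`, and both the per-time maximum and
#'   the pooled (concatenated over times) relative L2 error are reported.
#' * `"dirichlet"`: absorbing inner sphere with Coulombic PMF, steady state
#'   compared against the closed-form profile and rate.
#' * `"robin"`: reactive inner boundary (coefficient `alpha`), steady state
#'   against the closed-form Robin profile and rate.
#'
#' @param case one of `"transient"`, `"dirichlet"`, `"robin"`.
#' @param dx lattice spacing, Angstrom.
#' @param R2,R1 outer/inner radii, Angstrom.
#' @param alpha Robin reactive coefficient, Angstrom/us.
#' @param D diffusion coefficient, Angstrom^2/us.
#' @param Q Coulomb strength of the shell PMF, Angstrom.
#' @param times_dimless dimensionless comparison times for the transient
#'   case.
#' @param integrator passed to [solver_config()] (`"euler"` reaches the same
#'   steady state in half the work).
#' @param verbose print progress.
#' @return One-row data frame: `case`, `dx`, particle counts, `l2` (pooled
#'   for the transient case, steady-state otherwise), `l2_max` (transient
#'   per-time maximum), `k_sph`, `k_balance`, `k_analytic`, relative rate
#'   errors, and `converged`.
#' @export
run_spherical_case <- function(case = c("transient", "dirichlet", "robin"),
                               dx = 8, R2 = 125, R1 = 50, alpha = 1e3,
                               D = 78000, Q = bjerrum_length(),
                               times_dimless = c(0.02, 0.05, 0.1, 0.2),
                               integrator = "euler", verbose = FALSE) {
  case <- match.arg(case)
  row <- data.frame(case = case, dx = dx, n_particles = NA_integer_,
                    n_solvent = NA_integer_, l2 = NA_real_, l2_max = NA_real_,
                    k_sph = NA_real_, k_balance = NA_real_,
                    k_analytic = NA_real_, k_rel_err = NA_real_,
                    k_balance_rel_err = NA_real_, converged = NA)
  if (case == "transient") {
    sys <- build_particles(domain_spec(dx = dx, R2 = R2))
    pmf <- zero_pmf(sys)
    cfg <- solver_config(D = D, bc_mode = "dirichlet", integrator = integrator)
    prob <- radial_problem(R1 = 0, R2 = R2, D = D)
    times <- times_dimless * R2^2 / D
    run <- run_transient(sys, pmf, cfg, times)
    sol <- sys$region == "solvent"
    r <- sqrt(rowSums(sys$positions[sol, , drop = FALSE]^2))
    err2 <- ref2 <- 0
    l2s <- numeric(length(times))
    for (m in seq_along(times)) {
      pref <- transient_sphere_profile(r, times[m], prob)
      pnum <- run$snapshots[sol, m]
      l2s[m] <- l2_error(pnum, pref)
      err2 <- err2 + sum((pnum - pref)^2)
      ref2 <- ref2 + sum(pref^2)
    }
    row$n_particles <- nrow(sys$positions)
    row$n_solvent <- sum(sol)
    row$l2 <- sqrt(err2 / ref2)
    row$l2_max <- max(l2s)
    row$converged <- TRUE
    attr(row, "l2_per_time") <- data.frame(t_dimless = times_dimless, l2 = l2s)
    if (verbose)
      message(sprintf("transient dx=%g: pooled L2 = %.4f, max = %.4f",
                      dx, row$l2, row$l2_max))
    return(row)
  }
  ## steady shell cases
  sys <- build_particles(domain_spec(dx = dx, R2 = R2, R1 = R1))
  sys <- compute_color_normals(sys)
  pmf <- coulomb_pmf(sys, Q = Q)
  bw <- radial_coulomb(Q)
  if (case == "dirichlet") {
    cfg <- solver_config(D = D, bc_mode = "dirichlet", integrator = integrator)
    prob <- radial_problem(R1 = R1, R2 = R2, D = D, betaW = bw)
  } else {
    cfg <- solver_config(D = D, alpha = alpha, bc_mode = "robin",
                         integrator = integrator)
    prob <- radial_problem(R1 = R1, R2 = R2, D = D, betaW = bw,
                           inner_bc = "robin", alpha = alpha)
  }
  res <- run_to_steady(sys, pmf, cfg, verbose = verbose)
  sol <- sys$region == "solvent"
  r <- sqrt(rowSums(sys$positions[sol, , drop = FALSE]^2))
  pref <- steady_profile(pmin(pmax(r, R1), R2), prob)
  row$n_particles <- nrow(sys$positions)
  row$n_solvent <- sum(sol)
  row$l2 <- l2_error(res$state$p[sol], pref)
  row$k_analytic <- steady_rate(prob)
  row$k_sph <- if (case == "dirichlet")
    kon_dirichlet(res$state, sys, pmf, cfg) else
    kon_robin(res$state, sys, cfg)
  row$k_balance <- kon_balance(res$state, sys, pmf, cfg)
  row$k_rel_err <- row$k_sph / row$k_analytic - 1
  row$k_balance_rel_err <- row$k_balance / row$k_analytic - 1
  row$converged <- res$converged
  if (verbose)
    message(sprintf("%s dx=%g: L2 = %.5f, k err = %+.3f (balance %+.3f)",
                    case, dx, row$l2, row$k_rel_err, row$k_balance_rel_err))
  row
}

#' Spherical verification suite
#'
#' Runs the spherical benchmark cases over a ladder of resolutions and
#' collects the error table; optionally checks the numbers against named
#' thresholds.
#'
#' @param cases subset of `c("transient", "dirichlet", "robin")`.
#' @param dx_ladder decreasing vector of lattice spacings, Angstrom.
#' @param thresholds optional named list; recognized entries
#'   `transient_l2`, `dirichlet_l2`, `robin_l2` (upper bounds on the pooled /
#'   steady L2 at the coarsest resolution) and `rate_rel_err` (upper bound on
#'   `|k_balance_rel_err|` at the finest resolution). Adds a logical `pass`
#'   attribute per check.
#' @param ... forwarded to [run_spherical_case()].
#' @return Data frame with one row per case x resolution (class
#'   `verification_report`), with any threshold checks in
#'   `attr(, "checks")`.
#' @export
verify_spherical <- function(cases = c("transient", "dirichlet", "robin"),
                             dx_ladder = c(8, 4), thresholds = NULL, ...) {
  cases <- match.arg(cases, several.ok = TRUE)
  stopifnot(all(diff(dx_ladder) < 0) || length(dx_ladder) == 1L)
  rows <- list()
  for (case in cases)
    for (dx in dx_ladder)
      rows[[length(rows) + 1L]] <- run_spherical_case(case, dx = dx, ...)
  rep <- do.call(rbind, rows)
  class(rep) <- c("verification_report", "data.frame")
  if (!is.null(thresholds)) {
    checks <- list()
    coarse <- max(dx_ladder); fine <- min(dx_ladder)
    get <- function(case, dx, col) {
      v <- rep[rep$case == case & rep$dx == dx, col]
      if (length(v)) v else NA_real_
    }
    if (!is.null(thresholds$transient_l2))
      checks$transient_l2 <- get("transient", coarse, "l2") <= thresholds$transient_l2
    if (!is.null(thresholds$dirichlet_l2))
      checks$dirichlet_l2 <- get("dirichlet", coarse, "l2") <= thresholds$dirichlet_l2
    if (!is.null(thresholds$robin_l2))
      checks$robin_l2 <- get("robin", coarse, "l2") <= thresholds$robin_l2
    if (!is.null(thresholds$rate_rel_err)) {
      for (case in intersect(cases, c("dirichlet", "robin")))
        checks[[paste0(case, "_rate")]] <-
          abs(get(case, fine, "k_balance_rel_err")) <= thresholds$rate_rel_err
    }
    attr(rep, "checks") <- checks
  }
  rep
}

#' @export
print.verification_report <- function(x, ...) {
  cat("Spherical verification report\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  checks <- attr(x, "checks")
  if (!is.null(checks)) {
    cat("threshold checks:\n")
    for (nm in names(checks))
      cat(sprintf("  %-16s %s\n", nm, if (isTRUE(checks[[nm]])) "PASS" else "FAIL"))
  }
  invisible(x)
}
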