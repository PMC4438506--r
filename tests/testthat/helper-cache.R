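## Memoized heavy runs shared between the benchmark (acceptance) tests and
## the unit tests, so each expensive simulation happens once per test session.

.run_cache <- new.env(parent = emptyenv())

## spherical benchmark runs at the study conditions (R2 = 125, R1 = 50,
## Bjerrum Coulomb PMF, D = 78000, alpha = 1e3)
benchmark_runs <- function() {
  if (!is.null(.run_cache$bench)) return(.run_cache$bench)
  runs <- list(
    transient8 = run_spherical_case("transient", dx = 8),
    transient4 = run_spherical_case("transient", dx = 4),
    dirichlet8 = run_spherical_case("dirichlet", dx = 8),
    dirichlet4 = run_spherical_case("dirichlet", dx = 4),
    robin8     = run_spherical_case("robin", dx = 8),
    robin4     = run_spherical_case("robin", dx = 4))
  .run_cache$bench <- runs
  runs
}

## coarse shell (R1 = 10, R2 = 25, dx = 1) solved to steady state in both
## modes, with the 1-D finite-difference oracle evaluated on the particles
oracle_shell_runs <- function() {
  if (!is.null(.run_cache$oracle)) return(.run_cache$oracle)
  sys <- build_particles(domain_spec(dx = 1, R2 = 25, R1 = 10))
  sys <- compute_color_normals(sys)
  pmf <- coulomb_pmf(sys, Q = 7.136)
  sol <- sys$region == "solvent"
  r <- pmin(pmax(sqrt(rowSums(sys$positions[sol, , drop = FALSE]^2)), 10), 25)
  out <- list()
  for (mode in c("dirichlet", "robin")) {
    cfg <- solver_config(D = 1000, bc_mode = mode,
                         alpha = if (mode == "robin") 50 else 0,
                         integrator = "euler")
    res <- run_to_steady(sys, pmf, cfg)
    prob <- radial_problem(R1 = 10, R2 = 25, D = 1000,
                           betaW = radial_coulomb(7.136),
                           inner_bc = mode, alpha = 50)
    fd <- fd_radial_steady(prob, nr = 1500)
    pfd <- approx(fd$r, fd$p, xout = r)$y
    out[[mode]] <- list(
      converged = res$converged,
      l2_vs_fd = l2_error(res$state$p[sol], pfd),
      fd_vs_closed = l2_error(pfd, steady_profile(r, prob)))
  }
  .run_cache$oracle <- out
  out
}
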