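## shared small fixtures for solver properties (built once per file)
small_shell <- local({
  sys <- build_particles(domain_spec(dx = 1.5, R2 = 25, R1 = 10))
  compute_color_normals(sys)
})
small_cfg_dir <- solver_config(D = 1000, bc_mode = "dirichlet")

test_that("uniform concentration with zero PMF is stationary", {
  sys <- small_shell
  pmf <- zero_pmf(sys)
  cfg <- solver_config(D = 1000, bc_mode = "robin", alpha = 0)
  st <- init_state(sys, cfg)
  st$p[] <- cfg$p_bulk
  ## robin, alpha = 0: reflective everywhere, nothing moves
  expect_equal(max(abs(rhs_robin(st, sys, pmf, cfg))), 0)
  st2 <- sph_step(st, sys, pmf, cfg)
  expect_equal(st2$p, st$p)
  ## dirichlet with the reactive layer also at p_bulk: pair differences vanish
  st3 <- init_state(sys, small_cfg_dir)
  st3$p[] <- 1
  expect_equal(max(abs(rhs_dirichlet(st3, sys, zero_pmf(sys), small_cfg_dir))), 0)
})

test_that("pure diffusion conserves mass on a closed box", {
  sys <- closed_box_system(n_cells = 8L, dx = 1)
  pmf <- zero_pmf(sys)
  cfg <- solver_config(D = 100, bc_mode = "robin", alpha = 0,
                       integrator = "euler")
  st <- init_state(sys, cfg)
  set.seed(21)
  st$p <- runif(length(st$p))
  ## RHS sums to zero up to roundoff (pairwise antisymmetry): compare the
  ## cancellation against the gross magnitude being cancelled
  rhs <- rhs_robin(st, sys, pmf, cfg)
  expect_lt(abs(sum(rhs)) / sum(abs(rhs)), 1e-12)
  m0 <- sum(st$p / sys$d)
  op <- sph_operator(sys, pmf, cfg)
  for (s in 1:1000) st <- sph_step(st, sys, pmf, cfg, op)
  expect_lt(abs(sum(st$p / sys$d) - m0) / m0, 1e-10)
})

test_that("drift term also conserves mass pairwise on a closed box", {
  sys <- closed_box_system(n_cells = 8L, dx = 1)
  set.seed(22)
  pmf <- structure(list(W = runif(nrow(sys$positions), -1, 1),
                        provider = "test", parameters = list()),
                   class = "pmf_field")
  cfg <- solver_config(D = 100, bc_mode = "robin", alpha = 0)
  st <- init_state(sys, cfg)
  st$p <- runif(length(st$p), 0.5, 1.5)
  rhs <- rhs_robin(st, sys, pmf, cfg)
  expect_lt(abs(sum(rhs)) / sum(abs(rhs)), 1e-12)
})

test_that("time step above the stability cap is rejected at configuration", {
  sys <- small_shell
  cfg <- solver_config(D = 1000, dt = 0.3 * 1.5^2 / 1000)  # 3x the cap
  expect_error(sph_operator(sys, zero_pmf(sys), cfg), "stability cap")
  ok <- solver_config(D = 1000, dt = 0.05 * 1.5^2 / 1000)
  expect_s3_class(sph_operator(sys, zero_pmf(sys), ok), "sph_operator")
})

test_that("one Heun step is second-order against two half steps", {
  sys <- small_shell
  pmf <- zero_pmf(sys)
  mk <- function(dt) solver_config(D = 1000, bc_mode = "dirichlet", dt = dt,
                                   integrator = "heun")
  dt <- 0.08 * 1.5^2 / 1000
  st0 <- init_state(sys, mk(dt))
  full <- sph_step(st0, sys, pmf, mk(dt))
  half <- sph_step(sph_step(st0, sys, pmf, mk(dt / 2)), sys, pmf, mk(dt / 2))
  e1 <- max(abs(full$p - half$p))
  ## quarter steps: error should shrink ~4x (O(dt^2) local comparison)
  full2 <- sph_step(st0, sys, pmf, mk(dt / 2))
  half2 <- sph_step(sph_step(st0, sys, pmf, mk(dt / 4)), sys, pmf, mk(dt / 4))
  e2 <- max(abs(full2$p - half2$p))
  ## Heun: local error O(dt^3) -> full-vs-halved difference shrinks ~8x
  expect_gt(e1 / e2, 6)
  ## Euler: local error O(dt^2) -> shrinks ~4x
  mke <- function(dt) solver_config(D = 1000, bc_mode = "dirichlet", dt = dt,
                                    integrator = "euler")
  fe1 <- max(abs(sph_step(st0, sys, pmf, mke(dt))$p -
                 sph_step(sph_step(st0, sys, pmf, mke(dt / 2)), sys, pmf,
                          mke(dt / 2))$p))
  fe2 <- max(abs(sph_step(st0, sys, pmf, mke(dt / 2))$p -
                 sph_step(sph_step(st0, sys, pmf, mke(dt / 4)), sys, pmf,
                          mke(dt / 4))$p))
  expect_lt(fe1 / fe2, 5)
  expect_gt(fe1 / fe2, 3)
})

test_that("reflective Robin surface with alpha = 0 relaxes to the bulk", {
  sys <- small_shell
  pmf <- zero_pmf(sys)
  cfg <- solver_config(D = 1000, bc_mode = "robin", alpha = 0,
                       integrator = "euler", steady_rel_tol = 1e-7)
  res <- run_to_steady(sys, pmf, cfg)
  expect_true(res$converged)
  sol <- sys$region == "solvent"
  expect_lt(max(abs(res$state$p[sol] - 1)), 1e-6)
  expect_equal(kon_robin(res$state, sys, cfg), 0)
  expect_equal(tail(res$rates$k_raw, 1), 0)
})

test_that("steady shell profiles match the 1-D finite-difference oracle", {
  ## coarse shell, both boundary conditions, with a Coulomb PMF
  runs <- oracle_shell_runs()
  expect_true(runs$dirichlet$converged)
  expect_true(runs$robin$converged)
  ## Robin agrees to well under 1%; the absorbing case carries ~2% from the
  ## half-spacing offset of the pinned-layer wall at this resolution
  expect_lt(runs$robin$l2_vs_fd, 0.02)
  expect_lt(runs$dirichlet$l2_vs_fd, 0.025)
  ## and the FD oracle itself agrees with the closed-form solution
  expect_lt(runs$dirichlet$fd_vs_closed, 0.005)
  expect_lt(runs$robin$fd_vs_closed, 0.005)
})

test_that("concentration respects the approximate discrete maximum principle", {
  sys <- small_shell
  pmf <- coulomb_pmf(sys, Q = 7.136)
  for (mode in c("dirichlet", "robin")) {
    cfg <- solver_config(D = 1000, bc_mode = mode,
                         alpha = if (mode == "robin") 100 else 0,
                         integrator = "euler", max_steps = 4000)
    res <- suppressWarnings(run_to_steady(sys, pmf, cfg))
    expect_gt(min(res$state$p), -0.02)
    expect_lt(max(res$state$p), 1.02)
  }
})

test_that("steady k_on is non-decreasing in alpha", {
  sys <- small_shell
  pmf <- zero_pmf(sys)
  ks <- vapply(c(0, 20, 100, 1000, 1e5), function(a) {
    cfg <- solver_config(D = 1000, bc_mode = "robin", alpha = a,
                         integrator = "euler")
    res <- run_to_steady(sys, pmf, cfg)
    kon_robin(res$state, sys, cfg)
  }, numeric(1))
  expect_true(all(diff(ks) >= 0))
  expect_equal(ks[1], 0)
})

test_that("divergent configurations raise a divergence error naming the step", {
  sys <- small_shell
  pmf <- zero_pmf(sys)
  cfg <- solver_config(D = 1000, bc_mode = "dirichlet", integrator = "euler")
  st <- init_state(sys, cfg)
  st$p[which(sys$region == "solvent")[1]] <- Inf
  expect_error(sph_step(st, sys, pmf, cfg), "divergence.*step")
})
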