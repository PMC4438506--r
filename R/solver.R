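#' Solver configuration
#'
#' Physical and numerical parameters for the SPH integration of the
#' Smoluchowski equation.
#'
#' The explicit time step must satisfy `dt <= stability_cap * dx^2 / D`
#' (default cap 0.1, an empirically safe bound for the 3-D SPH Laplacian with
#' `h = 1.3 dx`); when `dt` is `NULL` it is set to exactly that bound at
#' operator assembly. The reactive sink term is always advanced
#' semi-implicitly (backward in the local sink), which leaves the steady
#' state unchanged while remaining stable for arbitrarily large `alpha`.
#'
#' @param D diffusion coefficient, Angstrom^2 / microsecond.
#' @param alpha reactive (Robin) coefficient, Angstrom / microsecond;
#'   `alpha = 0` is a reflective surface, `alpha -> Inf` approaches an
#'   absorbing one.
#' @param bc_mode boundary condition on the reactive surface: `"dirichlet"`
#'   (absorbing, concentration pinned to 0 on the reactive layer) or
#'   `"robin"` (reflective layer plus continuum-surface-reaction sink).
#' @param dt time step, microseconds, or `NULL` for the stability bound.
#' @param p_bulk bulk concentration (dimensionless normalization; default 1).
#' @param integrator `"heun"` (two-stage, default) or `"euler"` (forward).
#'   Steady states are identical; only transient accuracy differs.
#' @param stability_cap multiplier in the `dt` bound.
#' @param max_steps integration step limit.
#' @param steady_rel_tol relative change of k_on (and of the field, scaled by
#'   `p_bulk`) over `steady_window` steps below which the run is declared
#'   steady.
#' @param steady_window window length in steps for the steadiness test.
#' @param cadence steps between k_on recordings.
#' @return Object of class `solver_config`.
#' @export
solver_config <- function(D = 78000, alpha = 0,
                          bc_mode = c("dirichlet", "robin"),
                          dt = NULL, p_bulk = 1,
                          integrator = c("heun", "euler"),
                          stability_cap = 0.1, max_steps = 200000L,
                          steady_rel_tol = 1e-5, steady_window = 200L,
                          cadence = 50L) {
  bc_mode <- match.arg(bc_mode)
  integrator <- match.arg(integrator)
  stopifnot(D > 0, alpha >= 0, p_bulk > 0, stability_cap > 0,
            max_steps >= 1, steady_rel_tol > 0, steady_window >= 1,
            cadence >= 1)
  structure(list(D = D, alpha = alpha, bc_mode = bc_mode, dt = dt,
                 p_bulk = p_bulk, integrator = integrator,
                 stability_cap = stability_cap,
                 max_steps = as.integer(max_steps),
                 steady_rel_tol = steady_rel_tol,
                 steady_window = as.integer(steady_window),
                 cadence = as.integer(cadence)),
            class = "solver_config")
}

check_dt <- function(config, dx) {
  cap <- config$stability_cap * dx^2 / config$D
  if (is.null(config$dt)) return(cap)
  if (config$dt > cap * (1 + 1e-12))
    stop(sprintf("dt = %g exceeds the stability cap %g = %g * dx^2 / D",
                 config$dt, cap, config$stability_cap), call. = FALSE)
  config$dt
}

#' Assemble the discrete SPH evolution operator
#'
#' Builds the sparse linear operator `A` with `dp/dt = A p` (minus the
#' reactive sink, kept separate), encoding the pairwise SPH discretization of
#' the Smoluchowski equation:
#' * diffusion term over solvent + outer (+ reactive in Dirichlet mode)
#'   neighbors, with the reactive layer excluded in Robin mode (reflective by
#'   exclusion);
#' * drift term (PMF differences) over solvent neighbors only;
#' * in Robin mode, the per-particle surface-delta sink coefficients
#'   `alpha * s_i` (see [robin_sink_coefficients()]).
#'
#' Rows of pinned particles (outer layer; reactive layer in Dirichlet mode)
#' are zero, so pinned values are invariant under the evolution. `molecule`
#' particles are excluded from every sum.
#'
#' @param system a `particle_system` (neighbors computed on demand; normals
#'   required in Robin mode).
#' @param pmf a `pmf_field` (`beta W` per particle).
#' @param config a [solver_config()].
#' @return Internal operator object (class `sph_operator`) consumed by
#'   [sph_step()], [run_to_steady()] and the rate functions.
#' @export
sph_operator <- function(system, pmf, config) {
  stopifnot(inherits(system, "particle_system"),
            inherits(pmf, "pmf_field"),
            inherits(config, "solver_config"))
  system <- ensure_neighbors(system)
  n <- nrow(system$positions)
  if (length(pmf$W) != n)
    stop("PMF field length does not match the particle count", call. = FALSE)
  reg <- system$region
  sol <- reg == "solvent"
  summed <- if (config$bc_mode == "dirichlet")
    c("solvent", "reactive", "outer") else c("solvent", "outer")
  if (any(!is.finite(pmf$W[reg %in% c("solvent", "reactive", "outer")])))
    stop("non-finite PMF on a summed particle", call. = FALSE)

  pr <- system$pairs
  h <- system$kernel$h
  Dc <- config$D
  W <- pmf$W

  use <- sol[pr$i] & (reg[pr$j] %in% summed) & pr$r <= system$kernel$kappa * h
  i <- pr$i[use]; j <- pr$j[use]; r <- pr$r[use]
  cij <- (2 * Dc / system$d[j]) * kernel_radial_derivative(r, h) / r
  Ai <- c(i, i); Aj <- c(j, i); Ax <- c(-cij, cij)

  used <- sol[pr$i] & sol[pr$j] & pr$r <= system$kernel$kappa * h
  i2 <- pr$i[used]; j2 <- pr$j[used]; r2 <- pr$r[used]
  cd <- (Dc / system$d[j2]) * (W[i2] - W[j2]) *
    kernel_radial_derivative(r2, h) / r2
  Ai <- c(Ai, i2, i2); Aj <- c(Aj, i2, j2); Ax <- c(Ax, cd, cd)

  A <- Matrix::sparseMatrix(i = Ai, j = Aj, x = Ax, dims = c(n, n))

  sink <- numeric(n)
  if (config$bc_mode == "robin" && config$alpha > 0) {
    if (is.null(system$normals))
      stop("Robin mode requires surface normals: call compute_color_normals() first",
           call. = FALSE)
    sink <- robin_sink_coefficients(system)
  }
  pinned <- reg == "outer" | (config$bc_mode == "dirichlet" & reg == "reactive")
  pin_value <- ifelse(reg == "outer", config$p_bulk, 0)
  structure(list(A = A, sink = sink, pinned = pinned, pin_value = pin_value,
                 solvent = sol, bc_mode = config$bc_mode,
                 dt = check_dt(config, system$kernel$dx)),
            class = "sph_operator")
}

#' Initial concentration state
#'
#' The concentration starts at zero throughout the problem domain (and the
#' reactive layer) and at `p_bulk` on the outer layer, emulating ligand
#' entering from the bulk boundary.
#'
#' @param system a `particle_system`.
#' @param config a [solver_config()].
#' @return Object of class `concentration_state`: list with `p` (per-particle
#'   concentration), `t` (elapsed time, microseconds) and `step`.
#' @export
init_state <- function(system, config) {
  p <- numeric(nrow(system$positions))
  p[system$region == "outer"] <- config$p_bulk
  structure(list(p = p, t = 0, step = 0L, bc_mode = config$bc_mode),
            class = "concentration_state")
}

#' @export
print.concentration_state <- function(x, ...) {
  cat(sprintf("concentration state (%s): t = %g us (%g ns), step %d, p in [%.4g, %.4g]\n",
              x$bc_mode, x$t, 1e3 * x$t, x$step, min(x$p), max(x$p)))
  invisible(x)
}

#' Right-hand side, Dirichlet mode
#'
#' Per-particle `dp/dt` of the SPH-discretized Smoluchowski equation with an
#' absorbing reactive layer: pairwise diffusion over solvent, outer and
#' reactive neighbors plus the drift (PMF) term over solvent neighbors;
#' zero on pinned (outer, reactive) and `molecule` particles.
#'
#' @param state a `concentration_state`.
#' @param system a `particle_system`.
#' @param pmf a `pmf_field`.
#' @param config a [solver_config()] with `bc_mode = "dirichlet"`.
#' @param op optional pre-assembled [sph_operator()] (assembled on the fly
#'   otherwise).
#' @return Numeric vector of `dp/dt`, microsecond^-1.
#' @export
rhs_dirichlet <- function(state, system, pmf, config, op = NULL) {
  if (config$bc_mode != "dirichlet")
    stop("config is not in dirichlet mode", call. = FALSE)
  if (is.null(op)) op <- sph_operator(system, pmf, config)
  as.numeric(op$A %*% state$p)
}

#' Right-hand side, Robin mode
#'
#' As [rhs_dirichlet()] but with the reactive layer excluded from the
#' diffusion sum (reflective treatment) and the continuum-surface-reaction
#' sink `- alpha * p_i * s_i` applied near the reactive surface.
#'
#' @inheritParams rhs_dirichlet
#' @param config a [solver_config()] with `bc_mode = "robin"`.
#' @export
rhs_robin <- function(state, system, pmf, config, op = NULL) {
  if (config$bc_mode != "robin")
    stop("config is not in robin mode", call. = FALSE)
  if (is.null(op)) op <- sph_operator(system, pmf, config)
  as.numeric(op$A %*% state$p) - config$alpha * op$sink * state$p
}

stage_update <- function(p, op, alpha, dt) {
  pn <- p + dt * as.numeric(op$A %*% p)
  if (alpha > 0) pn <- pn / (1 + dt * alpha * op$sink)
  pn[op$pinned] <- op$pin_value[op$pinned]
  pn
}

#' Advance the concentration one time step
#'
#' Explicit update of the SPH ODE system: forward Euler or two-stage Heun on
#' the diffusion + drift operator, with the reactive sink treated
#' semi-implicitly (stable for any `alpha`, identical fixed point). Pinned
#' boundary values are re-imposed after the update.
#'
#' @inheritParams rhs_dirichlet
#' @return The advanced `concentration_state`.
#' @export
sph_step <- function(state, system, pmf, config, op = NULL) {
  if (is.null(op)) op <- sph_operator(system, pmf, config)
  dt <- if (is.null(config$dt)) op$dt else check_dt(config, system$kernel$dx)
  p <- state$p
  if (config$integrator == "euler") {
    pn <- stage_update(p, op, config$alpha, dt)
  } else {
    p1 <- stage_update(p, op, config$alpha, dt)
    p2 <- stage_update(p1, op, config$alpha, dt)
    pn <- 0.5 * (p + p2)
    pn[op$pinned] <- op$pin_value[op$pinned]
  }
  if (any(!is.finite(pn)))
    stop(sprintf("divergence: non-finite concentration after step %d (t = %g us)",
                 state$step + 1L, state$t + dt), call. = FALSE)
  state$p <- pn
  state$t <- state$t + dt
  state$step <- state$step + 1L
  state
}

#' Integrate to steady state
#'
#' Advances the system until the reaction rate and the concentration field
#' stop changing: the run is declared steady when, over a window of
#' `steady_window` steps, both the relative change of k_on and the maximum
#' field change (scaled by `p_bulk`) drop below `steady_rel_tol`. The k_on(t)
#' series is recorded every `cadence` steps.
#'
#' @inheritParams rhs_dirichlet
#' @param config a [solver_config()] (either mode).
#' @param verbose print progress every recording.
#' @return List with `state` (final `concentration_state`), `rates` (a
#'   `rate_series` data frame: `t_us`, `t_ns`, `k_raw` in Angstrom^3/us,
#'   `k_molar` in 1/(M min)), and `converged` (logical).
#' @export
run_to_steady <- function(system, pmf, config, verbose = FALSE) {
  if (any(system$region == "reactive") && is.null(system$normals))
    system <- compute_color_normals(system)
  system <- ensure_neighbors(system)
  op <- sph_operator(system, pmf, config)
  attr(op, "rate_ctx") <- make_rate_context(system, pmf, config)
  state <- init_state(system, config)
  dt <- op$dt
  rec_t <- rec_k <- numeric(0)
  k_prev <- NA_real_
  p_prev <- state$p
  steps_since_check <- 0L
  converged <- FALSE
  check_every <- max(config$steady_window, config$cadence)
  for (s in seq_len(config$max_steps)) {
    state <- sph_step(state, system, pmf, config, op)
    steps_since_check <- steps_since_check + 1L
    if (state$step %% config$cadence == 0L) {
      k <- kon_state(state, system, pmf, config, op)
      rec_t <- c(rec_t, state$t); rec_k <- c(rec_k, k)
      if (verbose)
        message(sprintf("step %d  t = %.4g ns  k_on = %.6g A^3/us",
                        state$step, 1e3 * state$t, k))
    }
    if (steps_since_check >= check_every) {
      k <- kon_state(state, system, pmf, config, op)
      dk <- if (is.na(k)) 0 else if (is.na(k_prev)) Inf else
        abs(k - k_prev) / max(abs(k), .Machine$double.eps)
      dp <- max(abs(state$p - p_prev)) / config$p_bulk
      if (dk < config$steady_rel_tol && dp < config$steady_rel_tol) {
        converged <- TRUE
        break
      }
      k_prev <- k
      p_prev <- state$p
      steps_since_check <- 0L
    }
  }
  k_final <- kon_state(state, system, pmf, config, op)
  rec_t <- c(rec_t, state$t); rec_k <- c(rec_k, k_final)
  rates <- rate_series(rec_t, rec_k)
  if (!converged)
    warning(sprintf("not steady after %d steps (last k_on = %g)",
                    state$step, k_final))
  list(state = state, rates = rates, converged = converged, operator = op)
}

#' Integrate to prescribed times and record snapshots
#'
#' Advances the system and returns the concentration field at each requested
#' time (the step size divides each interval exactly, rounded to the nearest
#' count that respects the stability cap).
#'
#' @inheritParams run_to_steady
#' @param times increasing vector of target times, microseconds.
#' @return List with `state` (final) and `snapshots` (matrix, one column per
#'   requested time).
#' @export
run_transient <- function(system, pmf, config, times) {
  stopifnot(all(diff(times) > 0), all(times > 0))
  op <- sph_operator(system, pmf, config)
  state <- init_state(system, config)
  snaps <- matrix(NA_real_, nrow(system$positions), length(times))
  cfg <- config
  for (m in seq_along(times)) {
    span <- times[m] - state$t
    nst <- max(1L, ceiling(span / op$dt - 1e-9))
    cfg$dt <- span / nst
    for (s in seq_len(nst)) state <- sph_step(state, system, pmf, cfg, op)
    state$t <- times[m]  # guard against roundoff drift
    snaps[, m] <- state$p
  }
  list(state = state, snapshots = snaps, times = times)
}
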