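#' Export particles (and optionally a field) to CSV
#'
#' Columns: `x, y, z, region, nx, ny, nz` (normal components are zero where
#' no normal is defined) and, when a state is given, the concentration `p`.
#'
#' @param system a `particle_system`.
#' @param path output file.
#' @param state optional `concentration_state` whose `p` column to include.
#' @return `path`, invisibly.
#' @export
export_particles_csv <- function(system, path, state = NULL) {
  df <- data.frame(x = system$positions[, 1],
                   y = system$positions[, 2],
                   z = system$positions[, 3],
                   region = as.character(system$region))
  if (!is.null(system$normals)) {
    df$nx <- system$normals[, 1]
    df$ny <- system$normals[, 2]
    df$nz <- system$normals[, 3]
  } else {
    df$nx <- df$ny <- df$nz <- 0
  }
  if (!is.null(state)) df$p <- state$p
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a rate series to CSV
#'
#' @param rates a `rate_series`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_rates_csv <- function(rates, path) {
  utils::write.csv(as.data.frame(rates), path, row.names = FALSE)
  invisible(path)
}

#' Save / load a simulation checkpoint
#'
#' Binary container (RDS) holding positions, labels, the concentration field
#' and the elapsed time.
#'
#' @param system a `particle_system`.
#' @param state a `concentration_state`.
#' @param path checkpoint file.
#' @return `write_checkpoint`: `path` invisibly; `read_checkpoint`: a list
#'   with `system` and `state`.
#' @export
write_checkpoint <- function(system, state, path) {
  saveRDS(list(system = system, state = state,
               package_version = as.character(utils::packageVersion("smolsph"))),
          path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- readRDS(path)
  stopifnot(is.list(obj), !is.null(obj$system), !is.null(obj$state))
  obj
}

#' Read a run configuration file
#'
#' YAML or JSON (by extension) mapping of the run parameters; see the
#' package CLI script for the recognized keys (`dx`, `R1`, `R2`, `alpha`,
#' `D`, `bc_mode`, `pmf`, ...).
#'
#' @param path configuration file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

#' Export a Debye-Hueckel fit as JSON
#'
#' @param fit a `dh_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_dh_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(k0 = fit$k0, kH = fit$kH, Z_E = fit$Z_E, Z_I = fit$Z_I,
         kH_policy = fit$kH_policy, se = as.list(fit$se), rmsd = fit$rmsd,
         I = fit$I, k = fit$k, fitted = fit$fitted),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
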