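#' Run configuration files
#'
#' A run configuration bundles everything needed to reproduce a
#' simulation: grid size, model parameters, integrator and noise settings,
#' a protocol selector with its parameters, the master seed and output
#' path. Configurations round-trip losslessly through JSON; unknown keys
#' are rejected on read so typos cannot silently change a run.
#'
#' @param n Grid points per side.
#' @param params [model_params()].
#' @param integrator [integrator_config()].
#' @param noise [noise_spec()] or NULL.
#' @param protocol Protocol name ("simulate", "ramp", "hysteresis",
#'   "ensemble", "lyapunov", "kymograph", "dispersion").
#' @param protocol_params Named list of protocol-specific settings.
#' @param seed Master seed.
#' @param out Output path.
#' @return Object of class \code{an_run_config}.
#' @export
run_config <- function(n = 256, params = model_params(A = 1000),
                       integrator = integrator_config(),
                       noise = noise_spec(), protocol = "simulate",
                       protocol_params = list(t_final = 1), seed = 1,
                       out = "out") {
  structure(list(n = n, params = params, integrator = integrator,
                 noise = noise, protocol = protocol,
                 protocol_params = protocol_params, seed = seed, out = out),
            class = "an_run_config")
}

#' @rdname run_config
#' @param config An \code{an_run_config}.
#' @param path File path (JSON).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "an_run_config"))
  x <- list(
    n = config$n,
    params = config$params[c("A", "R", "S", "time_unit")],
    integrator = config$integrator[c("dt", "cfl_warn_threshold")],
    noise = if (is.null(config$noise)) NULL else
      config$noise[c("D", "duration", "seed")],
    protocol = config$protocol,
    protocol_params = config$protocol_params,
    seed = config$seed,
    out = config$out)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("n", "params", "integrator", "noise", "protocol",
             "protocol_params", "seed", "out")
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  }
  chk <- function(part, keys) {
    bad <- setdiff(names(part), keys)
    if (length(bad)) stop("unknown configuration keys: ",
                          paste(bad, collapse = ", "))
  }
  chk(x$params, c("A", "R", "S", "time_unit"))
  chk(x$integrator, c("dt", "cfl_warn_threshold"))
  if (!is.null(x$noise)) chk(x$noise, c("D", "duration", "seed"))
  run_config(
    n = x$n,
    params = model_params(x$params$A, x$params$R, x$params$S,
                          x$params$time_unit),
    integrator = integrator_config(x$integrator$dt,
                                   x$integrator$cfl_warn_threshold),
    noise = if (is.null(x$noise)) NULL else
      noise_spec(x$noise$D, x$noise$duration, x$noise$seed),
    protocol = x$protocol,
    protocol_params = x$protocol_params,
    seed = x$seed,
    out = x$out)
}

#' Save and load trajectories
#'
#' Trajectories are written as a plain-text directory container:
#' \code{meta.json} (parameters, configuration, seeds, package version,
#' configuration hash, time stamps), \code{diagnostics.csv},
#' \code{theta.csv} (final field) and \code{snapshots/snap_NNNN.csv}.
#'
#' @param traj An \code{an_trajectory}.
#' @param dir Target directory (created; must not already contain a
#'   trajectory unless \code{overwrite = TRUE}).
#' @param overwrite Replace an existing container.
#' @return \code{dir}, invisibly; \code{load_trajectory} returns the
#'   reconstructed \code{an_trajectory}.
#' @export
save_trajectory <- function(traj, dir, overwrite = FALSE) {
  stopifnot(inherits(traj, "an_trajectory"))
  if (file.exists(file.path(dir, "meta.json")) && !overwrite) {
    stop("directory already holds a trajectory; use overwrite = TRUE")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(list(
    params = traj$params[c("A", "R", "S", "time_unit")],
    n = traj$grid$n,
    integrator = traj$config[c("dt", "cfl_warn_threshold")],
    noise = if (is.null(traj$noise)) NULL else
      traj$noise[c("D", "duration", "seed")]),
    auto_unbox = TRUE, digits = NA, null = "null")
  meta <- list(
    package_version = as.character(utils::packageVersion("activenematic")),
    config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE),
    config_hash = config_hash(cfg_json),
    seed = traj$seed,
    t_final = traj$t_final,
    cfl_max = traj$cfl_max,
    time_unit_times = traj$time_unit_times,
    time_unit_values = traj$time_unit_values,
    state_time = traj$state$time,
    snapshot_times = traj$snapshot_times)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(traj$diagnostics, file.path(dir, "diagnostics.csv"),
                   row.names = FALSE)
  write_matrix_csv(traj$state$theta, file.path(dir, "theta.csv"))
  if (length(traj$snapshots)) {
    dir.create(file.path(dir, "snapshots"), showWarnings = FALSE)
    for (i in seq_along(traj$snapshots)) {
      write_matrix_csv(traj$snapshots[[i]],
                       file.path(dir, "snapshots",
                                 sprintf("snap_%04d.csv", i)))
    }
  }
  invisible(dir)
}

#' @rdname save_trajectory
#' @export
load_trajectory <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  cfg <- meta$config
  params <- model_params(cfg$params$A, cfg$params$R, cfg$params$S,
                         cfg$params$time_unit)
  grid <- make_grid(cfg$n)
  snaps <- list()
  snap_dir <- file.path(dir, "snapshots")
  if (dir.exists(snap_dir)) {
    files <- sort(list.files(snap_dir, full.names = TRUE))
    snaps <- lapply(files, read_matrix_csv)
  }
  structure(list(
    state = director_field(read_matrix_csv(file.path(dir, "theta.csv")),
                           time = meta$state_time,
                           time_unit = meta$time_unit_values),
    diagnostics = utils::read.csv(file.path(dir, "diagnostics.csv")),
    snapshots = snaps,
    snapshot_times = if (length(meta$snapshot_times)) meta$snapshot_times
                     else numeric(0),
    params = params, grid = grid,
    config = integrator_config(cfg$integrator$dt,
                               cfg$integrator$cfl_warn_threshold),
    noise = if (is.null(cfg$noise)) NULL else
      noise_spec(cfg$noise$D, cfg$noise$duration, cfg$noise$seed),
    seed = meta$seed, cfl_max = meta$cfl_max, t_final = meta$t_final,
    time_unit_times = meta$time_unit_times,
    time_unit_values = meta$time_unit_values),
    class = "an_trajectory")
}

write_matrix_csv <- function(m, path) {
  data.table::fwrite(data.table::as.data.table(m), path)
}

read_matrix_csv <- function(path) {
  unname(as.matrix(data.table::fread(path)))
}

config_hash <- function(json_string) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(json_string), tf)
  unname(tools::md5sum(tf))
}
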