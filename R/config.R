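#' Simulation configuration
#'
#' One serializable record of everything a run needs: model parameters,
#' grid, initial-condition recipe, forcing, sampling plan, seed and mode
#' flags. Configurations round-trip losslessly through YAML
#' ([save_config()] / [load_config()]) and every [run_preset()] writes its
#' resolved configuration beside its outputs, so a run directory is
#' sufficient to reproduce the run bit-for-bit.
#'
#' @param params Named list of [model_params()] overrides.
#' @param grid Named list of [grid_spec()] overrides.
#' @param init List describing the recipe: `kind` one of `"stripe_seed"`,
#'   `"homogeneous"`, `"from_checkpoint"` plus the kind's payload.
#' @param forcing List with `radiation` (list of source lists), `noise`
#'   (list of patch lists) and `noise_mode`.
#' @param snapshot_times Times at which to keep full snapshots.
#' @param monitor List (or matrix) of 1-based `(row, col)` nodes.
#' @param stride Series stride in steps.
#' @param mode `"induction"` or `"baseline"`.
#' @param seed Integer seed or `NULL`.
#' @param develop Time to pre-integrate without forcing before the drives
#'   switch on (two-phase protocols; 0 = none). Counted within `duration`.
#' @return An object of class `fhn_config` (a named list).
#' @export
sim_config <- function(params = list(), grid = list(), init = list(),
                       forcing = list(), snapshot_times = numeric(),
                       monitor = NULL, stride = 1L, mode = "induction",
                       seed = NULL, develop = 0) {
  cfg <- list(params = params, grid = grid,
              init = if (length(init) == 0) list(kind = "stripe_seed")
                     else init,
              forcing = forcing, snapshot_times = snapshot_times,
              monitor = monitor, stride = stride, mode = mode,
              seed = seed, develop = develop)
  validate_config(cfg)
}

.cfg_keys <- c("params", "grid", "init", "forcing", "snapshot_times",
               "monitor", "stride", "mode", "seed", "develop", "preset")

validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), .cfg_keys)
  if (length(unknown) > 0)
    abort(paste0("unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")))
  bad_par <- setdiff(names(cfg$params), names(formals(model_params)))
  if (length(bad_par) > 0)
    abort(paste0("unknown params key(s): ", paste(bad_par, collapse = ", ")))
  bad_grid <- setdiff(names(cfg$grid), names(formals(grid_spec)))
  if (length(bad_grid) > 0)
    abort(paste0("unknown grid key(s): ", paste(bad_grid, collapse = ", ")))
  if (!is.null(cfg$grid$h) && cfg$grid$h <= 0)
    abort("invalid value for `h`: must be > 0")
  if (!is.null(cfg$develop) && cfg$develop < 0)
    abort("invalid value for `develop`: must be >= 0")
  if (!is.null(cfg$mode) &&
      !cfg$mode %in% c("induction", "baseline", "diffusion"))
    abort("invalid value for `mode`")
  # constructors re-validate every numeric field and name the offender
  do.call(model_params, cfg$params)
  do.call(grid_spec, cfg$grid %||% list())
  structure(cfg, class = "fhn_config")
}

# Turn the plain-list config into live objects.
resolve_config <- function(cfg) {
  cfg <- validate_config(unclass(cfg))
  params <- do.call(model_params, cfg$params)
  grid <- do.call(grid_spec, cfg$grid %||% list())
  init <- switch(cfg$init$kind %||% "stripe_seed",
    stripe_seed = stripe_recipe(),
    homogeneous = homogeneous_recipe(cfg$init$u %||% 0, cfg$init$v %||% 0,
                                     cfg$init$phi %||% 0),
    from_checkpoint = checkpoint_recipe(cfg$init$path),
    abort(paste0("unknown init kind: ", cfg$init$kind)))
  rad <- purrr::map(cfg$forcing$radiation %||% list(), function(s)
    do.call(radiation_source, s))
  noi <- purrr::map(cfg$forcing$noise %||% list(), function(s)
    do.call(noise_patch, s))
  forcing <- forcing_spec(rad, noi, cfg$forcing$noise_mode %||% "em")
  monitor <- cfg$monitor
  if (!is.null(monitor) && !is.matrix(monitor))
    monitor <- matrix(as.integer(unlist(monitor)), ncol = 2L, byrow = TRUE)
  list(cfg = cfg, params = params, grid = grid, init = init,
       forcing = forcing, monitor = monitor)
}

#' Save / load a configuration as YAML
#'
#' The on-disk dialect is YAML with exactly the keys of [sim_config()];
#' unknown keys are rejected on load with the offending name. A file may
#' instead (or additionally) name a `preset:`, whose fields are resolved
#' first and then overridden by any other keys present.
#'
#' @param cfg An `fhn_config`.
#' @param path File path.
#' @return `load_config()` returns the validated `fhn_config`.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "fhn_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no configuration file at ", path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) abort(paste0("cannot parse ", path,
                                                   ": ", conditionMessage(e))))
  if (!is.list(raw)) abort("configuration must be a YAML mapping")
  if (!is.null(raw$preset)) {
    base <- unclass(experiment_preset(raw$preset))
    raw$preset <- NULL
    raw <- modifyList(base, raw)
  }
  defaults <- unclass(sim_config())
  validate_config(modifyList(defaults, raw))
}

#' Run a configuration
#'
#' Executes the full pipeline a configuration describes: resolves it,
#' integrates (in two phases when `develop > 0`: the drives are off
#' during development and switch on afterwards), and computes
#' [pattern_metrics()] for every snapshot and the final state.
#'
#' @param cfg An `fhn_config` (see [sim_config()], [experiment_preset()]).
#' @param duration Override of `grid$duration`.
#' @return List with `run` (`fhn_run`), `metrics` (tibble, one row per
#'   snapshot plus the final state), `summary` (list: classification and
#'   headline numbers), and `config`.
#' @export
run_config <- function(cfg, duration = NULL) {
  rc <- resolve_config(cfg)
  duration <- duration %||% rc$grid$duration
  dev <- rc$cfg$develop %||% 0
  if (dev > 0 && dev < duration) {
    snaps1 <- rc$cfg$snapshot_times[rc$cfg$snapshot_times <= dev]
    snaps2 <- rc$cfg$snapshot_times[rc$cfg$snapshot_times > dev]
    if (!is.null(rc$cfg$seed)) set.seed(rc$cfg$seed)
    r1 <- simulate_media(rc$init, rc$params, rc$grid, forcing = NULL,
                         duration = dev, snapshot_times = snaps1,
                         monitor = rc$monitor, stride = rc$cfg$stride,
                         mode = rc$cfg$mode)
    r2 <- simulate_media(r1$final, rc$params, rc$grid, forcing = rc$forcing,
                         duration = duration - dev, snapshot_times = snaps2,
                         monitor = rc$monitor, stride = rc$cfg$stride,
                         mode = rc$cfg$mode)
    run <- r2
    run$snapshots <- c(r1$snapshots, r2$snapshots)
    run$series <- dplyr::bind_rows(r1$series,
                                   dplyr::filter(r2$series,
                                                 .data$t > max(r1$series$t)))
    run$duration <- duration
    run$n_steps <- r1$n_steps + r2$n_steps
    run$seed <- rc$cfg$seed
  } else {
    run <- simulate_media(rc$init, rc$params, rc$grid, forcing = rc$forcing,
                          duration = duration,
                          snapshot_times = rc$cfg$snapshot_times,
                          monitor = rc$monitor, stride = rc$cfg$stride,
                          mode = rc$cfg$mode, seed = rc$cfg$seed)
  }
  transient <- 0.5 * duration
  states <- c(run$snapshots, list(final = run$final))
  metrics <- purrr::map_dfr(states, pattern_metrics, series = run$series,
                            transient = transient, .id = "snapshot")
  fin <- metrics[nrow(metrics), ]
  label <- classify_pattern(fin$spatial_std_u, fin$n_singularities)
  node_label <- classify_activity(
    detect_peaks(run$series, transient = transient),
    dplyr::filter(run$series, .data$t >= transient))
  list(run = run, metrics = metrics,
       summary = list(pattern = label, node_activity = node_label,
                      spatial_std_u = fin$spatial_std_u,
                      n_singularities = fin$n_singularities,
                      t_final = fin$t),
       config = rc$cfg)
}

#' Classify a spatial pattern from its metrics
#'
#' Maps the two pattern metrics to the qualitative classes used in the
#' experiment summaries: `"suppressed"` (near-homogeneous media,
#' `spatial_std_u < std_floor`), `"spiral"` (1 to `max_spiral_cores`
#' singularities), `"broken"` (more cores than that: breakup/turbulence),
#' `"patterned"` otherwise (heterogeneous but core-free, e.g. plane
#' waves).
#'
#' @param spatial_std_u Spatial standard deviation of the `u` field.
#' @param n_singularities Phase-singularity count.
#' @param std_floor Homogeneity threshold (default 0.05).
#' @param max_spiral_cores Largest core count still called a (multi-armed)
#'   spiral rather than breakup (default 3).
#' @return A classification string.
#' @export
classify_pattern <- function(spatial_std_u, n_singularities,
                             std_floor = 0.05, max_spiral_cores = 3L) {
  if (spatial_std_u < std_floor) return("suppressed")
  if (n_singularities >= 1 && n_singularities <= max_spiral_cores)
    return("spiral")
  if (n_singularities > max_spiral_cores) return("broken")
  "patterned"
}
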