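# Experiment presets: each encodes the parameter set of one canonical
# numerical experiment. The shared base is the spiral regime k0 = 0.1,
# k1 = 0.5, k2 = 1, alpha = 1, beta = 2 on the 200 x 200 / L = 350 grid
# with h = 0.03 and the stripe (wedge) seed.
.presets <- list(
  # stable spiral development; snapshots at t = 10, 60, 100, 200
  fig3 = function() sim_config(
    params = list(k0 = 0.1),
    grid = list(duration = 200),
    snapshot_times = c(10, 60, 100, 200)),
  # larger feedback gain magnetizes the media to a homogeneous state
  fig3_suppress = function() sim_config(
    params = list(k0 = 0.9),
    grid = list(duration = 200),
    snapshot_times = c(10, 60, 100, 200)),
  # small flux-leak gain: spiral seeds break up, media turns turbulent
  fig7 = function() sim_config(
    params = list(k0 = 0.1, k2 = 0.15),
    grid = list(duration = 200),
    snapshot_times = c(10, 60, 100, 200)),
  # large flux-leak gain: standing perfect spiral
  fig8 = function() sim_config(
    params = list(k0 = 0.1, k2 = 3.0),
    grid = list(duration = 200),
    snapshot_times = c(10, 60, 100, 200)),
  # small flux-drive gain: excitable media, waves survive
  fig10 = function() sim_config(
    params = list(k0 = 0.1, k1 = 0.2, k2 = 1.0),
    grid = list(duration = 200),
    snapshot_times = c(10, 60, 100, 200)),
  # local static radiation A exp(-m r) centered at (84, 84)
  fig11 = function() sim_config(
    params = list(k0 = 0.1, k2 = 1.6),
    grid = list(duration = 800),
    forcing = list(radiation = list(list(A = 12, m = 0.06,
                                         x0 = 84, y0 = 84))),
    snapshot_times = c(10, 120, 600, 800)),
  # disk-confined Gaussian white noise from the stripe seed
  fig12 = function() sim_config(
    params = list(k0 = 0.1, k2 = 1.6),
    grid = list(duration = 800),
    forcing = list(noise = list(list(D = 9, x0 = 60, y0 = 60, radius = 40)),
                   noise_mode = "naive"),
    snapshot_times = c(10, 60, 120, 200, 400, 800),
    seed = 1L),
  # noise applied only after a 200-unit spiral development phase
  fig14 = function() sim_config(
    params = list(k0 = 0.1, k2 = 1.6),
    grid = list(duration = 800),
    forcing = list(noise = list(list(D = 9, x0 = 60, y0 = 60, radius = 40)),
                   noise_mode = "naive"),
    snapshot_times = c(10, 100, 200, 300, 400, 800),
    develop = 200, seed = 1L),
  # gain scans for bifurcation diagrams at node (100, 100)
  fig2_scan = function() sim_config(params = list(),
                                    grid = list(duration = 200)),
  fig4_scan = function() sim_config(params = list(k0 = 0.1),
                                    grid = list(duration = 200)),
  fig9_scan = function() sim_config(params = list(k0 = 0.1, k2 = 1.0),
                                    grid = list(duration = 200))
)

.scan_presets <- list(
  fig2_scan = list(param = "k0", values = seq(0.1, 1.0, by = 0.1)),
  fig4_scan = list(param = "k2", values = c(0.1, 0.15, 0.2, 0.5, 1.0,
                                            1.6, 2.0, 3.0)),
  fig9_scan = list(param = "k1", values = c(0.2, 0.7, 1.2, 1.6, 2.2, 2.7))
)

#' Experiment presets
#'
#' `preset_names()` lists the available one-command experiments;
#' `experiment_preset()` returns the configuration a preset encodes,
#' optionally with overrides (overrides win on colliding fields; two
#' override lists touching the same field are an error, so composition is
#' order-independent).
#'
#' Available presets: `fig3` (spiral formation, `k0 = 0.1`),
#' `fig3_suppress` (`k0 = 0.9`; pass `list(params = list(k0 = 0.4))` for
#' the milder case), `fig7` (breakup at `k2 = 0.15`), `fig8` (standing
#' spiral at `k2 = 3`), `fig10` (`k1 = 0.2`), `fig11` (static radiation,
#' `A = 12`, `m = 0.06`, center (84, 84), `k2 = 1.6`), `fig12`
#' (disk noise `D = 9`, radius 40 at (60, 60)), `fig14` (the same noise
#' applied to a spiral pre-developed for 200 time units), and the scans
#' `fig2_scan` (`k0`), `fig4_scan` (`k2`), `fig9_scan` (`k1`).
#'
#' @param name Preset name.
#' @param ... Named override lists merged into the preset configuration
#'   (e.g. `grid = list(n_rows = 60)`).
#' @return An `fhn_config`.
#' @export
experiment_preset <- function(name, ...) {
  if (!name %in% names(.presets))
    abort(paste0("unknown preset: ", name, "; see preset_names()"))
  cfg <- unclass(.presets[[name]]())
  ov <- list(...)
  if (length(ov) > 0) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      abort("preset overrides must be named")
    dup <- names(ov)[duplicated(names(ov))]
    if (length(dup) > 0)
      abort(paste0("colliding overrides for: ", paste(dup, collapse = ", ")))
    cfg <- modifyList(cfg, ov)
  }
  validate_config(cfg)
}

#' @rdname experiment_preset
#' @export
preset_names <- function() names(.presets)

#' Run an experiment preset
#'
#' Executes a preset end to end. Simulation presets run [run_config()]
#' (snapshots at the preset's times, node series, [pattern_metrics()] per
#' snapshot, machine-readable summary); scan presets run
#' [bifurcation_scan()] over their gain. With `out_dir` set, everything a
#' reproduction needs is written there: the resolved configuration
#' (`config.yaml`), node series (`series.csv`), per-snapshot metrics
#' (`metrics.csv`), summary (`summary.json`), final-state checkpoint
#' (`final.rds`) and a run log.
#'
#' @param name Preset name (see [experiment_preset()]).
#' @param ... Overrides forwarded to [experiment_preset()].
#' @param out_dir Optional output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return For simulation presets the [run_config()] result; for scan
#'   presets a list with the `fhn_bifurcation` table. Both carry
#'   `out_dir` when outputs were written.
#' @export
run_preset <- function(name, ..., out_dir = NULL, quiet = TRUE) {
  cfg <- experiment_preset(name, ...)
  t0 <- Sys.time()
  if (name %in% names(.scan_presets)) {
    sp <- .scan_presets[[name]]
    rc <- resolve_config(cfg)
    scan <- bifurcation_scan(sp$param, sp$values, rc$params, rc$grid,
                             rc$init, node = rc$monitor,
                             mode = rc$cfg$mode, seed = rc$cfg$seed)
    res <- list(scan = scan, config = unclass(cfg))
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      save_config(cfg, file.path(out_dir, "config.yaml"))
      write.csv(tidy(scan), file.path(out_dir, "peaks.csv"),
                row.names = FALSE)
      write.csv(dplyr::select(tibble::as_tibble(scan), -"peaks"),
                file.path(out_dir, "scan.csv"), row.names = FALSE)
      res$out_dir <- out_dir
    }
  } else {
    res <- run_config(cfg)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      save_config(cfg, file.path(out_dir, "config.yaml"))
      write.csv(res$run$series, file.path(out_dir, "series.csv"),
                row.names = FALSE)
      write.csv(res$metrics, file.path(out_dir, "metrics.csv"),
                row.names = FALSE)
      jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
      save_checkpoint(res$run$final, file.path(out_dir, "final.rds"))
      for (nm in names(res$run$snapshots))
        render_snapshot(res$run$snapshots[[nm]]$u,
                        file.path(out_dir, paste0("u_", gsub("[^0-9a-zA-Z.]",
                                                             "_", nm),
                                                  ".png")))
      res$out_dir <- out_dir
    }
  }
  if (!quiet)
    message(sprintf("preset %s done in %.1f s", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  if (!is.null(out_dir))
    writeLines(sprintf("preset=%s elapsed_s=%.2f finished=%s", name,
                       as.numeric(difftime(Sys.time(), t0, units = "secs")),
                       format(Sys.time())),
               file.path(out_dir, "run.log"))
  res
}
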