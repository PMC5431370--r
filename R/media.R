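#' Five-point Laplacian with no-flux (mirror-ghost) boundary
#'
#' Discrete Laplacian `(up + down + left + right - 4 * center) / dx^2`
#' where a neighbour beyond the edge is a mirror ghost carrying the edge
#' value itself, so the normal gradient vanishes at the boundary and no
#' flux leaves the tissue. With the reaction switched off this stencil
#' conserves the lattice sum of the field exactly (up to round-off).
#'
#' @param field Numeric matrix, at least 3 x 3.
#' @param dx Node spacing used in the denominator.
#' @return Matrix of the same shape.
#' @examples
#' laplacian_noflux(matrix(1, 4, 4))        # all zero
#' @export
laplacian_noflux <- function(field, dx = 1) {
  nr <- nrow(field); nc <- ncol(field)
  if (is.null(nr) || nr < 3L || nc < 3L) abort("field must be at least 3 x 3")
  up <- field[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- field[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  lf <- field[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- field[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  (up + dn + lf + rt - 4 * field) / dx^2
}

#' Advance the media by one Euler-forward step
#'
#' One synchronous explicit update of all three fields:
#' `u <- u + h * (rate_u + D_u * laplacian_noflux(u))`,
#' `v <- v + h * rate_v`, and
#' `phi <- phi + h * (k1 u - k2 phi + forcing) + noise`,
#' where `forcing` is a per-node deterministic flux drive and `noise` an
#' optional additive increment lattice applied outside the `h *` product
#' (the Euler-Maruyama convention; see [noise_increment()]).
#'
#' This is the reference R implementation of the update; [simulate_media()]
#' runs the identical scheme in compiled code. `mode = "diffusion"` is a
#' test hook that disables the reaction entirely, leaving pure diffusion
#' of `u`.
#'
#' @param state An [media_state()].
#' @param params An [model_params()].
#' @param grid An [grid_spec()] (supplies `h` and `dx`).
#' @param forcing Optional deterministic flux-drive matrix.
#' @param noise Optional additive flux-increment matrix.
#' @param mode `"induction"`, `"baseline"`, or `"diffusion"`.
#' @param guard,blowup Domain-error band for the recovery rate and the
#'   divergence abort threshold (see [integrate_cell()]).
#' @return The updated [media_state()] with `t` advanced by `h`.
#' @export
media_step <- function(state, params = model_params(), grid = grid_spec(),
                       forcing = NULL, noise = NULL,
                       mode = c("induction", "baseline", "diffusion"),
                       guard = 1e-12, blowup = 1e6) {
  mode <- match.arg(mode)
  stopifnot(inherits(state, "fhn_media"))
  u <- state$u; v <- state$v; phi <- state$phi
  h <- grid$h
  if (!is.null(forcing) && !identical(dim(forcing), dim(u)))
    abort("forcing lattice shape does not match the grid")
  if (!is.null(noise) && !identical(dim(noise), dim(u)))
    abort("noise increment lattice shape does not match the grid")
  if (mode == "diffusion") {
    u_new <- u + h * (params$D_u * laplacian_noflux(u, grid$dx))
    v_new <- v
    phi_new <- phi
  } else {
    du <- rate_u(u, v, phi, params, mode) +
      params$D_u * laplacian_noflux(u, grid$dx)
    dv <- rate_v(u, v, params, guard)
    dp <- rate_phi(u, phi, params, forcing %||% 0)
    u_new <- u + h * du
    v_new <- v + h * dv
    phi_new <- phi + h * dp
  }
  if (!is.null(noise)) phi_new <- phi_new + noise
  m <- max(abs(u_new), abs(v_new), abs(phi_new))
  if (!is.finite(m) || m > blowup)
    abort(sprintf("state diverged (max |state| = %g) at t = %g",
                  m, state$t + h))
  media_state(u_new, v_new, phi_new, t = state$t + h)
}

#' Simulate the media
#'
#' Integrates the full lattice model with the Euler-forward scheme and
#' no-flux boundary, emitting field snapshots at requested times and a
#' per-step (or strided) time series at monitored nodes. Requested
#' snapshot times are mapped to the nearest integer step (with `h = 0.03`
#' neither 10 nor 200 is an exact multiple). With `seed` set, stochastic
#' forcing is reproducible bit-for-bit; the noise draws come from R's RNG
#' stream, one per in-region node per step in fixed order.
#'
#' @param init An `fhn_recipe` (see [stripe_recipe()]) or an existing
#'   [media_state()] (e.g. a loaded checkpoint) to continue from.
#' @param params An [model_params()].
#' @param grid An [grid_spec()]; `grid$h` is the step and `grid$duration`
#'   the default run length.
#' @param forcing An [forcing_spec()], a single [radiation_source()] /
#'   [noise_patch()], or `NULL` for the closed model.
#' @param duration Simulated time; defaults to `grid$duration`.
#' @param snapshot_times Numeric vector of times at which to keep full
#'   `(u, v, phi)` snapshots (always includes the final state).
#' @param monitor Integer matrix or vector of 1-based `(row, col)` node
#'   coordinates to record each step; default node `(100, 100)` scaled to
#'   the grid.
#' @param stride Series recording stride in steps.
#' @param mode Integration mode, see [media_step()].
#' @param seed Optional integer seed applied before the run.
#' @param guard,blowup See [media_step()].
#' @return An object of class `fhn_run`: list with `final`
#'   ([media_state()]), `snapshots` (list of media states), `series`
#'   (tibble `t, row, col, u, v, phi`), and the resolved settings.
#' @examples
#' run <- simulate_media(stripe_recipe(), model_params(),
#'                       grid_spec(n_rows = 50, n_cols = 50, duration = 5))
#' run$final
#' @export
simulate_media <- function(init = stripe_recipe(), params = model_params(),
                           grid = grid_spec(), forcing = NULL,
                           duration = NULL, snapshot_times = numeric(),
                           monitor = NULL, stride = 1L,
                           mode = c("induction", "baseline", "diffusion"),
                           seed = NULL, guard = 1e-12, blowup = 1e6) {
  mode <- match.arg(mode)
  duration <- duration %||% grid$duration
  state <- initial_state(init, grid)
  if (!is.null(seed)) set.seed(seed)
  n_steps <- as.integer(round(duration / grid$h))
  if (n_steps < 1L) abort("`duration` must cover at least one step")

  if (is.null(monitor)) {
    monitor <- matrix(c(max(1L, round(100 * grid$n_rows / 200)),
                        max(1L, round(100 * grid$n_cols / 200))), 1L)
  }
  monitor <- matrix(as.integer(monitor), ncol = 2L)
  if (any(monitor[, 1] < 1L) || any(monitor[, 1] > grid$n_rows) ||
      any(monitor[, 2] < 1L) || any(monitor[, 2] > grid$n_cols))
    abort("monitored node outside the grid")

  fspec <- as_forcing_spec(forcing)
  fc <- compile_forcing(fspec, grid)

  snap_steps <- sort(unique(pmin(n_steps, pmax(0L, as.integer(
    round(snapshot_times / grid$h))))))

  res <- tryCatch(
    cpp_simulate(state$u, state$v, state$phi, state$t, par_vec(params),
                 grid$dx, grid$h, n_steps, .mode_code(mode),
                 fc$deterministic, fc$noise_cells, fc$noise_sd, NULL,
                 snap_steps, monitor[, 1] - 1L, monitor[, 2] - 1L,
                 as.integer(stride), guard, blowup),
    error = function(e) {
      abort(paste0("simulation failed: ", conditionMessage(e)))
    })

  snaps <- purrr::pmap(
    list(res$snap_u, res$snap_v, res$snap_phi, res$snap_t),
    function(u, v, p, t) media_state(u, v, p, t))
  names(snaps) <- sprintf("t=%g", res$snap_t)

  nm <- nrow(monitor)
  ser <- res$series
  series <- purrr::map_dfr(seq_len(nm), function(m) {
    tibble::tibble(t = ser[, 1], row = monitor[m, 1], col = monitor[m, 2],
                   u = ser[, 1 + 3 * (m - 1) + 1],
                   v = ser[, 1 + 3 * (m - 1) + 2],
                   phi = ser[, 1 + 3 * (m - 1) + 3])
  })

  structure(list(
    final = media_state(res$u, res$v, res$phi, t = res$t),
    snapshots = snaps,
    series = series,
    params = params, grid = grid, forcing = fspec, mode = mode,
    duration = duration, n_steps = n_steps, monitor = monitor,
    seed = seed, stride = as.integer(stride)
  ), class = "fhn_run")
}

#' @export
print.fhn_run <- function(x, ...) {
  cat("<fhn_run> ", x$n_steps, " steps of h =", x$grid$h, " (t =",
      signif(x$final$t, 6), "), mode =", x$mode, "\n")
  cat("  grid ", x$grid$n_rows, "x", x$grid$n_cols, "; ",
      length(x$snapshots), " snapshots; ", nrow(x$monitor),
      " monitored node(s)\n", sep = "")
  invisible(x)
}

#' Checkpoint a media state to disk
#'
#' Lossless, version-stamped round-trip of the three fields and the
#' current time, for two-phase protocols (develop a spiral, then perturb
#' it) and for resuming long runs.
#'
#' @param state An [media_state()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(state, path) {
  stopifnot(inherits(state, "fhn_media"))
  obj <- list(container = "memfhn_checkpoint", version = 1L,
              n_rows = nrow(state$u), n_cols = ncol(state$u),
              u = state$u, v = state$v, phi = state$phi, t = state$t)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param grid Optional [grid_spec()] the checkpoint must match; a shape
#'   mismatch is an error.
#' @return `load_checkpoint()` returns the restored [media_state()].
#' @export
load_checkpoint <- function(path, grid = NULL) {
  if (!file.exists(path)) abort(paste0("no checkpoint at ", path))
  obj <- tryCatch(readRDS(path),
                  error = function(e) abort(paste0("corrupt checkpoint: ",
                                                   conditionMessage(e))))
  if (!is.list(obj) || !identical(obj$container, "memfhn_checkpoint"))
    abort("file is not a memfhn checkpoint")
  if (!is.null(grid) &&
      (obj$n_rows != grid$n_rows || obj$n_cols != grid$n_cols))
    abort(sprintf("checkpoint shape %d x %d does not match grid %d x %d",
                  obj$n_rows, obj$n_cols, grid$n_rows, grid$n_cols))
  media_state(obj$u, obj$v, obj$phi, t = obj$t)
}
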