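#' External drives on the magnetic-flux field
#'
#' `radiation_source()` describes a static, localized electromagnetic
#' radiation profile `A * exp(-m * r)`, `r` the Euclidean distance to the
#' center `(x0, y0)`: an additive deterministic drive on the flux
#' equation. `noise_patch()` describes Gaussian white noise of intensity
#' `D` confined to the disk of given `radius` around `(x0, y0)`
#' (`radius = Inf` covers the whole media). `forcing_spec()` composes any
#' number of each; empty lists mean zero forcing. All drives act on the
#' flux equation only, never directly on `u` or `v`.
#'
#' Centers and radii are in node-index units by default (`units =
#' "node"`, matching centers like (84,84) and radius 40 on a 200 x 200
#' lattice); `units = "physical"` interprets them in the physical
#' coordinates `index * dx` instead.
#'
#' @param A Radiation amplitude.
#' @param m Spatial decay (gradient) factor, >= 0.
#' @param x0,y0 Center of the exposed area, `(row, col)` order.
#' @param units `"node"` (default) or `"physical"`.
#' @return `radiation_source()`, `noise_patch()` and `forcing_spec()`
#'   return objects of class `fhn_radiation`, `fhn_noise` and
#'   `fhn_forcing` respectively.
#' @examples
#' fs <- forcing_spec(radiation = list(radiation_source()),
#'                    noise = list(noise_patch()))
#' @export
radiation_source <- function(A = 12, m = 0.06, x0 = 84, y0 = 84,
                             units = c("node", "physical")) {
  units <- match.arg(units)
  if (m < 0) abort("`m` must be >= 0")
  structure(list(A = A, m = m, x0 = x0, y0 = y0, units = units),
            class = "fhn_radiation")
}

#' @rdname radiation_source
#' @param D Noise intensity (>= 0); the per-step flux increment is
#'   `sqrt(2 * D * h) * N(0, 1)` per in-disk node under the default
#'   Euler-Maruyama discretization.
#' @param radius Disk radius (>= 0); `Inf` applies noise uniformly.
#' @export
noise_patch <- function(D = 9, x0 = 60, y0 = 60, radius = 40,
                        units = c("node", "physical")) {
  units <- match.arg(units)
  if (D < 0) abort("`D` must be >= 0")
  if (radius < 0) abort("`radius` must be >= 0")
  structure(list(D = D, x0 = x0, y0 = y0, radius = radius, units = units),
            class = "fhn_noise")
}

#' @rdname radiation_source
#' @param radiation List of [radiation_source()] objects.
#' @param noise List of [noise_patch()] objects.
#' @param noise_mode Noise discretization: `"em"` (Euler-Maruyama, per-step
#'   increment sd `sqrt(2 D h)`; the standard additive-white-noise
#'   convention and the default here) or `"naive"` (increment sd `h * D`,
#'   a pattern common in older excitable-media codes). Caution: at the
#'   canonical noise intensity `D = 9` with `h = 0.03` and `k2 = 1.6` the
#'   `"em"` convention drives the flux far enough that the memductance
#'   feedback exceeds the explicit-Euler stability limit and the run
#'   diverges; the shipped noise presets therefore use `"naive"`, which
#'   stays bounded (see the methods vignette).
#' @export
forcing_spec <- function(radiation = list(), noise = list(),
                         noise_mode = c("em", "naive")) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(all(vapply(radiation, inherits, logical(1), "fhn_radiation")),
            all(vapply(noise, inherits, logical(1), "fhn_noise")))
  structure(list(radiation = radiation, noise = noise,
                 noise_mode = noise_mode), class = "fhn_forcing")
}

# Normalize NULL / single source / spec into an fhn_forcing.
as_forcing_spec <- function(x) {
  if (is.null(x)) return(forcing_spec())
  if (inherits(x, "fhn_forcing")) return(x)
  if (inherits(x, "fhn_radiation")) return(forcing_spec(radiation = list(x)))
  if (inherits(x, "fhn_noise")) return(forcing_spec(noise = list(x)))
  abort("forcing must be an fhn_forcing, fhn_radiation, fhn_noise or NULL")
}

# Node coordinates (row i, col j, 1-based) in the units of a source.
.node_coords <- function(grid, units) {
  i <- matrix(seq_len(grid$n_rows), grid$n_rows, grid$n_cols)
  j <- matrix(seq_len(grid$n_cols), grid$n_rows, grid$n_cols, byrow = TRUE)
  if (units == "physical") {
    dx <- grid$L / grid$n_rows
    list(x = i * dx, y = j * (grid$L / grid$n_cols))
  } else {
    list(x = i, y = j)
  }
}

.dist_to <- function(grid, x0, y0, units) {
  co <- .node_coords(grid, units)
  sqrt((co$x - x0)^2 + (co$y - y0)^2)
}

#' Radiation profile lattice
#'
#' Evaluates `A * exp(-m * r)` at every node, `r` the distance from the
#' source center. Time-independent; radially monotone non-increasing.
#'
#' @param source An [radiation_source()].
#' @param grid An [grid_spec()].
#' @return Numeric matrix of per-node flux drive.
#' @examples
#' pr <- radiation_profile(radiation_source(A = 12, m = 0.06), grid_spec())
#' pr[84, 84] # the amplitude, r = 0
#' @export
radiation_profile <- function(source, grid = grid_spec()) {
  stopifnot(inherits(source, "fhn_radiation"))
  r <- .dist_to(grid, source$x0, source$y0, source$units)
  source$A * exp(-source$m * r)
}

#' Disk mask of a noise patch
#'
#' @param patch An [noise_patch()].
#' @param grid An [grid_spec()].
#' @return Logical matrix, `TRUE` on nodes with distance <= radius.
#' @export
noise_mask <- function(patch, grid = grid_spec()) {
  stopifnot(inherits(patch, "fhn_noise"))
  .dist_to(grid, patch$x0, patch$y0, patch$units) <= patch$radius
}

# Per-step increment standard deviation for a patch under a mode.
.noise_sd <- function(D, h, mode) {
  switch(mode, em = sqrt(2 * D * h), naive = h * D,
         abort(paste0("unknown noise mode: ", mode)))
}

#' One lattice of stochastic flux increments
#'
#' Draws the per-step additive flux increments of a noise patch: each
#' in-disk node receives an independent `sd * N(0, 1)` draw, where `sd =
#' sqrt(2 D h)` under `"em"` (Euler-Maruyama; additive white noise of
#' intensity `D` with correlation `<xi(t) xi(t')> = 2 D delta(t - t')`)
#' or `sd = h * D` under `"naive"`. Nodes outside the disk are exactly
#' zero. Draws come from R's RNG, so `set.seed()` makes them
#' reproducible.
#'
#' @param patch An [noise_patch()].
#' @param grid An [grid_spec()].
#' @param h Time step.
#' @param mode `"em"` or `"naive"`.
#' @return Numeric matrix of increments.
#' @export
noise_increment <- function(patch, grid = grid_spec(), h = grid$h,
                            mode = c("em", "naive")) {
  mode <- match.arg(mode)
  mask <- noise_mask(patch, grid)
  out <- matrix(0, grid$n_rows, grid$n_cols)
  n_in <- sum(mask)
  if (n_in > 0 && patch$D > 0)
    out[mask] <- .noise_sd(patch$D, h, mode) * rnorm(n_in)
  out
}

#' Compose all drives for one step
#'
#' Sums the (time-independent, cacheable) radiation profiles and draws one
#' lattice of stochastic increments from all noise patches. The integrator
#' applies `h * (k1 u - k2 phi + deterministic) + stochastic`.
#'
#' @param spec An [forcing_spec()].
#' @param grid An [grid_spec()].
#' @param h Time step for the noise discretization.
#' @return List with matrices `deterministic` and `stochastic`.
#' @export
total_forcing <- function(spec, grid = grid_spec(), h = grid$h) {
  spec <- as_forcing_spec(spec)
  det <- matrix(0, grid$n_rows, grid$n_cols)
  for (src in spec$radiation) det <- det + radiation_profile(src, grid)
  sto <- matrix(0, grid$n_rows, grid$n_cols)
  for (p in spec$noise)
    sto <- sto + noise_increment(p, grid, h, spec$noise_mode)
  list(deterministic = det, stochastic = sto)
}

# Flatten a forcing spec for the C++ kernel: one cached deterministic
# lattice plus (0-based, column-major) noise cell indices with per-cell
# increment sd, ordered patch by patch then by linear index, which fixes
# the RNG draw order.
compile_forcing <- function(spec, grid) {
  spec <- as_forcing_spec(spec)
  det <- NULL
  if (length(spec$radiation) > 0) {
    det <- matrix(0, grid$n_rows, grid$n_cols)
    for (src in spec$radiation) det <- det + radiation_profile(src, grid)
  }
  cells <- integer(0); sds <- numeric(0)
  for (p in spec$noise) {
    if (p$D <= 0) next
    idx <- which(noise_mask(p, grid)) # column-major, ascending
    cells <- c(cells, idx - 1L)
    sds <- c(sds, rep(.noise_sd(p$D, grid$h, spec$noise_mode), length(idx)))
  }
  list(deterministic = det, noise_cells = cells, noise_sd = sds)
}
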