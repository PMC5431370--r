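#' Lattice geometry and integrator settings
#'
#' The media is a rectangular lattice of `n_rows` x `n_cols` nodes covering
#' a square of physical side `L`; the node spacing is `dx = L / n_rows`
#' per axis (the canonical setting is 200 x 200 nodes over side 350, so
#' `dx = 1.75`). Many excitable-media codes instead take the lattice
#' spacing as 1; set `unit_spacing = TRUE` to use `dx = 1` in the Laplacian
#' while keeping the node counts.
#'
#' @param n_rows,n_cols Node counts (>= 3).
#' @param L Physical side length.
#' @param h Euler time step (default 0.03).
#' @param duration Default total simulated time for runs on this grid.
#' @param unit_spacing If `TRUE`, the diffusion stencil uses `dx = 1`
#'   regardless of `L`.
#' @return An object of class `fhn_grid` with fields `n_rows`, `n_cols`,
#'   `L`, `dx`, `h`, `duration`, `unit_spacing`.
#' @examples
#' grid_spec()$dx # 1.75
#' @export
grid_spec <- function(n_rows = 200L, n_cols = 200L, L = 350, h = 0.03,
                      duration = 200, unit_spacing = FALSE) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 3L || n_cols < 3L) abort("grid must be at least 3 x 3")
  if (h <= 0) abort("`h` must be > 0")
  if (L <= 0) abort("`L` must be > 0")
  dx <- if (unit_spacing) 1.0 else L / n_rows
  structure(list(n_rows = n_rows, n_cols = n_cols, L = L, dx = dx, h = h,
                 duration = duration, unit_spacing = unit_spacing),
            class = "fhn_grid")
}

#' @export
print.fhn_grid <- function(x, ...) {
  cat("<fhn_grid> ", x$n_rows, "x", x$n_cols, " nodes, side L =", x$L,
      ", dx =", signif(x$dx, 6), ", h =", x$h, "\n")
  invisible(x)
}

#' Media state: the three fields on the lattice
#'
#' @param u,v,phi Numeric matrices of identical shape: membrane potential,
#'   recovery variable and magnetic flux fields.
#' @param t Current simulation time.
#' @return An object of class `fhn_media`.
#' @export
media_state <- function(u, v, phi, t = 0) {
  if (!is.matrix(u) || !is.matrix(v) || !is.matrix(phi))
    abort("u, v, phi must be matrices")
  if (!identical(dim(u), dim(v)) || !identical(dim(u), dim(phi)))
    abort("u, v, phi must share one grid shape")
  if (!all(is.finite(u)) || !all(is.finite(v)) || !all(is.finite(phi)))
    abort("media state fields must be finite")
  structure(list(u = u, v = v, phi = phi, t = as.numeric(t)),
            class = "fhn_media")
}

#' @export
print.fhn_media <- function(x, ...) {
  cat("<fhn_media> ", nrow(x$u), "x", ncol(x$u), " nodes at t =",
      signif(x$t, 6), "\n")
  cat("  u in [", signif(min(x$u), 4), ",", signif(max(x$u), 4),
      "], spatial sd =", signif(spatial_std(x$u), 4), "\n")
  invisible(x)
}

#' Initial-condition recipes
#'
#' `stripe_recipe()` is the wedge seed that nucleates a spiral: three
#' horizontal bands on a rest background, spanning the left part of the
#' domain so the excitation front is broken and curls. On the canonical
#' 200 x 200 grid the bands are rows 92-97, 98-103 and 104-109 over
#' columns 1-115 (1-based, inclusive), carrying `(u, v, phi)` values
#' `(1, 0, 0)`, `(0.7, 0.6, 0.1)` and `(0, 0.8, 0.2)`; all other nodes are
#' at rest `(0, 0, 0)`. On other grid sizes the band indices are rescaled
#' proportionally (rounded to nodes), preserving the geometry.
#'
#' `homogeneous_recipe()` fills the whole lattice with one constant triple.
#' `checkpoint_recipe()` resumes from a saved state (see
#' [save_checkpoint()]).
#'
#' @param rows Matrix-like list of three integer ranges, one per band
#'   (`NULL` uses the canonical rows above, rescaled to the grid).
#' @param cols Column range shared by the bands (`NULL`: columns 1-115
#'   rescaled).
#' @param values 3 x 3 numeric matrix of band `(u, v, phi)` triples,
#'   one row per band.
#' @return An object of class `fhn_recipe`.
#' @examples
#' initial_state(stripe_recipe(), grid_spec(n_rows = 40, n_cols = 40))
#' @export
stripe_recipe <- function(rows = NULL, cols = NULL,
                          values = rbind(c(1.0, 0.0, 0.0),
                                         c(0.7, 0.6, 0.1),
                                         c(0.0, 0.8, 0.2))) {
  stopifnot(is.matrix(values), nrow(values) == 3L, ncol(values) == 3L)
  structure(list(kind = "stripe_seed", rows = rows, cols = cols,
                 values = values), class = "fhn_recipe")
}

#' @rdname stripe_recipe
#' @param u,v,phi Constant values for the homogeneous fill.
#' @export
homogeneous_recipe <- function(u = 0, v = 0, phi = 0) {
  structure(list(kind = "homogeneous", u = u, v = v, phi = phi),
            class = "fhn_recipe")
}

#' @rdname stripe_recipe
#' @param path Path to a checkpoint written by [save_checkpoint()].
#' @export
checkpoint_recipe <- function(path) {
  structure(list(kind = "from_checkpoint", path = path),
            class = "fhn_recipe")
}

# Canonical stripe geometry on the 200 x 200 reference grid; rescaled
# proportionally to other sizes. 1-based inclusive (row, col) ranges.
.stripe_bands <- function(recipe, grid) {
  ref_rows <- list(c(92L, 97L), c(98L, 103L), c(104L, 109L))
  ref_cols <- c(1L, 115L)
  scale_r <- grid$n_rows / 200
  scale_c <- grid$n_cols / 200
  rows <- recipe$rows %||% lapply(ref_rows, function(r) {
    out <- pmax(1L, pmin(grid$n_rows, as.integer(round(r * scale_r))))
    out
  })
  cols <- recipe$cols %||%
    pmax(1L, pmin(grid$n_cols, as.integer(round(ref_cols * scale_c))))
  if (is.null(recipe$cols)) cols[1] <- 1L
  list(rows = rows, cols = cols)
}

#' Build the initial media state from a recipe
#'
#' @param recipe An `fhn_recipe` (see [stripe_recipe()]); an existing
#'   [media_state()] is passed through (shape-checked against the grid).
#' @param grid An [grid_spec()].
#' @return An [media_state()] at `t = 0` (checkpoints keep their own `t`).
#' @export
initial_state <- function(recipe, grid = grid_spec()) {
  if (inherits(recipe, "fhn_media")) {
    if (nrow(recipe$u) != grid$n_rows || ncol(recipe$u) != grid$n_cols)
      abort("state shape does not match the grid")
    return(recipe)
  }
  stopifnot(inherits(recipe, "fhn_recipe"))
  nr <- grid$n_rows; nc <- grid$n_cols
  switch(recipe$kind,
    homogeneous = media_state(matrix(recipe$u, nr, nc),
                              matrix(recipe$v, nr, nc),
                              matrix(recipe$phi, nr, nc)),
    from_checkpoint = load_checkpoint(recipe$path, grid = grid),
    stripe_seed = {
      u <- matrix(0, nr, nc); v <- matrix(0, nr, nc); phi <- matrix(0, nr, nc)
      b <- .stripe_bands(recipe, grid)
      jj <- b$cols[1]:b$cols[2]
      for (band in 1:3) {
        ii <- b$rows[[band]][1]:b$rows[[band]][2]
        u[ii, jj] <- recipe$values[band, 1]
        v[ii, jj] <- recipe$values[band, 2]
        phi[ii, jj] <- recipe$values[band, 3]
      }
      media_state(u, v, phi)
    },
    abort(paste0("unknown recipe kind: ", recipe$kind))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
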