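# Independent reference implementations used as oracles. These stay naive
# on purpose: explicit double loops and literal formula transcriptions,
# sharing no code with the package's vectorized / compiled paths.

# Five-point no-flux Laplacian via explicit ghost nodes.
naive_laplacian <- function(f, dx = 1) {
  nr <- nrow(f); nc <- ncol(f)
  out <- matrix(NA_real_, nr, nc)
  gv <- function(i, j) {
    i <- min(max(i, 1L), nr)  # mirror ghost: value copy across the edge
    j <- min(max(j, 1L), nc)
    f[i, j]
  }
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    out[i, j] <- (gv(i - 1L, j) + gv(i + 1L, j) + gv(i, j - 1L) +
                    gv(i, j + 1L) - 4 * f[i, j]) / dx^2
  }
  out
}

# One synchronous Euler step, per node, straight from the rate formulas.
naive_step <- function(u, v, phi, p, dx, h, mode = "induction",
                       forcing = NULL) {
  nr <- nrow(u); nc <- ncol(u)
  lap <- naive_laplacian(u, dx)
  un <- u; vn <- v; pn <- phi
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    uu <- u[i, j]; vv <- v[i, j]; pp <- phi[i, j]
    drive <- if (mode == "induction")
      p$k0 * (p$alpha + 3 * p$beta * pp^2) * uu else p$I_st
    du <- -p$k * uu * (uu - p$a) * (uu - 1.0) - uu * vv + drive +
      p$D_u * lap[i, j]
    dv <- (p$eps + vv * p$mu1 / (uu + p$mu2)) *
      (-vv - p$k * uu * (uu - p$a - 1.0))
    f <- if (is.null(forcing)) 0 else forcing[i, j]
    dp <- p$k1 * uu - p$k2 * pp + f
    un[i, j] <- uu + h * du
    vn[i, j] <- vv + h * dv
    pn[i, j] <- pp + h * dp
  }
  list(u = un, v = vn, phi = pn)
}

# Exhaustive strict-local-maximum scan.
naive_peaks <- function(x) {
  idx <- integer(0)
  for (i in seq_along(x)) {
    if (i == 1L || i == length(x)) next
    if (x[i] > x[i - 1L] && x[i] > x[i + 1L]) idx <- c(idx, i)
  }
  idx
}

# Small random media state away from the u = -mu2 singular line.
random_state <- function(n = 16L, seed = 1L) {
  set.seed(seed)
  media_state(matrix(runif(n * n, -0.2, 1.2), n, n),
              matrix(runif(n * n, 0, 1.5), n, n),
              matrix(runif(n * n, -0.5, 0.5), n, n))
}

fast_grid <- function(n = 16L, ...) {
  grid_spec(n_rows = n, n_cols = n, L = 350 * n / 200, h = 0.03, ...)
}
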