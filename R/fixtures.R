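#' Synthetic test inputs
#'
#' Generates the small synthetic objects used to exercise the analysis
#' instruments against known ground truth:
#'
#' * `"random_field"` — a `size` x `size` matrix of standard-normal
#'   values.
#' * `"spiral_phase"` — a phase field `charge * atan2(y - yc, x - xc)`
#'   with exactly `|charge|` = 1 singularity of known topological charge
#'   at the center.
#' * `"defect_pair"` — two superposed opposite-charge defects (count 2,
#'   net charge 0).
#' * `"two_cluster_peaks"` — a series whose strict maxima alternate
#'   between two fixed values (multimodal by construction).
#' * `"sine_series"` — `sin(t)` sampled over `n_periods` full periods.
#'
#' @param kind Fixture kind, see above.
#' @param size Lattice side (fields) or sample count (series).
#' @param seed Integer seed (`NULL` leaves the RNG alone).
#' @param charge Topological charge for `"spiral_phase"` (+1 or -1).
#' @param n_periods Full periods for `"sine_series"`.
#' @return The fixture: a matrix for field kinds, a tibble `t, value`
#'   for series kinds.
#' @examples
#' ph <- make_fixtures("spiral_phase", size = 40)
#' count_phase_singularities(ph)$count
#' @export
make_fixtures <- function(kind = c("random_field", "spiral_phase",
                                   "defect_pair", "two_cluster_peaks",
                                   "sine_series"),
                          size = 16L, seed = NULL, charge = 1L,
                          n_periods = 4L) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  xc <- (size + 1) / 2
  grid_xy <- function() list(
    x = matrix(seq_len(size), size, size) - xc,
    y = matrix(seq_len(size), size, size, byrow = TRUE) - xc)
  switch(kind,
    random_field = matrix(rnorm(size * size), size, size),
    spiral_phase = {
      g <- grid_xy()
      atan2(sin(charge * atan2(g$y, g$x)), cos(charge * atan2(g$y, g$x)))
    },
    defect_pair = {
      g <- grid_xy()
      off <- size / 4
      th <- atan2(g$y, g$x - off) - atan2(g$y, g$x + off)
      atan2(sin(th), cos(th))
    },
    two_cluster_peaks = {
      # peaks at every 4th sample, alternating heights 1 and 0.5
      n <- max(size, 16L)
      v <- rep(0, n)
      pk <- seq(3L, n - 1L, by = 4L)
      v[pk] <- rep(c(1, 0.5), length.out = length(pk))
      tibble::tibble(t = seq_len(n) - 1, value = v)
    },
    sine_series = {
      t <- seq(0, n_periods * 2 * pi, length.out = max(size, 100L))
      tibble::tibble(t = t, value = sin(t))
    })
}
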