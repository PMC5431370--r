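#' Strict local-maximum peak detection
#'
#' Records a sample as a peak only when it strictly exceeds both the
#' pre-adjacent and post-adjacent samples; plateaus (equal neighbours) and
#' series endpoints are never peaks. Samples before `transient` are
#' discarded first, so an interior point of the full series can become an
#' endpoint of the analysed window.
#'
#' @param x Numeric vector of samples, or a data frame with columns `t`
#'   and `u` (or `value`) such as the `series` of an [simulate_media()]
#'   run.
#' @param times Sample times; defaults to `0, 1, 2, ...` for a bare
#'   vector.
#' @param transient Time before which samples are discarded.
#' @return A tibble with columns `time` and `value`, one row per peak,
#'   times strictly increasing; zero rows when no strict maximum exists.
#' @examples
#' detect_peaks(c(0, 1, 0, 2, 0))
#' @export
detect_peaks <- function(x, times = NULL, transient = 0) {
  if (is.data.frame(x)) {
    pick <- function(df, nms) {
      hit <- intersect(nms, names(df))
      if (length(hit) == 0) NULL else df[[hit[1]]]
    }
    times <- pick(x, c("t", "time"))
    x <- pick(x, c("u", "value"))
    if (is.null(x) || is.null(times))
      abort("data frame input needs columns `t`/`time` and `u`/`value`")
  }
  x <- as.numeric(x)
  times <- times %||% (seq_along(x) - 1)
  if (length(times) != length(x)) abort("`times` must match the series length")
  keep <- times >= transient
  if (!any(keep)) abort("no samples remain after the transient")
  x <- x[keep]; times <- times[keep]
  n <- length(x)
  if (n < 3L) return(tibble::tibble(time = numeric(0), value = numeric(0)))
  mid <- x[2:(n - 1)]
  is_peak <- mid > x[1:(n - 2)] & mid > x[3:n]
  idx <- which(is_peak) + 1L
  tibble::tibble(time = times[idx], value = x[idx])
}

#' Classify the activity of a node series
#'
#' Labels post-transient electrical activity from its detected peaks:
#' `"quiescent"` when there are at most `min_peaks` peaks or the series
#' amplitude stays below `amp_floor`; `"periodic"` when both the
#' inter-peak intervals and the peak values have relative dispersion
#' (sd / |mean|) below `rel_tol`; `"multimodal"` when the peak values
#' split into more than one cluster (successive sorted-value gaps larger
#' than `gap_factor` times the typical within-cluster gap); `"irregular"`
#' otherwise (e.g. the chaotic-like series seen at small flux-leak gain).
#'
#' @param peaks A peak tibble from [detect_peaks()].
#' @param series The post-transient sample values the peaks came from
#'   (used for the amplitude floor); optional.
#' @param amp_floor Minimum series amplitude (max - min) for activity.
#' @param rel_tol Relative-dispersion tolerance for periodicity.
#' @param gap_factor Cluster-gap multiplier for multimodality.
#' @param min_peaks Peak count at or below which the node is quiescent.
#' @return One of `"quiescent"`, `"periodic"`, `"multimodal"`,
#'   `"irregular"`.
#' @export
classify_activity <- function(peaks, series = NULL, amp_floor = 0.05,
                              rel_tol = 0.05, gap_factor = 3,
                              min_peaks = 1L) {
  n <- nrow(peaks)
  if (n <= min_peaks) return("quiescent")
  if (!is.null(series)) {
    if (is.data.frame(series)) {
      hit <- intersect(c("u", "value"), names(series))
      series <- series[[hit[1]]]
    }
    series <- as.numeric(series)
    if (max(series) - min(series) < amp_floor) return("quiescent")
  }
  rel_disp <- function(z) {
    m <- mean(abs(z))
    if (m < .Machine$double.eps) 0 else sd(z) / m
  }
  ivals <- diff(peaks$time)
  if (rel_disp(ivals) < rel_tol && rel_disp(peaks$value) < rel_tol)
    return("periodic")
  if (length(.cluster_1d(peaks$value, gap_factor, amp_floor)) > 1L)
    return("multimodal")
  "irregular"
}

# Gap-based 1D clustering: recursively split sorted values at the largest
# gap whenever it exceeds gap_factor times the within-cluster spread of
# the resulting halves (absolute floor so exact-tie clusters still split
# at a real jump). Returns a list of value groups.
.cluster_1d <- function(values, gap_factor = 3, floor_gap = 0.05) {
  sd0 <- function(z) if (length(z) < 2L) 0 else sd(z)
  split_rec <- function(v) {
    if (length(v) < 2L) return(list(v))
    gaps <- diff(v)
    gi <- which.max(gaps)
    left <- v[seq_len(gi)]
    right <- v[-seq_len(gi)]
    within <- max(sd0(left), sd0(right))
    if (gaps[gi] > max(gap_factor * within, floor_gap * 0.5))
      return(c(split_rec(left), split_rec(right)))
    list(v)
  }
  split_rec(sort(values))
}

#' Bifurcation scan over an induction gain
#'
#' For each value of the scanned gain (`k0`, `k1` or `k2`), runs the full
#' 2D media simulation from the same initial recipe, detects the
#' post-transient peaks of the membrane potential at the monitored node,
#' and labels the activity. This is the instrument behind bifurcation
#' diagrams of maximal membrane potential versus a gain. A failed value
#' (e.g. divergence) is flagged and does not abort the scan.
#'
#' @param param One of `"k0"`, `"k1"`, `"k2"`.
#' @param values Numeric vector of gain values to scan.
#' @param params Base [model_params()]; the scanned entry is overwritten.
#' @param grid An [grid_spec()].
#' @param init Initial recipe (default the stripe seed).
#' @param node 1-based `(row, col)` of the monitored node; default scales
#'   node (100, 100) to the grid.
#' @param transient Fraction of the run discarded before peak detection
#'   (in (0, 1)), or an absolute time if >= 1.
#' @param forcing,mode,seed Passed to [simulate_media()].
#' @param ... Further arguments to [simulate_media()].
#' @return An `fhn_bifurcation`: a tibble with one row per value and
#'   columns `param`, `value`, `n_peaks`, `peak_max`, `label`, `failed`
#'   and a list-column `peaks` of peak tibbles.
#' @export
bifurcation_scan <- function(param = c("k0", "k1", "k2"), values,
                             params = model_params(), grid = grid_spec(),
                             init = stripe_recipe(), node = NULL,
                             transient = 0.5, forcing = NULL,
                             mode = "induction", seed = NULL, ...) {
  param <- match.arg(param)
  t_cut <- if (transient < 1) transient * (grid$duration) else transient
  rows <- purrr::map(values, function(val) {
    p <- params
    p[[param]] <- val
    res <- tryCatch({
      run <- simulate_media(init, p, grid, forcing = forcing,
                            monitor = node, mode = mode, seed = seed, ...)
      ser <- dplyr::filter(run$series, .data$t >= t_cut)
      pk <- detect_peaks(run$series, transient = t_cut)
      list(peaks = pk, label = classify_activity(pk, ser), failed = FALSE)
    }, error = function(e) {
      list(peaks = tibble::tibble(time = numeric(0), value = numeric(0)),
           label = NA_character_, failed = TRUE)
    })
    tibble::tibble(param = param, value = val,
                   n_peaks = nrow(res$peaks),
                   peak_max = if (nrow(res$peaks) > 0) max(res$peaks$value)
                              else NA_real_,
                   label = res$label, failed = res$failed,
                   peaks = list(res$peaks))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("fhn_bifurcation", class(out)),
            transient = t_cut, node = node)
}

#' Spatial dispersion of a field
#'
#' Population standard deviation over all lattice nodes: zero for a
#' homogeneous (magnetized/suppressed) media, large when the media
#' carries waves or turbulence.
#'
#' @param field Numeric matrix.
#' @return Scalar standard deviation (denominator `n`, not `n - 1`).
#' @export
spatial_std <- function(field) {
  m <- mean(field)
  sqrt(mean((field - m)^2))
}

#' Local phase of the excitation cycle
#'
#' Maps each node's `(u, v)` to an angle `atan2(v - v0, u - u0)` in
#' `(-pi, pi]` around a reference point `(u0, v0)` chosen inside the
#' oscillation loop. A practical reference is the post-transient
#' trajectory centroid of a monitored node (see [pattern_metrics()]); the
#' model itself defines no phase, so this is a standard excitable-media
#' instrument layered on top. The angle of an exactly zero vector is
#' defined as 0; the number of such nodes is attached as attribute
#' `n_zero`.
#'
#' @param u_field,v_field Matrices of the two fast/slow fields.
#' @param reference Numeric `(u0, v0)`.
#' @return Matrix of angles in `(-pi, pi]`, attribute `n_zero`.
#' @export
phase_field <- function(u_field, v_field, reference) {
  stopifnot(identical(dim(u_field), dim(v_field)), length(reference) == 2L)
  du <- u_field - reference[1]
  dv <- v_field - reference[2]
  ph <- atan2(dv, du)
  structure(ph, n_zero = sum(du == 0 & dv == 0))
}

#' Count phase singularities
#'
#' A phase singularity (spiral core) is a node around which the phase
#' winds by +-2 pi. For every 2 x 2 plaquette the four wrapped phase
#' differences around the loop are summed; a plaquette with |winding|
#' near 2 pi contains a singularity. Positive and negative topological
#' charges are counted separately and totalled.
#'
#' @param phase An angle matrix from [phase_field()].
#' @return List with `count`, `net_charge`, and `locations` (tibble
#'   `row, col, charge`; coordinates are plaquette centers, i.e. node
#'   index + 0.5).
#' @examples
#' th <- outer(1:50 - 25.5, 1:50 - 25.5, function(x, y) atan2(y, x))
#' count_phase_singularities(th)$count # 1
#' @export
count_phase_singularities <- function(phase) {
  nr <- nrow(phase); nc <- ncol(phase)
  wrap <- function(x) atan2(sin(x), cos(x))
  a <- phase[-nr, -nc]  # (i, j)
  b <- phase[-nr, -1]   # (i, j+1)
  cc <- phase[-1, -1]   # (i+1, j+1)
  d <- phase[-1, -nc]   # (i+1, j)
  # loop oriented so that a field atan2(col - c0, row - r0) carries
  # charge +1
  w <- -(wrap(b - a) + wrap(cc - b) + wrap(d - cc) + wrap(a - d))
  hit <- abs(w) > pi    # winding is a multiple of 2*pi; nonzero => +-2pi
  idx <- which(hit, arr.ind = TRUE)
  loc <- tibble::tibble(row = idx[, 1] + 0.5, col = idx[, 2] + 0.5,
                        charge = as.integer(sign(w[hit])))
  list(count = nrow(loc), net_charge = sum(loc$charge), locations = loc)
}

#' Pattern metrics of a media state
#'
#' Quantifies the qualitative pattern classes — developed spiral,
#' suppressed/homogeneous media, breakup/turbulence — as numbers: the
#' spatial standard deviation of `u` and the phase-singularity count. The
#' phase reference defaults to the post-transient `(u, v)` centroid of a
#' monitored-node series when one is supplied (an oscillating node's
#' centroid sits inside the excitation loop), else to the field medians.
#'
#' @param state An [media_state()] (or an `fhn_run`, whose final state is
#'   used and whose series supplies the reference).
#' @param reference Optional explicit phase reference `(u0, v0)`.
#' @param series Optional node-series tibble used to derive the
#'   reference.
#' @param transient Time before which series samples are ignored when
#'   deriving the reference.
#' @return One-row tibble: `t`, `spatial_std_u`, `n_singularities`,
#'   `net_charge`, `ref_u`, `ref_v`.
#' @export
pattern_metrics <- function(state, reference = NULL, series = NULL,
                            transient = 0) {
  if (inherits(state, "fhn_run")) {
    series <- series %||% state$series
    state <- state$final
  }
  stopifnot(inherits(state, "fhn_media"))
  if (is.null(reference)) {
    if (!is.null(series)) {
      s <- series[series$t >= transient, , drop = FALSE]
      reference <- c(mean(s$u), mean(s$v))
    } else {
      reference <- c(median(state$u), median(state$v))
    }
  }
  ph <- phase_field(state$u, state$v, reference)
  ps <- count_phase_singularities(ph)
  tibble::tibble(t = state$t, spatial_std_u = spatial_std(state$u),
                 n_singularities = ps$count, net_charge = ps$net_charge,
                 ref_u = reference[1], ref_v = reference[2])
}
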