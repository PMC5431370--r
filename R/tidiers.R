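#' Tidy methods for simulation results
#'
#' `tidy()` on an `fhn_run` returns the monitored-node series (one row
#' per retained step and node); `glance()` a one-row summary of the run.
#' On an `fhn_bifurcation`, `tidy()` unnests every detected peak (one row
#' per peak per scanned value) — the classic way to draw a bifurcation
#' diagram — and `glance()` tabulates the activity labels.
#'
#' @param x An `fhn_run` or `fhn_bifurcation`.
#' @param ... Unused.
#' @return A tibble.
#' @name memfhn-tidiers
NULL

#' @rdname memfhn-tidiers
#' @export
tidy.fhn_run <- function(x, ...) x$series

#' @rdname memfhn-tidiers
#' @export
glance.fhn_run <- function(x, ...) {
  tibble::tibble(
    t_final = x$final$t, n_steps = x$n_steps, h = x$grid$h,
    n_rows = x$grid$n_rows, n_cols = x$grid$n_cols, mode = x$mode,
    spatial_std_u = spatial_std(x$final$u),
    u_min = min(x$final$u), u_max = max(x$final$u),
    n_snapshots = length(x$snapshots))
}

#' @rdname memfhn-tidiers
#' @export
tidy.fhn_bifurcation <- function(x, ...) {
  df <- tibble::as_tibble(x)
  df$peaks <- purrr::map(df$peaks, function(p)
    dplyr::rename(p, peak_time = "time", peak_value = "value"))
  tidyr::unnest(dplyr::select(df, "param", "value", "label", "peaks"),
                "peaks", keep_empty = FALSE)
}

#' @rdname memfhn-tidiers
#' @export
glance.fhn_bifurcation <- function(x, ...) {
  df <- tibble::as_tibble(x)
  tibble::tibble(
    param = df$param[1], n_values = nrow(df),
    n_failed = sum(df$failed),
    n_quiescent = sum(df$label == "quiescent", na.rm = TRUE),
    n_periodic = sum(df$label == "periodic", na.rm = TRUE),
    n_multimodal = sum(df$label == "multimodal", na.rm = TRUE),
    n_irregular = sum(df$label == "irregular", na.rm = TRUE),
    transient = attr(x, "transient"))
}
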