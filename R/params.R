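#' Model parameters for the memristive FitzHugh-Nagumo media
#'
#' Bundles every scalar coefficient of the three-variable model in one
#' immutable record. The membrane potential `u` obeys a cubic FitzHugh-Nagumo
#' kinetics `-k u (u - a)(u - 1) - u v` plus either an external stimulus
#' current `I_st` (baseline two-variable mode) or the induction feedback
#' `k0 rho(phi) u` (three-variable mode), with diffusion `D_u` acting on `u`
#' only. The recovery variable `v` relaxes at a rate set by `eps`, `mu1`,
#' `mu2`; the magnetic flux `phi` integrates `k1 u` and leaks at rate `k2`.
#' The memductance is `rho(phi) = alpha + 3 beta phi^2`.
#'
#' Defaults are the canonical excitable-cardiac-tissue setting: `k = 8`,
#' `a = 0.15`, `eps = 0.002`, `mu1 = 0.2`, `mu2 = 0.3`, `I_st = 0`,
#' `D_u = 1`, and induction gains `k0 = 0.1`, `k1 = 0.5`, `k2 = 1` with
#' memductance coefficients `alpha = 1`, `beta = 2` (the regime in which a
#' stripe seed develops a stable spiral). All quantities are dimensionless.
#'
#' @param k Cubic-nonlinearity gain (> 0).
#' @param a Excitation threshold.
#' @param eps Recovery time-scale separation (> 0).
#' @param mu1,mu2 Recovery-rate shape parameters (`mu2` > 0; the recovery
#'   rate divides by `u + mu2`).
#' @param I_st External stimulus current (baseline mode only).
#' @param D_u Diffusion coefficient of the membrane potential (>= 0).
#' @param k0 Induction feedback gain multiplying `rho(phi) u`.
#' @param k1 Flux-drive gain (how strongly `u` charges the flux).
#' @param k2 Flux-leak gain (>= 0).
#' @param alpha Memductance offset.
#' @param beta Memductance curvature.
#'
#' @return An object of class `fhn_params`: a named list of the twelve
#'   coefficients.
#' @examples
#' p <- model_params()
#' p$k2
#' model_params(k0 = 0.9) # suppression regime
#' @export
model_params <- function(k = 8.0, a = 0.15, eps = 0.002, mu1 = 0.2,
                         mu2 = 0.3, I_st = 0.0, D_u = 1.0, k0 = 0.1,
                         k1 = 0.5, k2 = 1.0, alpha = 1.0, beta = 2.0) {
  p <- list(k = k, a = a, eps = eps, mu1 = mu1, mu2 = mu2, I_st = I_st,
            D_u = D_u, k0 = k0, k1 = k1, k2 = k2, alpha = alpha,
            beta = beta)
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                            is.finite(x), logical(1))]
  if (length(bad) > 0)
    abort(paste0("model parameters must be finite scalars; offending: ",
                 paste(bad, collapse = ", ")))
  if (p$k <= 0) abort("`k` must be > 0")
  if (p$eps <= 0) abort("`eps` must be > 0")
  if (p$mu2 <= 0) abort("`mu2` must be > 0")
  if (p$k2 < 0) abort("`k2` must be >= 0")
  if (p$D_u < 0) abort("`D_u` must be >= 0")
  structure(p, class = "fhn_params")
}

#' @export
print.fhn_params <- function(x, ...) {
  cat("<fhn_params>\n")
  cat("  kinetics:  k =", x$k, " a =", x$a, " eps =", x$eps,
      " mu1 =", x$mu1, " mu2 =", x$mu2, "\n")
  cat("  drive:     I_st =", x$I_st, " D_u =", x$D_u, "\n")
  cat("  induction: k0 =", x$k0, " k1 =", x$k1, " k2 =", x$k2,
      " alpha =", x$alpha, " beta =", x$beta, "\n")
  invisible(x)
}

# Fixed-order parameter vector handed to the C++ kernel.
par_vec <- function(params) {
  stopifnot(inherits(params, "fhn_params"))
  as.numeric(params[c("k", "a", "eps", "mu1", "mu2", "I_st", "D_u",
                      "k0", "k1", "k2", "alpha", "beta")])
}

.mode_code <- function(mode) {
  switch(match.arg(mode, c("induction", "baseline", "diffusion")),
         baseline = 0L, induction = 1L, diffusion = 2L)
}

#' Single-cell state
#'
#' A point state of the space-free model: membrane potential `u`, recovery
#' variable `v` and magnetic flux `phi`. Used by [integrate_cell()]; the rate
#' functions also accept plain numeric vectors for vectorized evaluation.
#'
#' @param u Membrane potential.
#' @param v Recovery variable.
#' @param phi Magnetic flux.
#' @return An object of class `fhn_cell`: named numeric vector
#'   `(u, v, phi)`.
#' @examples
#' cell_state(0.7, 0.6, 0.1)
#' @export
cell_state <- function(u = 0, v = 0, phi = 0) {
  s <- c(u = as.numeric(u), v = as.numeric(v), phi = as.numeric(phi))
  if (length(s) != 3L || any(!is.finite(s)))
    abort("cell state must be three finite scalars (u, v, phi)")
  structure(s, class = "fhn_cell")
}
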