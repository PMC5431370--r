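#' Flux-controlled memductance
#'
#' The memristor conductance as a function of magnetic flux,
#' `rho(phi) = alpha + 3 beta phi^2`: the derivative of the memristor's
#' charge-flux constitutive relation. Even in `phi`, and bounded below by
#' `alpha` whenever `beta >= 0`. This is the coupling through which flux
#' feeds back on the membrane potential (term `k0 rho(phi) u`).
#'
#' @param phi Magnetic flux (numeric vector or matrix).
#' @param params An [model_params()] object (only `alpha`, `beta` used).
#' @return `alpha + 3 * beta * phi^2`, same shape as `phi`.
#' @examples
#' memductance(0, model_params())   # alpha
#' memductance(1, model_params())   # 1 + 3*2 = 7
#' @export
memductance <- function(phi, params = model_params()) {
  params$alpha + 3 * params$beta * phi^2
}

#' Reaction rate of the membrane potential
#'
#' Time derivative of `u` from the point kinetics, excluding diffusion
#' (which acts at the lattice level, see [media_step()]):
#' `-k u (u - a)(u - 1) - u v` plus either the stimulus current `I_st`
#' (`mode = "baseline"`, the classical two-variable model) or the induction
#' feedback `k0 rho(phi) u` (`mode = "induction"`, the three-variable
#' model, which carries no `I_st` term).
#'
#' @param u,v,phi State components; any shapes that recycle together.
#' @param params An [model_params()] object.
#' @param mode `"induction"` (default) or `"baseline"`.
#' @return `du/dt`, same shape as the inputs.
#' @examples
#' rate_u(1, 0, 0, model_params(k0 = 0.1)) # 0.1: only the feedback survives
#' @export
rate_u <- function(u, v, phi = 0, params = model_params(),
                   mode = c("induction", "baseline")) {
  mode <- match.arg(mode)
  drive <- if (mode == "induction") {
    params$k0 * memductance(phi, params) * u
  } else {
    params$I_st
  }
  -params$k * u * (u - params$a) * (u - 1.0) - u * v + drive
}

#' Reaction rate of the recovery variable
#'
#' Time derivative of `v`:
#' `(eps + v * mu1 / (u + mu2)) * (-v - k * u * (u - a - 1))`.
#' The rate is undefined on the line `u = -mu2`; evaluation within `guard`
#' of it is a domain error (raised, never clamped, so NaN cannot propagate
#' silently).
#'
#' @inheritParams rate_u
#' @param guard Half-width of the excluded band around `u = -mu2`.
#' @return `dv/dt`, same shape as the inputs.
#' @examples
#' rate_v(1, 0, model_params()) # 0.002 * 1.2 = 0.0024
#' @export
rate_v <- function(u, v, params = model_params(), guard = 1e-12) {
  denom <- u + params$mu2
  if (any(abs(denom) < guard))
    abort(sprintf("recovery rate undefined: |u + mu2| < %g", guard))
  (params$eps + v * params$mu1 / denom) *
    (-v - params$k * u * (u - params$a - 1.0))
}

#' Rate of the magnetic flux
#'
#' Time derivative of `phi`: `k1 * u - k2 * phi + forcing`, where `forcing`
#' is any external electromagnetic drive on the flux (zero for the closed
#' model; see [radiation_profile()] and [noise_increment()] for the drives
#' used on the lattice).
#'
#' @inheritParams rate_u
#' @param forcing External flux drive (default 0).
#' @return `dphi/dt`, same shape as the inputs.
#' @export
rate_phi <- function(u, phi, params = model_params(), forcing = 0) {
  params$k1 * u - params$k2 * phi + forcing
}

#' Integrate a single isolated cell
#'
#' Explicit Euler-forward integration of the space-free three-variable
#' model, for fast parameter scans and convergence checks. This is a
#' testing and exploration device: lattice nodes are integrated by
#' [simulate_media()], and an isolated cell's waveform need not match a
#' node embedded in the diffusively coupled media.
#'
#' @param state0 Initial [cell_state()] (or named numeric `(u, v, phi)`).
#' @param params An [model_params()] object.
#' @param duration Total simulated time (>= `h`).
#' @param h Euler time step (> 0).
#' @param forcing_fn Optional function of time returning the external flux
#'   drive at that time; `NULL` means no drive.
#' @param mode `"induction"` or `"baseline"` (see [rate_u()]).
#' @param freeze Character vector of variables (`"u"`, `"v"`, `"phi"`) to
#'   hold constant at their initial values; used e.g. to expose the linear
#'   flux subsystem for closed-form verification.
#' @param stride Record every `stride`-th step (default every step).
#' @param guard,blowup Domain-error band for [rate_v()] and the abort
#'   threshold on `max(|state|)` (divergence is an error, never clipped).
#' @return A tibble with columns `t`, `u`, `v`, `phi`; first row is the
#'   initial state.
#' @examples
#' tr <- integrate_cell(cell_state(0.7, 0.6, 0.1), model_params(),
#'                      duration = 5, h = 0.03)
#' tail(tr, 3)
#' @export
integrate_cell <- function(state0, params = model_params(), duration, h,
                           forcing_fn = NULL, mode = c("induction", "baseline"),
                           freeze = character(), stride = 1L,
                           guard = 1e-12, blowup = 1e6) {
  mode <- match.arg(mode)
  if (h <= 0) abort("`h` must be > 0")
  if (duration < h) abort("`duration` must be >= h")
  stopifnot(all(freeze %in% c("u", "v", "phi")))
  s <- as.numeric(state0[c("u", "v", "phi")])
  u <- s[1]; v <- s[2]; phi <- s[3]
  n_steps <- round(duration / h)
  keep <- seq(0L, n_steps, by = as.integer(stride))
  out <- matrix(NA_real_, nrow = length(keep), ncol = 4L,
                dimnames = list(NULL, c("t", "u", "v", "phi")))
  out[1L, ] <- c(0, u, v, phi)
  row <- 2L
  fu <- "u" %in% freeze; fv <- "v" %in% freeze; fp <- "phi" %in% freeze
  for (i in seq_len(n_steps)) {
    t_now <- (i - 1) * h
    f <- if (is.null(forcing_fn)) 0 else forcing_fn(t_now)
    du <- if (fu) 0 else rate_u(u, v, phi, params, mode)
    dv <- if (fv) 0 else rate_v(u, v, params, guard)
    dp <- if (fp) 0 else rate_phi(u, phi, params, f)
    u <- u + h * du; v <- v + h * dv; phi <- phi + h * dp
    m <- max(abs(u), abs(v), abs(phi))
    if (!is.finite(m) || m > blowup)
      abort(sprintf("cell state diverged (max |state| = %g) at t = %g",
                    m, i * h))
    if (i %% stride == 0L) {
      out[row, ] <- c(i * h, u, v, phi)
      row <- row + 1L
    }
  }
  tibble::as_tibble(out[seq_len(row - 1L), , drop = FALSE])
}
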