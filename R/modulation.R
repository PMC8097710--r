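#' Modulation parameter set
#'
#' Bundles everything that defines the modulator `M(f, t)`: its kind
#' (exponential, linear or none), depth, temporal rate, spectral density and
#' envelope phase. The per-carrier envelope phase is
#' `Phi(f) = 2 pi Omega log2(f / f0) + Phi0`, so the ripple is periodic on an
#' octave scale; `rate = 0` gives pure spectral modulation (SM) and
#' `density = 0` gives pure temporal modulation (TM, all carriers share
#' phase `Phi0`).
#'
#' @param kind `"exponential"`, `"linear"` or `"none"`.
#' @param depth An [exponential_depth()], [linear_depth()], or a bare number
#'   interpreted in the kind's convention (dB midpoint-to-peak for
#'   exponential, unitless in `[0,1)` for linear). Ignored for `"none"`.
#' @param rate Temporal modulation rate `w` in Hz, `>= 0`.
#' @param density Spectral modulation density `Omega` in cycles/octave, `>= 0`.
#' @param phase0 Global envelope phase `Phi0` in radians.
#' @param f_ref Reference frequency `f0 > 0` in Hz: the frequency whose
#'   envelope phase equals `Phi0` (conventionally the lower band edge).
#' @return An object of class `"modulation_params"`.
#' @seealso [sm_params()], [tm_params()], [stm_params()] for the standard
#'   special cases.
#' @export
modulation_params <- function(kind = c("exponential", "linear", "none"),
                              depth = NULL, rate = 0, density = 0,
                              phase0 = 0, f_ref = 400) {
  kind <- match.arg(kind)
  if (kind != "none" && is.null(depth))
    stop_domain("'depth' is required for kind '%s'", kind)
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0)
    stop_domain("'rate' (temporal modulation rate, Hz) must be >= 0")
  if (!is.numeric(density) || length(density) != 1L || is.na(density) ||
      density < 0)
    stop_domain("'density' (cycles/octave) must be >= 0")
  if (!is.numeric(f_ref) || length(f_ref) != 1L || is.na(f_ref) || f_ref <= 0)
    stop_domain("'f_ref' must be > 0 Hz")
  structure(
    list(kind = kind, depth = as_depth(depth, kind),
         rate = as.numeric(rate), density = as.numeric(density),
         phase0 = as.numeric(phase0), f_ref = as.numeric(f_ref)),
    class = "modulation_params"
  )
}

#' Standard modulation parameter constructors
#'
#' Convenience constructors for the three canonical modulator geometries:
#' spectral modulation (`sm_params`, rate fixed at 0), temporal modulation
#' (`tm_params`, density fixed at 0 so all carriers share the envelope phase)
#' and spectro-temporal modulation (`stm_params`, both nonzero).
#'
#' @param depth Modulation depth (see [modulation_params()]).
#' @param density Spectral density in cycles/octave (default 2).
#' @param rate Temporal rate in Hz.
#' @param phase0 Global envelope phase in radians.
#' @param f_ref Reference frequency in Hz.
#' @param kind Modulator kind, default `"exponential"`.
#' @return A [modulation_params()] object.
#' @export
sm_params <- function(depth, density = 2, phase0 = 0, f_ref = 400,
                      kind = "exponential") {
  modulation_params(kind, depth, rate = 0, density = density,
                    phase0 = phase0, f_ref = f_ref)
}

#' @rdname sm_params
#' @export
tm_params <- function(depth, rate, phase0 = 0, f_ref = 400,
                      kind = "exponential") {
  modulation_params(kind, depth, rate = rate, density = 0,
                    phase0 = phase0, f_ref = f_ref)
}

#' @rdname sm_params
#' @export
stm_params <- function(depth, rate, density = 2, phase0 = 0, f_ref = 400,
                       kind = "exponential") {
  modulation_params(kind, depth, rate = rate, density = density,
                    phase0 = phase0, f_ref = f_ref)
}

#' Envelope phase as a function of carrier frequency
#'
#' `Phi(f) = 2 pi Omega log2(f / f0) + Phi0`: each cycle/octave of spectral
#' density advances the envelope by one full cycle per octave above the
#' reference frequency. With `density = 0` every carrier receives `Phi0`.
#'
#' @param f Frequency (or vector of frequencies) in Hz, `> 0`.
#' @param params A [modulation_params()] object.
#' @return Envelope phase(s) in radians.
#' @examples
#' p <- sm_params(20, density = 1, f_ref = 400)
#' envelope_phase(800, p)   # one octave up: 2 pi
#' @export
envelope_phase <- function(f, params) {
  stopifnot(inherits(params, "modulation_params"))
  if (!is.numeric(f) || anyNA(f) || any(f <= 0))
    stop_domain("'f' must be positive (Hz)")
  2 * pi * params$density * log2(f / params$f_ref) + params$phase0
}

#' @export
print.modulation_params <- function(x, ...) {
  dtxt <- switch(x$kind,
    none = "unmodulated",
    exponential = sprintf("m = %g dB midpoint-to-peak", x$depth$m),
    linear = sprintf("m = %g (linear)", x$depth$m_lin))
  cat(sprintf(
    "Modulation: %s (%s), rate = %g Hz, density = %g cyc/oct, Phi0 = %.3g rad, f0 = %g Hz\n",
    x$kind, dtxt, x$rate, x$density, x$phase0, x$f_ref))
  invisible(x)
}
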