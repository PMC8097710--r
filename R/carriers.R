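#' Carrier tone set
#'
#' The stationary pure tones that make up a multi-tone noise before
#' modulation: a frequency, non-negative amplitude and phase per tone. All
#' stimulus statistics of the underlying noise (spectral shaping, amplitude
#' distribution) live in these three vectors; the modulator is applied on top.
#'
#' @param frequency Carrier frequencies in Hz, all `> 0`.
#' @param amplitude Carrier amplitudes (linear units), all `>= 0`. Recycled.
#' @param phase Carrier phases in radians. Recycled.
#' @return An object of class `"carrier_set"`.
#' @examples
#' carrier_set(c(500, 1000), amplitude = 1, phase = c(0, pi / 4))
#' @export
carrier_set <- function(frequency, amplitude = 1, phase = 0) {
  if (!is.numeric(frequency) || length(frequency) < 1L || anyNA(frequency) ||
      any(frequency <= 0))
    stop_domain("carrier frequencies must be positive (Hz)")
  n <- length(frequency)
  amplitude <- rep_len(as.numeric(amplitude), n)
  phase <- rep_len(as.numeric(phase), n)
  if (anyNA(amplitude) || any(amplitude < 0))
    stop_domain("carrier amplitudes must be non-negative")
  if (anyNA(phase)) stop_domain("carrier phases must be finite")
  structure(
    list(frequency = as.numeric(frequency), amplitude = amplitude,
         phase = phase),
    class = "carrier_set"
  )
}

#' @export
length.carrier_set <- function(x) length(x$frequency)

#' @export
as.data.frame.carrier_set <- function(x, ...) {
  data.frame(frequency_hz = x$frequency, amplitude = x$amplitude,
             phase_rad = x$phase)
}

#' @export
print.carrier_set <- function(x, ...) {
  cat(sprintf("Carrier set: %d tones, %g-%g Hz, total power %.4g\n",
              length(x), min(x$frequency), max(x$frequency),
              sum(x$amplitude^2) / 2))
  invisible(x)
}
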