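#' Exponential (logarithmic) modulation depth
#'
#' Depth of a modulator that is sinusoidal on a dB scale,
#' `M(t) = 10^((m/20) sin(theta))`. `m` is the midpoint-to-peak depth in
#' decibels; the peak-to-valley depth of the resulting envelope is `2 m`.
#' The derived exponent scale `M' = (m/20) ln 10` is the argument passed to
#' the modified Bessel functions that give the sideband amplitudes.
#'
#' @param m Midpoint-to-peak modulation depth in dB, `m >= 0`. `m = 0` leaves
#'   the carrier unmodified.
#' @return An object of class `"exponential_depth"` with fields `m` (dB) and
#'   `M_prime` (unitless Bessel argument).
#' @examples
#' d <- exponential_depth(20)  # 40 dB peak-to-valley
#' d$M_prime                   # ln(10) * 20/20
#' @export
exponential_depth <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0)
    stop_domain("exponential depth 'm' must be a single non-negative dB value")
  structure(
    list(m = as.numeric(m), M_prime = as.numeric(m) / 20 * log(10)),
    class = "exponential_depth"
  )
}

#' Linear modulation depth
#'
#' Depth of a modulator sinusoidal on a linear amplitude scale,
#' `M(t) = 1 + m sin(theta)`, with `m` restricted to `[0, 1)` so the envelope
#' never goes negative. Literature often reports this depth as
#' `20 log10(m)` dB; the `db` argument accepts that form.
#'
#' @param m Unitless linear depth in `[0, 1)`.
#' @param db Alternative specification: the depth as `20 log10(m)` dB
#'   (necessarily `< 0`). Exactly one of `m`, `db` must be given.
#' @return An object of class `"linear_depth"` with field `m_lin`.
#' @export
linear_depth <- function(m = NULL, db = NULL) {
  if (is.null(m) == is.null(db))
    stop_domain("give exactly one of 'm' (linear) or 'db' (20*log10(m))")
  if (!is.null(db)) m <- 10^(db / 20)
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0 || m >= 1)
    stop_domain("linear depth must lie in [0, 1); got %s", format(m))
  structure(list(m_lin = as.numeric(m)), class = "linear_depth")
}

#' @export
print.exponential_depth <- function(x, ...) {
  cat(sprintf(
    "Exponential modulation depth: m = %g dB midpoint-to-peak (%g dB peak-to-valley), M' = %.6g\n",
    x$m, 2 * x$m, x$M_prime))
  invisible(x)
}

#' @export
print.linear_depth <- function(x, ...) {
  cat(sprintf("Linear modulation depth: m = %g (%.3g dB)\n",
              x$m_lin, if (x$m_lin > 0) 20 * log10(x$m_lin) else -Inf))
  invisible(x)
}

# coerce a bare number to the depth class expected by a modulator kind
as_depth <- function(depth, kind) {
  if (kind == "none") return(NULL)
  if (kind == "exponential") {
    if (inherits(depth, "exponential_depth")) return(depth)
    if (inherits(depth, "linear_depth"))
      stop_domain("exponential modulator given a linear_depth")
    return(exponential_depth(depth))
  }
  if (inherits(depth, "linear_depth")) return(depth)
  if (inherits(depth, "exponential_depth"))
    stop_domain("linear modulator given an exponential_depth")
  linear_depth(depth)
}
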