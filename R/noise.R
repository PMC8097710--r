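#' Band-shaped random-carrier noise specification
#'
#' Describes a multi-tone noise built in the frequency domain: one carrier
#' per DFT bin (at maximum density) inside a passband, amplitudes drawn i.i.d.
#' from a Rayleigh distribution (or equal), and a dB-per-octave roll-off
#' applied outside the band edges, truncated where the attenuation exceeds
#' 60 dB. Phases are uniform on `[0, 2 pi)`. This is the classic
#' stationary-uncorrelated-tone construction of bandpass noise.
#'
#' @param band_lo,band_hi Passband edges in Hz, `0 < band_lo < band_hi`.
#' @param slope_db_per_octave Roll-off rate outside the passband (positive
#'   number of dB of attenuation per octave of distance from the band edge).
#'   The default 32 dB/octave emulates a steep bandpass filter.
#' @param amplitude_law `"rayleigh"` (scale 1) or `"equal"`.
#' @param density Carriers per DFT bin in-band, in `(0, 1]`; 1 is maximum
#'   density. Values below 1 keep every `round(1/density)`-th bin.
#' @param seed Optional integer seed for reproducible draws.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(band_lo = 400, band_hi = 3200,
                       slope_db_per_octave = 32,
                       amplitude_law = c("rayleigh", "equal"),
                       density = 1, seed = NULL) {
  amplitude_law <- match.arg(amplitude_law)
  if (!is.numeric(band_lo) || !is.numeric(band_hi) ||
      band_lo <= 0 || band_hi <= band_lo)
    stop_domain("need 0 < band_lo < band_hi")
  if (!is.numeric(density) || density <= 0 || density > 1)
    stop_domain("'density' must be in (0, 1]")
  if (!is.numeric(slope_db_per_octave) || slope_db_per_octave < 0)
    stop_domain("'slope_db_per_octave' must be >= 0")
  structure(
    list(band_lo = band_lo, band_hi = band_hi,
         slope_db_per_octave = slope_db_per_octave,
         amplitude_law = amplitude_law, density = density, seed = seed),
    class = "noise_spec"
  )
}

#' Generate the carrier tones of a band-shaped noise
#'
#' Places one carrier on each retained DFT bin inside the passband, plus the
#' roll-off regions out to where the band-shaping attenuation reaches 60 dB
#' (clipped below Nyquist). Amplitudes are Rayleigh(1) or equal, multiplied by
#' the shaping gain; phases are uniform. Fully deterministic when the spec
#' carries a seed.
#'
#' @param spec A [noise_spec()].
#' @param config A [render_config()]; its sample rate and length set the DFT
#'   grid (bin spacing `sample_rate / n_samples`).
#' @return A [carrier_set()].
#' @examples
#' sp <- noise_spec(400, 3200, amplitude_law = "equal", seed = 1)
#' cs <- generate_noise_carriers(sp, render_config(8000, duration = 0.5))
#' @export
generate_noise_carriers <- function(spec, config) {
  stopifnot(inherits(spec, "noise_spec"), inherits(config, "render_config"))
  sr <- config$sample_rate
  n <- config$n_samples
  df <- sr / n
  if (spec$band_hi >= sr / 2)
    stop_domain("band_hi must be below Nyquist (%g Hz)", sr / 2)

  # region covered: passband widened by the 60-dB roll-off span on each side
  span_oct <- if (spec$slope_db_per_octave > 0)
    60 / spec$slope_db_per_octave else 0
  f_min <- max(df, spec$band_lo / 2^span_oct)
  f_max <- min(sr / 2 - df, spec$band_hi * 2^span_oct)
  bins <- seq(ceiling(f_min / df), floor(f_max / df))
  f <- bins * df
  if (length(f) == 0) stop_domain("no DFT bins fall inside the noise band")

  in_band <- f >= spec$band_lo & f <= spec$band_hi
  if (!any(in_band)) stop_domain("no DFT bins fall inside the passband")
  if (spec$density < 1) {
    stride <- max(1L, as.integer(round(1 / spec$density)))
    sel <- rep(FALSE, length(f))
    ib <- which(in_band)
    sel[ib[seq(1, length(ib), by = stride)]] <- TRUE
    sel[!in_band] <- TRUE  # roll-off skirts keep full density
    f <- f[sel]
    in_band <- in_band[sel]
  }

  gain <- rep(1, length(f))
  below <- f < spec$band_lo
  above <- f > spec$band_hi
  gain[below] <- 10^(-spec$slope_db_per_octave *
                       log2(spec$band_lo / f[below]) / 20)
  gain[above] <- 10^(-spec$slope_db_per_octave *
                       log2(f[above] / spec$band_hi) / 20)

  if (!is.null(spec$seed)) set.seed(spec$seed)
  amp <- switch(spec$amplitude_law,
    rayleigh = sqrt(2 * stats::rexp(length(f))),
    equal = rep(1, length(f)))
  phase <- runif(length(f), 0, 2 * pi)
  carrier_set(f, amp * gain, phase)
}
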