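#' Spectral envelope of a waveform
#'
#' Magnitude of the full-length DFT restricted to an analysis band. For a
#' spectrally modulated (SM) stimulus the modulation envelope is inscribed
#' directly into these magnitudes, so no smoothing is applied by default.
#'
#' @param waveform An `stm_waveform` or numeric vector.
#' @param band Two-element analysis band in Hz (`c(lo, hi)`).
#' @param sample_rate Required when `waveform` is a bare vector.
#' @param smooth Optional odd integer length of a moving-average smoother
#'   applied to the magnitudes; 0 (default) disables smoothing.
#' @return A `spectral_envelope`: list with `frequency` (Hz), `magnitude`
#'   and `band`.
#' @export
spectral_envelope <- function(waveform, band, sample_rate = NULL,
                              smooth = 0) {
  if (inherits(waveform, "stm_waveform")) {
    x <- waveform$samples
    sample_rate <- waveform$sample_rate
  } else {
    x <- as.numeric(waveform)
    if (is.null(sample_rate)) stop_domain("'sample_rate' required")
  }
  if (length(x) < 2) stop_domain("waveform must have at least 2 samples")
  if (length(band) != 2 || band[1] >= band[2] || band[1] < 0)
    stop_domain("'band' must be c(lo, hi) with 0 <= lo < hi")
  n <- length(x)
  freq <- (seq_len(n) - 1) * sample_rate / n
  keep <- freq >= band[1] & freq <= min(band[2], sample_rate / 2)
  if (!any(keep)) stop_domain("analysis band contains no DFT bins")
  mag <- Mod(fft(x))[keep]
  if (smooth > 0) {
    k <- as.integer(smooth)
    if (k %% 2 == 0) k <- k + 1L
    mag <- as.numeric(stats::filter(mag, rep(1 / k, k), sides = 2))
    ok <- !is.na(mag)
    mag <- mag[ok]
    freq <- freq[keep][ok]
    return(structure(list(frequency = freq, magnitude = mag, band = band),
                     class = "spectral_envelope"))
  }
  structure(list(frequency = freq[keep], magnitude = mag, band = band),
            class = "spectral_envelope")
}

#' @export
print.spectral_envelope <- function(x, ...) {
  cat(sprintf("Spectral envelope: %d bins, %g-%g Hz\n",
              length(x$magnitude), min(x$frequency), max(x$frequency)))
  invisible(x)
}

#' @export
plot.spectral_envelope <- function(x, ...) {
  plot(x$frequency, 20 * log10(pmax(x$magnitude, .Machine$double.xmin)),
       type = "l", log = "x", xlab = "frequency (Hz)",
       ylab = "magnitude (dB)", ...)
  invisible(x)
}

env_values <- function(env) {
  E <- if (inherits(env, "spectral_envelope")) env$magnitude
       else as.numeric(env)
  if (length(E) == 0 || anyNA(E) || any(E < 0))
    stop_domain("envelope must be non-negative and non-empty")
  if (all(E == 0)) stop_domain("envelope is identically zero")
  E
}

#' Normalized fourth moment of a spectral envelope
#'
#' `M4 = mean(E^4) / mean(E^2)^2`, a scale-invariant measure of spectral
#' fluctuation strength: 1 for a flat envelope, 2 for Rayleigh-distributed
#' magnitudes, and larger for deeper envelope ripple. By Cauchy-Schwarz,
#' `M4 >= 1` with equality iff the envelope is constant.
#'
#' @param env A `spectral_envelope` or non-negative numeric vector.
#' @return The normalized fourth moment (unitless).
#' @export
normalized_fourth_moment <- function(env) {
  E <- env_values(env)
  mean(E^4) / mean(E^2)^2
}

#' Crest factor of a spectral envelope
#'
#' `CF = max(E) / rms(E)`: the peak-to-RMS ratio of the envelope magnitudes.
#' Sensitive to suppressed or exaggerated spectral peaks; `CF >= 1` with
#' equality iff the envelope is constant.
#'
#' @param env A `spectral_envelope` or non-negative numeric vector.
#' @return The crest factor (unitless).
#' @export
crest_factor <- function(env) {
  E <- env_values(env)
  max(E) / sqrt(mean(E^2))
}

#' Spectrogram power ratio between two waveforms
#'
#' Short-time power spectrograms of two equal-length waveforms and their
#' bin-wise ratio in dB (`10 log10(P1 / P2)`). Bins where both powers fall
#' below `floor_rel` times the overall maximum are masked (`NA`) rather than
#' reported as infinite. Used to visualize how closely a truncated sideband
#' rendering tracks the explicit rendering across time and frequency.
#'
#' @param w1,w2 `stm_waveform`s or numeric vectors of equal length.
#' @param window_len STFT window length in samples (Hann window).
#' @param hop Hop size in samples; default 50% overlap.
#' @param sample_rate Required when inputs are bare vectors.
#' @param floor_rel Relative power floor for masking (default `1e-12`).
#' @return A matrix of dB ratios (frequency x time) with attributes
#'   `frequency` (Hz) and `time` (s); masked cells are `NA`.
#' @export
spectrogram_power_ratio <- function(w1, w2, window_len = 1024,
                                    hop = window_len / 2,
                                    sample_rate = NULL, floor_rel = 1e-12) {
  get_x <- function(w) if (inherits(w, "stm_waveform")) w$samples else
    as.numeric(w)
  if (inherits(w1, "stm_waveform")) sample_rate <- w1$sample_rate
  if (is.null(sample_rate)) stop_domain("'sample_rate' required")
  x1 <- get_x(w1); x2 <- get_x(w2)
  if (length(x1) != length(x2))
    stop_domain("waveforms must have equal length")
  if (length(x1) < window_len)
    stop_domain("waveforms shorter than the analysis window")
  overlap <- window_len - hop
  win <- signal::hanning(window_len)
  sg1 <- signal::specgram(x1, n = window_len, Fs = sample_rate,
                          window = win, overlap = overlap)
  sg2 <- signal::specgram(x2, n = window_len, Fs = sample_rate,
                          window = win, overlap = overlap)
  P1 <- Mod(sg1$S)^2
  P2 <- Mod(sg2$S)^2
  floor_val <- floor_rel * max(max(P1), max(P2))
  ratio <- 10 * log10(P1 / P2)
  ratio[P1 < floor_val & P2 < floor_val] <- NA_real_
  attr(ratio, "frequency") <- as.numeric(sg1$f)
  attr(ratio, "time") <- as.numeric(sg1$t)
  ratio
}
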