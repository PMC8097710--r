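#' Render configuration
#'
#' Sample rate, length and method settings shared by both renderers. The
#' frequency-domain method guarantees exact equivalence with the explicit
#' time-domain evaluation only when every component frequency lies on a DFT
#' bin (`f * duration` integral); `grid_policy` controls what happens
#' otherwise: `"strict"` raises an error, `"quantize"` rounds each component
#' to the nearest bin and reports the worst-case rounding error.
#'
#' @param sample_rate Sampling rate in Hz.
#' @param duration Duration in seconds; used to derive `n_samples` when the
#'   latter is not given.
#' @param n_samples Number of samples (overrides `duration`).
#' @param method `"sideband"` (frequency-domain assembly, one inverse DFT) or
#'   `"explicit"` (per-sample evaluation of the modulator; the reference).
#' @param extent Sideband extent `K`; mutually exclusive with `tolerance_db`.
#' @param tolerance_db Energy-deficiency budget in dB used to choose the
#'   extent via [min_extent_for_tolerance()]. When neither `extent` nor
#'   `tolerance_db` is given the default budget is `1e-4` dB, with the extent
#'   capped at 50.
#' @param grid_policy `"strict"` or `"quantize"`.
#' @param normalize `NULL` for no level scaling (the rendered level is the
#'   faithful expansion level), or a target RMS in dB full scale passed to
#'   [rms_normalize()].
#' @param seed Optional integer seed recorded for downstream stages that draw
#'   random numbers (noise design, sweeps).
#' @return An object of class `"render_config"`.
#' @export
render_config <- function(sample_rate = 44100, duration = 1,
                          n_samples = NULL,
                          method = c("sideband", "explicit"),
                          extent = NULL, tolerance_db = NULL,
                          grid_policy = c("strict", "quantize"),
                          normalize = NULL, seed = NULL) {
  method <- match.arg(method)
  grid_policy <- match.arg(grid_policy)
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop_domain("'sample_rate' must be > 0")
  if (is.null(n_samples)) {
    if (!is.numeric(duration) || duration <= 0)
      stop_domain("'duration' must be > 0 seconds")
    n_samples <- round(duration * sample_rate)
  }
  if (n_samples < 1) stop_domain("'n_samples' must be >= 1")
  if (!is.null(extent) && !is.null(tolerance_db))
    stop_domain("'extent' and 'tolerance_db' are mutually exclusive")
  if (!is.null(tolerance_db) && (!is.numeric(tolerance_db) || tolerance_db <= 0))
    stop_domain("'tolerance_db' must be a positive dB value")
  structure(
    list(sample_rate = as.numeric(sample_rate),
         n_samples = as.integer(n_samples),
         method = method, extent = extent, tolerance_db = tolerance_db,
         grid_policy = grid_policy, normalize = normalize, seed = seed),
    class = "render_config"
  )
}

# resolve the sideband extent for a parameter set under a config:
# explicit K wins, else tolerance, else the default 1e-4 dB budget capped at 50
resolve_extent <- function(params, config) {
  if (params$kind != "exponential") return(1L)
  if (!is.null(config$extent)) return(as.integer(config$extent))
  tol <- config$tolerance_db %||% 1e-4
  min(min_extent_for_tolerance(params$depth, tol), 50L)
}

#' Expand a carrier set into pure-tone components
#'
#' Applies a sideband template to every carrier: each template entry emits a
#' component at `f_n + side * k * rate` with amplitude `A_n * |amp_factor|`
#' and phase `phi_n + env_coeff * Phi(f_n) + quad_phase` (plus `pi` when the
#' amplitude factor is negative). Two degenerate geometries are handled
#' algebraically: with `rate = 0` all entries of a carrier land on `f_n` and
#' are summed as phasors into a single component, and a sideband pushed below
#' 0 Hz is reflected using `sin(2 pi (-f) t + p) = sin(2 pi f t + (pi - p))`
#' (with a warning); a component at exactly 0 Hz reduces to a DC constant and
#' is dropped with a warning.
#'
#' @param carriers A [carrier_set()].
#' @param params A [modulation_params()] whose kind matches the template's.
#' @param template A `sideband_template` from [exponential_template()] or
#'   [linear_template()]; ignored (may be `NULL`) for kind `"none"`.
#' @return A `component_set`: data frame with columns `carrier_index`, `k`,
#'   `side`, `frequency_hz`, `amplitude`, `phase_rad`.
#' @export
expand_carriers <- function(carriers, params, template = NULL) {
  stopifnot(inherits(carriers, "carrier_set"),
            inherits(params, "modulation_params"))
  if (params$kind == "none") {
    out <- data.frame(
      carrier_index = seq_along(carriers$frequency), k = 0L, side = "base",
      frequency_hz = carriers$frequency, amplitude = carriers$amplitude,
      phase_rad = wrap_phase(carriers$phase), stringsAsFactors = FALSE)
    return(structure(out, class = c("component_set", "data.frame")))
  }
  stopifnot(inherits(template, "sideband_template"))
  if (attr(template, "kind") != params$kind)
    stop_domain("template kind '%s' does not match modulator kind '%s'",
                attr(template, "kind"), params$kind)

  N <- length(carriers)
  Phi_n <- envelope_phase(carriers$frequency, params)
  side_sign <- ifelse(template$side == "upper", 1,
                      ifelse(template$side == "lower", -1, 0))

  idx <- rep(seq_len(N), each = nrow(template))
  tk <- rep(template$k, N)
  tside <- rep(template$side, N)
  tamp <- rep(template$amp_factor, N)
  tquad <- rep(template$quad_phase, N)
  tenv <- rep(template$env_coeff, N)
  tsign <- rep(side_sign, N)

  freq <- carriers$frequency[idx] + tsign * tk * params$rate
  amp <- carriers$amplitude[idx] * abs(tamp)
  phase <- carriers$phase[idx] + tenv * Phi_n[idx] + tquad +
    ifelse(tamp < 0, pi, 0)

  if (params$rate == 0) {
    # all sidebands of a carrier coincide with its base frequency: sum phasors
    z <- amp * exp(1i * phase)
    zsum <- vapply(seq_len(N), function(n) sum(z[idx == n]), complex(1))
    out <- data.frame(
      carrier_index = seq_len(N), k = 0L, side = "base",
      frequency_hz = carriers$frequency, amplitude = Mod(zsum),
      phase_rad = wrap_phase(Arg(zsum)), stringsAsFactors = FALSE)
    return(structure(out, class = c("component_set", "data.frame")))
  }

  at_dc <- freq == 0
  if (any(at_dc)) {
    warning(sprintf(
      "%d component(s) at exactly 0 Hz reduce to DC and were dropped",
      sum(at_dc)))
    keep <- !at_dc
    idx <- idx[keep]; tk <- tk[keep]; tside <- tside[keep]
    freq <- freq[keep]; amp <- amp[keep]; phase <- phase[keep]
  }
  neg <- freq < 0
  if (any(neg)) {
    warning(sprintf(
      "%d sideband(s) crossed 0 Hz and were reflected to positive frequency",
      sum(neg)))
    phase[neg] <- pi - phase[neg]
    freq[neg] <- -freq[neg]
  }

  out <- data.frame(
    carrier_index = idx, k = tk, side = tside, frequency_hz = freq,
    amplitude = amp, phase_rad = wrap_phase(phase), stringsAsFactors = FALSE)
  structure(out, class = c("component_set", "data.frame"))
}

wrap_phase <- function(p) {
  w <- (p + pi) %% (2 * pi) - pi
  # keep +pi rather than -pi for the boundary case
  w[w == -pi] <- pi
  w
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("Component set: %d pure-tone components, %g-%g Hz\n",
              nrow(x), min(x$frequency_hz), max(x$frequency_hz)))
  invisible(x)
}

#' Render a component set with a single inverse DFT
#'
#' Accumulates each component `a sin(2 pi f t + p)` as a complex phasor
#' `(a/2) exp(i (p - pi/2))` on its positive-frequency bin (with the
#' conjugate on the mirrored bin) and performs exactly one inverse transform.
#' For on-bin frequencies the result equals the analytic sum of sines to
#' machine precision. Components sharing a bin accumulate.
#'
#' @param components A `component_set` (or data frame with `frequency_hz`,
#'   `amplitude`, `phase_rad`).
#' @param config A [render_config()]; `grid_policy` governs off-bin and
#'   above-Nyquist components.
#' @return An `stm_waveform`: list with `samples`, `sample_rate` and rendering
#'   metadata.
#' @export
render_frequency_domain <- function(components, config) {
  stopifnot(is.data.frame(components), inherits(config, "render_config"))
  n <- config$n_samples
  sr <- config$sample_rate
  Tdur <- n / sr
  f <- components$frequency_hz
  a <- components$amplitude
  p <- components$phase_rad
  if (any(f <= 0)) stop_domain("component frequencies must be > 0")

  bins <- f * Tdur
  rbins <- round(bins)
  off <- abs(bins - rbins)
  if (config$grid_policy == "strict") {
    if (any(off > 1e-9 * pmax(1, bins)))
      stop_domain(paste0(
        "off-bin component under grid_policy 'strict': worst offset ",
        format(max(off / Tdur)), " Hz; use grid_policy 'quantize' or adjust ",
        "frequencies to multiples of 1/duration"))
    if (any(rbins >= n / 2))
      stop_domain("component at or above Nyquist under grid_policy 'strict'")
  } else {
    if (any(off > 0))
      warning(sprintf(
        "quantized %d component(s) to the DFT grid; max rounding error %.4g Hz",
        sum(off > 1e-12), max(off) / Tdur))
    drop <- rbins >= n / 2 | rbins <= 0
    if (any(drop)) {
      warning(sprintf(
        "dropped %d component(s) at/above Nyquist or rounded to DC",
        sum(drop)))
      rbins <- rbins[!drop]; a <- a[!drop]; p <- p[!drop]
    }
  }

  X <- complex(n)
  phasor <- (a / 2) * exp(1i * (p - pi / 2))
  for (grp in split(seq_along(rbins), rbins)) {
    b <- rbins[grp[1]]
    s <- sum(phasor[grp])
    X[b + 1] <- X[b + 1] + s
    X[n - b + 1] <- X[n - b + 1] + Conj(s)
  }
  samples <- Re(fft(X, inverse = TRUE))
  new_waveform(samples, sr, method = "sideband",
               n_components = length(rbins))
}

#' Explicit time-domain rendering (the reference evaluator)
#'
#' Evaluates `S(t) = sum_n A_n sin(2 pi f_n t + phi_n) M(f_n, t)` sample by
#' sample, with the exponential modulator `10^((m/20) sin(2 pi w t + Phi_n))`,
#' the linear modulator `1 + m sin(...)`, or `M = 1`. This is the ground
#' truth against which the sideband renderer is validated; it is orders of
#' magnitude slower for large carrier counts but makes no truncation. Time
#' runs `t = 0 .. (n-1)/sample_rate`, sample-aligned with the DFT renderer.
#'
#' @param carriers A [carrier_set()].
#' @param params A [modulation_params()].
#' @param config A [render_config()].
#' @return An `stm_waveform`.
#' @export
render_explicit <- function(carriers, params, config) {
  stopifnot(inherits(carriers, "carrier_set"),
            inherits(params, "modulation_params"),
            inherits(config, "render_config"))
  n <- config$n_samples
  sr <- config$sample_rate
  f <- carriers$frequency
  a <- carriers$amplitude
  p <- carriers$phase

  if (params$kind == "none") {
    samples <- cpp_tone_sum(f, a, p, n, sr)
  } else if (params$rate == 0) {
    # stationary modulator: M(f_n, t) is constant per carrier, fold it in
    Phi_n <- envelope_phase(f, params)
    const <- if (params$kind == "exponential")
      exp(params$depth$M_prime * sin(Phi_n))
    else 1 + params$depth$m_lin * sin(Phi_n)
    samples <- cpp_tone_sum(f, a * const, p, n, sr)
  } else {
    Phi_n <- envelope_phase(f, params)
    depth_par <- if (params$kind == "exponential")
      params$depth$M_prime else params$depth$m_lin
    kind_code <- if (params$kind == "exponential") 1L else 2L
    samples <- cpp_modulated_sum(f, a, p, Phi_n, depth_par, params$rate,
                                 kind_code, n, sr)
  }
  new_waveform(samples, sr, method = "explicit", n_components = length(f))
}

#' Render a modulated stimulus
#'
#' High-level entry: chooses the sideband extent, expands the carriers, and
#' renders with the method named in the config (frequency-domain sideband
#' assembly or explicit evaluation). Optional RMS normalization is applied
#' identically for both methods.
#'
#' @param carriers A [carrier_set()].
#' @param params A [modulation_params()].
#' @param config A [render_config()].
#' @return An `stm_waveform` with `extent` and `deficiency_db` recorded for
#'   exponential sideband renders.
#' @examples
#' cs <- carrier_set(c(500, 1000, 2000), amplitude = 1,
#'                   phase = c(0.1, 0.5, 1.2))
#' pars <- stm_params(depth = 20, rate = 4, density = 2, f_ref = 500)
#' cfg <- render_config(sample_rate = 8000, duration = 0.5)
#' w <- render_stm(cs, pars, cfg)
#' @export
render_stm <- function(carriers, params, config) {
  stopifnot(inherits(config, "render_config"))
  K <- resolve_extent(params, config)
  if (config$method == "explicit") {
    w <- render_explicit(carriers, params, config)
  } else {
    tpl <- switch(params$kind,
      exponential = exponential_template(params$depth, K),
      linear = linear_template(params$depth),
      none = NULL)
    comps <- expand_carriers(carriers, params, tpl)
    w <- render_frequency_domain(comps, config)
  }
  if (params$kind == "exponential") {
    w$extent <- K
    w$deficiency_db <- energy_deficiency_db(params$depth, K)$deficiency_db
  }
  if (!is.null(config$normalize))
    w <- rms_normalize(w, config$normalize)
  w
}

#' RMS-normalize a waveform
#'
#' Scales the waveform to a target RMS level in dB full scale
#' (`target = -20` gives RMS 0.1). The default rendering pipeline applies no
#' normalization, so levels remain those of the analytic expansion; use this
#' when a fixed presentation level is needed.
#'
#' @param waveform An `stm_waveform` or numeric vector.
#' @param target_dbfs Target RMS level in dB re full scale.
#' @return The same type as the input, rescaled.
#' @export
rms_normalize <- function(waveform, target_dbfs) {
  x <- if (inherits(waveform, "stm_waveform")) waveform$samples else waveform
  r <- sqrt(mean(x^2))
  if (r == 0) stop_domain("cannot RMS-normalize a silent waveform")
  g <- 10^(target_dbfs / 20) / r
  if (inherits(waveform, "stm_waveform")) {
    waveform$samples <- x * g
    waveform
  } else x * g
}

new_waveform <- function(samples, sample_rate, method, n_components = NA) {
  structure(
    list(samples = samples, sample_rate = sample_rate, method = method,
         n_components = n_components, extent = NULL, deficiency_db = NULL),
    class = "stm_waveform"
  )
}

#' @export
print.stm_waveform <- function(x, ...) {
  cat(sprintf(
    "STM waveform: %d samples @ %g Hz (%.3g s), method '%s', RMS %.4g\n",
    length(x$samples), x$sample_rate, length(x$samples) / x$sample_rate,
    x$method, sqrt(mean(x$samples^2))))
  if (!is.null(x$extent))
    cat(sprintf("  sideband extent %d (energy deficiency %.3g dB)\n",
                x$extent, x$deficiency_db))
  invisible(x)
}

#' @export
plot.stm_waveform <- function(x, ...) {
  t <- (seq_along(x$samples) - 1) / x$sample_rate
  plot(t, x$samples, type = "l", xlab = "time (s)", ylab = "amplitude", ...)
  invisible(x)
}
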