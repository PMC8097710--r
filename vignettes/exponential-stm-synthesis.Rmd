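---
title: "Synthesizing exponential spectro-temporal modulation with Bessel sidebands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing exponential spectro-temporal modulation with Bessel sidebands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stmnoise)
```

## The stimulus model

Spectro-temporally modulated (STM) noise — the "moving ripple" stimulus of
psychoacoustics and auditory physiology — is built here as a sum of `N`
stationary carrier tones, each multiplied by a modulator that depends on time
and on the carrier's frequency:

\[
S(t) = \sum_{n=1}^{N} A_n \sin(2\pi f_n t + \phi_n)\, M(f_n, t).
\]

The carrier amplitudes \(A_n\), frequencies \(f_n\) and phases \(\phi_n\)
carry all properties of the underlying noise (band shape, amplitude
statistics); the modulator carries the ripple. Two modulators are supported:

* **linear**: \(M = 1 + m \sin(2\pi\omega t + \Phi(f))\) with
  \(m \in [0, 1)\), and
* **exponential** (sinusoidal *in decibels*):
  \(M = 10^{(m/20)\sin(2\pi\omega t + \Phi(f))}\), where `m` is the
  midpoint-to-peak depth in dB (peak-to-valley depth `2m`).

\(\omega\) is the temporal modulation rate in Hz and
\(\Phi(f) = 2\pi\Omega \log_2(f/f_0) + \Phi_0\) advances the envelope phase by
\(\Omega\) cycles per octave, producing the spectral ripple. Setting
\(\omega = 0\) gives pure spectral modulation (SM), \(\Omega = 0\) pure
temporal modulation (TM).

Because loudness grows with level in dB rather than linear amplitude, the
exponential modulator is usually the scientifically appropriate one — but it
has no finite trigonometric expansion, which historically forced slow
per-sample evaluation. The package's core is the analytic way around this:
writing \(M' = (m/20)\ln 10\), the exponential of a sine expands into a
Fourier series whose coefficients are modified Bessel functions of the first
kind,

\[
e^{M'\sin\Theta} = I_0(M') +
2\sum_{k \text{ even}} (-1)^{k/2} I_k(M') \cos(k\Theta) +
2\sum_{k \text{ odd}} (-1)^{(k-1)/2} I_k(M') \sin(k\Theta),
\]

so each modulated carrier becomes a *base tone* of amplitude
\(A_n I_0(M')\) plus sidebands at \(f_n \pm k\omega\) with amplitudes
\(A_n I_k(M')\) and parity-dependent signs and quadrature.
`exponential_template()` tabulates exactly this transformation; every term is
stored in sine convention (`amplitude * sin(2*pi*f*t + phase)`), cosines as a
`+pi/2` phase offset and negative printed amplitudes as a `+pi` phase shift,
so the emitted component table is unambiguous. With all components known, the
entire stimulus is assembled as complex phasors on a DFT grid and rendered
with **one** inverse FFT (`render_frequency_domain()`), instead of evaluating
an exponential per carrier per sample.

`render_explicit()` keeps the direct per-sample evaluation as the ground
truth; every sideband claim in the test suite is validated against it.

## Choosing the sideband extent

The infinite sideband series must be truncated at some extent `K` (retaining
`2K + 1` terms per carrier). The cost of truncation is quantified by the
**energy deficiency**: the retained fraction of the complete-sum energy,

\[
10\log_{10}\frac{I_0(M')^2 + 2\sum_{k=1}^{K} I_k(M')^2}{I_0(2M')} \le 0
\text{ dB},
\]

where the closed form \(I_0(2M')\) for the complete sum (a Bessel energy
identity, verified numerically in the tests to relative `1e-12`) avoids a
second truncation. Convergence is hyper-exponential: at `m = 40` dB
midpoint-to-peak (an 80-dB peak-to-valley ripple), extent 10 — 21 terms —
already leaves less than `1e-9` dB of energy unaccounted for, and a very
conservative 0.01-dB budget is met by extent 4 for depths up to 40 dB
peak-to-valley:

```{r extent}
energy_deficiency_db(40, 10)
min_extent_for_tolerance(20, 0.01)
```

`min_extent_for_tolerance()` turns a deficiency budget into the smallest
sufficient extent. When the user supplies neither an extent nor a budget the
renderer uses a `1e-4` dB budget capped at `K = 50`: far below any level
difference of perceptual relevance, at negligible cost.

Two caveats that the deficiency number does *not* capture:

* **Waveform error scale.** A deficiency of \(\delta\) dB corresponds to a
  *missing energy fraction* \(\varepsilon = 1 - 10^{\delta/10}\), so the
  sample-level difference from the explicit render has RMS about
  \(\sqrt{\varepsilon}\) of the stimulus RMS — e.g. a `1e-8` dB budget yields
  agreement at the `1e-5`–`1e-4` RMS-relative level, not `1e-8`. The tests
  assert at this energetically consistent scale.
* **Valley accuracy.** Relative accuracy of the *modulator itself* at its
  envelope valley (where it is only \(10^{-m/20}\)) requires a deeper extent
  than the same relative accuracy at the peak, because the truncation
  residual is roughly uniform in absolute terms. A `1e-14` dB budget keeps
  the valley-relative error of the series below `1e-4` at all tested depths
  up to 40 dB.

## Rendering conventions

* **Time origin.** Both renderers evaluate at `t = 0 .. (n-1)/sample_rate`,
  so they are sample-aligned and can be compared sample by sample.
* **Frequency grid.** Exact DFT assembly requires on-bin components
  (`f * duration` integral). `grid_policy = "strict"` (the default, used
  throughout the tests) raises an error otherwise; `"quantize"` (the CLI
  default) rounds to the nearest bin and reports the worst rounding error.
* **Spectrum packing.** A component `a*sin(2*pi*f*t + p)` contributes
  `(a/2)*exp(1i*(p - pi/2))` on its positive-frequency bin and the conjugate
  on the mirror bin; this fixed convention is what makes the inverse
  transform land on the sine convention exactly.
* **Degenerate geometries.** With `rate = 0` (SM) all sidebands of a carrier
  collapse onto `f_n`; they are summed as phasors into a single component,
  whose amplitude approaches \(A_n 10^{(m/20)\sin\Phi(f_n)}\) as `K` grows.
  Sidebands pushed below 0 Hz are reflected
  (`sin(-2*pi*f*t + p) = sin(2*pi*f*t + pi - p)`) rather than dropped, which
  preserves equivalence with the explicit render; a component landing at
  exactly 0 Hz reduces to a DC constant and is dropped, both with warnings.
* **No implicit scaling.** The default pipeline applies no normalization or
  ramping; `rms_normalize()` is available and the CLI exposes it. This keeps
  the rendered level exactly that of the analytic expansion.

## Noise design

`generate_noise_carriers()` builds the classic frequency-domain bandpass
noise: one carrier per DFT bin (maximum density) inside the passband,
amplitudes i.i.d. Rayleigh (scale 1) or equal, phases uniform. Band shaping
is interpreted as unity gain in the passband with a constant dB-per-octave
roll-off outside each edge, truncated where attenuation exceeds 60 dB — the
common psychoacoustic band-shaping reading; both the slope and the law are
configurable rather than asserted. Carrier density below 1 keeps every
`round(1/density)`-th in-band bin — a deterministic stride, chosen over
random thinning so that carrier counts are exact and reproducible.

One practical limitation: if the roll-off skirt reaches Nyquist (e.g. a
3200-Hz band edge with a 32 dB/octave skirt at an 8-kHz sample rate), the
explicit render aliases modulation sidebands of near-Nyquist carriers that
the frequency-domain render drops. This is a band-design artifact, not a
method discrepancy; keep the shaped band clear of Nyquist when comparing
methods.

## Validation metrics and the method sweep

For pure SM the modulation envelope is inscribed directly into the spectrum,
so spectral-envelope statistics compare generation methods cleanly. On the
in-band DFT magnitudes `E` (no smoothing by default), the package computes
the normalized fourth moment \(M_4 = \overline{E^4}/(\overline{E^2})^2\),
a fluctuation-strength measure (1 for a flat envelope, 2 for Rayleigh
magnitudes, larger with deeper ripple), and the crest factor
\(\mathrm{CF} = E_{\text{peak}}/E_{\text{rms}}\). Both are scale- and
permutation-invariant and reach their lower bound 1 only on constant
envelopes.

`run_validation_sweep()` renders SM exemplars at a grid of peak-to-valley
depths with both methods from *shared* random draws (a master seed spawns one
stream per depth-exemplar cell), so the methods can be compared pairwise.
The test suite runs a reduced sweep — 5 depths spanning 0–50 dB
peak-to-valley, 20 exemplars, 0.5 s at 16 kHz — as the package's standard
verification geometry, and checks that per-depth mean \(M_4\) and CF of the
sideband method stay within 1% of the explicit method while both rise
monotonically with depth. The sweep function's own defaults (20 depths, 100
exemplars, 1 s at 44.1 kHz) reproduce the full-scale comparison when more
time is available.

`spectrogram_power_ratio()` compares two renders in time–frequency
(Hann window, 50% hop, window length 1024 by default). STFT parameters
change the numbers, so the associated tests are property-based: identical
inputs give 0 dB everywhere, known gains are recovered exactly, in-band
deviations shrink as the extent grows. Large ratios concentrate where the
*signal* is near zero (modulation valleys, masked floor), which is why the
in-band median — not the maximum — is the stable summary.

## Numerical choices

* Bessel values come from `base::besselI()`; the defining power series is
  kept in the test suite as an independent oracle (agreement to relative
  `1e-12` across orders 0–20 and arguments up to 9.2).
* The deficiency is computed as `10*log10(partial/total)` in double
  precision; both sums are O(1)–O(1e3) in the supported depth range
  (`m <= 40` dB), so the quotient is accurate to ~1e-15 dB, comfortably
  below the smallest asserted deficiency (`1e-9` dB). Depth-monotonicity
  checks allow `1e-12` dB of jitter at the numerical noise floor.
* The explicit renderer's inner loops (carrier x sample, with an `exp` and a
  `sin` per point) are small C++ kernels; for stationary modulators
  (`rate = 0`) the per-carrier constant is folded into the amplitude first.
  The sideband path stays in R: its cost is one `stats::fft()`.
* Phases are wrapped to `(-pi, pi]` in component tables; upper/lower
  sideband magnitudes are identical by construction, so the tables satisfy
  the symmetry the expansion demands exactly.

## Known limitations

* Only sinusoidal (in dB or linear amplitude) envelopes are expanded;
  arbitrary envelope shapes are out of scope.
* Exact single-FFT rendering presumes on-bin components; off-grid frequency
  content is only approximated (quantized) with a reported error.
* Depths far beyond 40 dB midpoint-to-peak inflate \(I_0(2M')\) rapidly;
  the implementation is untested past that range.
* The synthetic noise generator emulates stationary, uncorrelated-tone
  bandpass noise; it does not model correlated carriers, non-Rayleigh
  amplitude statistics beyond the equal-amplitude law, or time-varying
  carrier populations, so passing sweeps demonstrate method equivalence on
  this family, not on arbitrary natural signals.
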