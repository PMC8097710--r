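# stmnoise

Synthesis of noise with **exponential spectro-temporal modulation** (STM) —
"moving ripple" stimuli whose level varies sinusoidally *in decibels* across
time and log-frequency — for psychoacoustics and auditory-physiology
experiments that need deep, precisely specified ripples generated quickly and
reproducibly.

## The method

A multi-tone noise is modulated carrier by carrier:

    S(t) = sum_n A_n sin(2 pi f_n t + phi_n) * M(f_n, t)

with the exponential modulator

    M(f, t) = 10^((m/20) sin(2 pi w t + Phi(f))),
    Phi(f)  = 2 pi Omega log2(f / f0) + Phi0,

where `m` is the midpoint-to-peak depth in dB (peak-to-valley `2m`), `w` the
temporal rate in Hz and `Omega` the spectral density in cycles/octave.
Because sensitivity to sound intensity is logarithmic, this dB-sinusoidal
envelope is usually what an experiment needs — but evaluated naively it costs
an exponential per carrier per sample.

The package instead expands each modulated carrier analytically. With
`M' = (m/20) ln 10`, the exponential-of-sine is a Fourier series whose
coefficients are modified Bessel functions of the first kind, so each carrier
becomes a base tone of amplitude `A_n I_0(M')` plus sidebands at
`f_n ± k w` with amplitudes `A_n I_k(M')` (parity-dependent signs and
quadrature). All components are accumulated on a DFT grid and the entire
stimulus — thousands of carriers, arbitrary depth — is rendered with a
**single inverse FFT**. The series converges hyper-exponentially: the energy
omitted by truncating at extent `K` is

    10 log10( [I_0(M')^2 + 2 sum_{k<=K} I_k(M')^2] / I_0(2M') )  dB,

and at `m = 40` dB (80 dB peak-to-valley) extent 10 already leaves under
`1e-9` dB unaccounted for. An explicit time-domain renderer is included as
the ground-truth reference, along with spectral-envelope validation metrics
(normalized fourth moment `M4 = mean(E^4)/mean(E^2)^2`, crest factor
`max(E)/rms(E)`) and band-shaped Rayleigh-amplitude noise design.

## Worked example

```r
library(stmnoise)

carriers <- generate_noise_carriers(
  noise_spec(400, 3200, amplitude_law = "rayleigh", seed = 1),
  render_config(sample_rate = 44100, duration = 0.5))
params <- stm_params(depth = 20, rate = 4, density = 2, f_ref = 400)

K <- min_extent_for_tolerance(20, 1e-6)        # extent for a 1e-6 dB budget
cfg <- render_config(sample_rate = 44100, duration = 0.5, extent = K)
w <- render_stm(carriers, params, cfg)
w

cfg$method <- "explicit"
w_ref <- render_stm(carriers, params, cfg)
max(abs(w$samples - w_ref$samples)) / sqrt(mean(w_ref$samples^2))

write_wav(rms_normalize(w, -20), "stm.wav")
```

Output:

```
STM waveform: 22050 samples @ 44100 Hz (0.5 s), method 'sideband', RMS 176.7
  sideband extent 6 (energy deficiency -1.82e-07 dB)
[1] 0.000759...
```

The 5814-carrier, 40-dB peak-to-valley ripple renders through one inverse
FFT; the recorded energy deficiency says extent 6 omits only `1.8e-7` dB of
sideband energy, and the direct sample-by-sample comparison with the explicit
render confirms agreement at the corresponding amplitude scale
(`7.6e-4` of the stimulus RMS — the square root of the omitted energy
fraction, times the error signal's crest). A deeper extent shrinks it
hyper-exponentially.

## Command line

A thin launcher wraps the same functions (`inst/cli/stmnoise.R`; after
installation, `Rscript $(Rscript -e 'cat(system.file("cli/stmnoise.R", package="stmnoise"))')`):

```sh
stmnoise generate --depth-db 20 --rate 4 --density-cpo 2 \
    --dur 1.0 --sr 44100 --seed 1 --out stm.wav --components-csv comps.csv
stmnoise converge --depths 5,10,20,40 --max-extent 15 --out convergence.csv
stmnoise sweep    --depths-pv 0,12.5,25,37.5,50 --exemplars 20 --out sweep.csv
stmnoise compare  --depth-db 20 --rate 4 --slope 0 --out ratio.csv
```

WAV output is 32-bit float by default (`--pcm16` for integer PCM with
clipping protection); every run is reproducible from `--seed`, and each
`generate` logs the extent and energy deficiency actually used.

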