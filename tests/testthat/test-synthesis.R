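test_that("envelope phase follows the octave-scaled ripple law", {
  p <- sm_params(20, density = 1, phase0 = 0.4, f_ref = 400)
  expect_equal(envelope_phase(400, p), 0.4)              # log2(1) = 0
  expect_equal(envelope_phase(800, p), 0.4 + 2 * pi)     # one octave, one cycle
  p0 <- tm_params(20, rate = 4, phase0 = 1.3)
  expect_equal(envelope_phase(c(100, 1000, 9000), p0), rep(1.3, 3))  # TM
  expect_error(envelope_phase(0, p), class = "stm_domain_error")
  expect_error(envelope_phase(-5, p), class = "stm_domain_error")
})

test_that("carrier expansion covers the degenerate modulator geometries", {
  cs <- carrier_set(c(500, 1000), c(1, 0.5), c(0.2, 0.9))

  # no modulation: components are the carriers themselves
  comps0 <- expand_carriers(cs, modulation_params("none"))
  expect_equal(comps0$frequency_hz, cs$frequency)
  expect_equal(comps0$amplitude, cs$amplitude)
  expect_equal(comps0$phase_rad, cs$phase)

  # linear modulation: exactly three components per carrier
  pl <- modulation_params("linear", 0.5, rate = 4, density = 1, f_ref = 500)
  compsl <- expand_carriers(cs, pl, linear_template(0.5))
  expect_equal(nrow(compsl), 6)
  one <- compsl[compsl$carrier_index == 1, ]
  expect_setequal(one$frequency_hz, c(500, 504, 496))
  expect_equal(sort(one$amplitude), c(0.25, 0.25, 1))

  # pure SM (rate 0): sidebands collapse into one phasor per carrier whose
  # amplitude approaches A * 10^((m/20) sin Phi) as the extent grows
  ps <- sm_params(20, density = 2, phase0 = 0.7, f_ref = 500)
  compss <- expand_carriers(cs, ps, exponential_template(20, 30))
  expect_equal(nrow(compss), 2)
  Phi <- envelope_phase(cs$frequency, ps)
  expect_equal(compss$amplitude, cs$amplitude * 10^(sin(Phi)),
               tolerance = 1e-9)
})

test_that("sidebands crossing 0 Hz are reflected without breaking the oracle", {
  # carrier low enough that k >= 4 lower sidebands go negative
  cs <- carrier_set(30, 1, 0.4)
  params <- stm_params(20, rate = 8, density = 0, phase0 = 0.9, f_ref = 30)
  cfg <- render_config(sample_rate = 512, duration = 1, extent = 7)
  tpl <- exponential_template(20, 7)
  expect_warning(comps <- expand_carriers(cs, params, tpl),
                 "reflected")
  expect_true(all(comps$frequency_hz > 0))
  w_sb <- render_frequency_domain(comps, cfg)
  cfg$method <- "explicit"
  w_ex <- render_explicit(cs, params, cfg)
  rms <- sqrt(mean(w_ex$samples^2))
  expect_lt(max(abs(w_sb$samples - w_ex$samples)), 1e-3 * rms)

  # a sideband landing exactly on 0 Hz reduces to DC and is dropped
  cs0 <- carrier_set(16, 1, 0)
  params0 <- stm_params(10, rate = 8, density = 0, phase0 = 0.2, f_ref = 16)
  expect_warning(expand_carriers(cs0, params0, exponential_template(10, 2)),
                 "0 Hz")
})

test_that("frequency-domain rendering reproduces on-bin sines exactly", {
  cfg <- render_config(sample_rate = 256, n_samples = 256)
  t <- (0:255) / 256
  comp <- data.frame(frequency_hz = 5, amplitude = 1, phase_rad = 0)
  w <- render_frequency_domain(comp, cfg)
  expect_lt(max(abs(w$samples - sin(2 * pi * 5 * t))), 1e-12)

  # arbitrary amplitude and phase, including a cosine-phase component
  comp2 <- data.frame(frequency_hz = c(5, 12), amplitude = c(0.7, 0.3),
                      phase_rad = c(1.1, pi / 2))
  w2 <- render_frequency_domain(comp2, cfg)
  ref <- 0.7 * sin(2 * pi * 5 * t + 1.1) + 0.3 * cos(2 * pi * 12 * t)
  expect_lt(max(abs(w2$samples - ref)), 1e-12)

  # Parseval: mean square equals sum(a^2)/2 for distinct on-bin components
  set.seed(42)
  comp3 <- data.frame(frequency_hz = sample(1:127, 30),
                      amplitude = runif(30), phase_rad = runif(30, 0, 2 * pi))
  w3 <- render_frequency_domain(comp3, cfg)
  expect_equal(mean(w3$samples^2), sum(comp3$amplitude^2) / 2,
               tolerance = 1e-10)
})

test_that("grid policy governs off-bin and above-Nyquist components", {
  cfg <- render_config(sample_rate = 256, n_samples = 256,
                       grid_policy = "strict")
  off <- data.frame(frequency_hz = 5.3, amplitude = 1, phase_rad = 0)
  expect_error(render_frequency_domain(off, cfg), class = "stm_domain_error")
  nyq <- data.frame(frequency_hz = 128, amplitude = 1, phase_rad = 0)
  expect_error(render_frequency_domain(nyq, cfg), class = "stm_domain_error")

  cfgq <- render_config(sample_rate = 256, n_samples = 256,
                        grid_policy = "quantize")
  expect_warning(wq <- render_frequency_domain(off, cfgq), "quantized")
  t <- (0:255) / 256
  expect_lt(max(abs(wq$samples - sin(2 * pi * 5 * t))), 1e-12)
  expect_warning(render_frequency_domain(nyq, cfgq), "dropped")
})

test_that("sideband rendering matches the explicit oracle within the truncation budget", {
  # seeded random draws; extent chosen for a 1e-8 dB energy deficiency. The
  # omitted-sideband energy fraction is then eps = 1 - 10^(-1e-9) ~ 2.3e-9,
  # which bounds the RMS of the waveform difference by sqrt(eps) ~ 5e-5 of
  # the stimulus RMS; the peak difference carries an extra crest factor
  set.seed(101)
  for (i in 1:8) {
    case <- draw_onbin_case(sr = 4096, duration = 1, max_carriers = 30)
    K <- min_extent_for_tolerance(case$params$depth, 1e-8)
    cfg <- render_config(sample_rate = 4096, duration = 1, extent = K)
    w_sb <- suppressWarnings(render_stm(case$carriers, case$params, cfg))
    cfg$method <- "explicit"
    w_ex <- render_stm(case$carriers, case$params, cfg)
    rms <- sqrt(mean(w_ex$samples^2))
    diff <- w_sb$samples - w_ex$samples
    expect_lt(sqrt(mean(diff^2)), 1e-4 * rms)
    expect_lt(max(abs(diff)), 1e-3 * rms)
  }
  # a deficiency budget of 1e-13 dB drives the agreement below 1e-6 * RMS
  set.seed(202)
  case <- draw_onbin_case(sr = 4096, duration = 1, max_carriers = 20,
                          max_m = 30)
  K <- min_extent_for_tolerance(case$params$depth, 1e-13)
  cfg <- render_config(sample_rate = 4096, duration = 1, extent = K)
  w_sb <- suppressWarnings(render_stm(case$carriers, case$params, cfg))
  cfg$method <- "explicit"
  w_ex <- render_stm(case$carriers, case$params, cfg)
  expect_lt(max(abs(w_sb$samples - w_ex$samples)),
            1e-6 * sqrt(mean(w_ex$samples^2)))
})

test_that("waveform error decreases strictly with sideband extent", {
  cs <- carrier_set(1000, 1, 0.3)
  params <- stm_params(20, rate = 4, density = 1, f_ref = 1000)
  errs <- sapply(c(1, 2, 4, 8, 16), function(K) {
    cfg <- render_config(sample_rate = 4096, duration = 1, extent = K)
    w_sb <- render_stm(cs, params, cfg)
    cfg$method <- "explicit"
    w_ex <- render_stm(cs, params, cfg)
    max(abs(w_sb$samples - w_ex$samples))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("explicit rendering agrees with a plain-R evaluation of the modulator", {
  cs <- carrier_set(c(200, 500, 900), c(1, 0.4, 0.7), c(0, 1, 2))
  params <- stm_params(15, rate = 6, density = 1.5, phase0 = 0.3, f_ref = 200)
  cfg <- render_config(sample_rate = 4096, duration = 0.5)
  cfg$method <- "explicit"
  w <- render_explicit(cs, params, cfg)
  Phi <- envelope_phase(cs$frequency, params)
  ref <- oracle_explicit_waveform(cs, 15, 6, Phi, cfg$n_samples, 4096)
  expect_equal(w$samples, ref, tolerance = 1e-12)
  # m = 0 leaves the carrier sum unmodified
  p0 <- stm_params(0, rate = 6, density = 1.5, f_ref = 200)
  w0 <- render_explicit(cs, p0, cfg)
  t <- (seq_len(cfg$n_samples) - 1) / 4096
  bare <- rowSums(sapply(1:3, function(i)
    cs$amplitude[i] * sin(2 * pi * cs$frequency[i] * t + cs$phase[i])))
  expect_equal(w0$samples, bare, tolerance = 1e-12)
})

test_that("rendering is linear in the carrier amplitudes", {
  set.seed(7)
  case <- draw_onbin_case(sr = 2048, duration = 1, max_carriers = 10)
  cfg <- render_config(sample_rate = 2048, duration = 1, extent = 8)
  w1 <- suppressWarnings(render_stm(case$carriers, case$params, cfg))
  doubled <- carrier_set(case$carriers$frequency, 2 * case$carriers$amplitude,
                         case$carriers$phase)
  w2 <- suppressWarnings(render_stm(doubled, case$params, cfg))
  expect_equal(w2$samples, 2 * w1$samples, tolerance = 1e-12)
})

test_that("RMS normalization scales to target and rejects silence", {
  x <- sin(2 * pi * 3 * (0:999) / 1000)
  y <- rms_normalize(x, -20)
  expect_equal(sqrt(mean(y^2)), 0.1, tolerance = 1e-12)
  # scale invariance: normalizing any rescaling gives the same output
  expect_equal(rms_normalize(5 * x, -20), y, tolerance = 1e-12)
  expect_error(rms_normalize(numeric(10), -20), class = "stm_domain_error")
})
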