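# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Power-series evaluation of the modified Bessel function of the first kind
# for integer order: (z/2)^nu * sum_k z^(2k) / (2^(2k) k! (nu+k)!),
# terms added until the next term falls below 1e-16 of the running sum.
oracle_bessel_series <- function(nu, z) {
  if (z == 0) return(if (nu == 0) 1 else 0)
  term <- (z / 2)^nu / factorial(nu)
  total <- term
  k <- 0
  repeat {
    k <- k + 1
    term <- term * (z / 2)^2 / (k * (nu + k))
    total <- total + term
    if (abs(term) < 1e-16 * abs(total)) break
  }
  total
}

# Direct evaluation of the exponential modulator at envelope angle theta.
oracle_exp_modulator <- function(theta, m_db) {
  10^((m_db / 20) * sin(theta))
}

# Direct per-sample evaluation of a modulated carrier sum in plain R,
# independent of the compiled kernels.
oracle_explicit_waveform <- function(carriers, m_db, omega, Phi_n, n, sr) {
  t <- (seq_len(n) - 1) / sr
  out <- numeric(n)
  for (i in seq_along(carriers$frequency)) {
    mod <- 10^((m_db / 20) * sin(2 * pi * omega * t + Phi_n[i]))
    out <- out + carriers$amplitude[i] *
      sin(2 * pi * carriers$frequency[i] * t + carriers$phase[i]) * mod
  }
  out
}

# Random on-bin STM parameter draw used by the oracle-equivalence tests.
# All frequencies are integer multiples of 1/duration so the frequency-domain
# path is exact.
draw_onbin_case <- function(sr, duration, max_carriers = 50, max_m = 40) {
  n_bins <- sr * duration
  nc <- sample(3:max_carriers, 1)
  f <- sort(sample(seq(50, sr / 2 - 100), nc)) / duration
  carriers <- carrier_set(f, amplitude = runif(nc, 0.2, 1),
                          phase = runif(nc, 0, 2 * pi))
  m <- runif(1, 1, max_m)
  omega <- sample(1:8, 1) / duration
  params <- stm_params(m, rate = omega, density = runif(1, 0, 3),
                       phase0 = runif(1, 0, 2 * pi), f_ref = min(f))
  list(carriers = carriers, params = params)
}
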