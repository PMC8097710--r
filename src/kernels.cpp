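#include <Rcpp.h>
using namespace Rcpp;

// Sum of pure tones: sum_c a_c * sin(2*pi*f_c*t + p_c) on t = j/sr.
// [[Rcpp::export]]
NumericVector cpp_tone_sum(NumericVector freq, NumericVector amp,
                           NumericVector phase, int n, double sample_rate) {
  NumericVector out(n);
  const double two_pi = 2.0 * M_PI;
  const int nc = freq.size();
  for (int c = 0; c < nc; ++c) {
    const double a = amp[c], p = phase[c], f = freq[c];
    for (int j = 0; j < n; ++j) {
      const double t = (double)j / sample_rate;
      out[j] += a * std::sin(two_pi * f * t + p);
    }
  }
  return out;
}

// Explicit modulated sum: per-sample evaluation of
//   sum_c a_c sin(2*pi*f_c*t + p_c) * M(f_c, t)
// with M = exp(depth * sin(2*pi*omega*t + Phi_c))  (kind 1, depth = M')
// or   M = 1 + depth * sin(2*pi*omega*t + Phi_c)   (kind 2, depth = m_lin).
// [[Rcpp::export]]
NumericVector cpp_modulated_sum(NumericVector freq, NumericVector amp,
                                NumericVector phase, NumericVector env_phase,
                                double depth, double omega, int kind,
                                int n, double sample_rate) {
  NumericVector out(n);
  const double two_pi = 2.0 * M_PI;
  const int nc = freq.size();
  for (int c = 0; c < nc; ++c) {
    const double a = amp[c], p = phase[c], f = freq[c], Phi = env_phase[c];
    for (int j = 0; j < n; ++j) {
      const double t = (double)j / sample_rate;
      const double th = two_pi * omega * t + Phi;
      const double mod = (kind == 1) ? std::exp(depth * std::sin(th))
                                     : 1.0 + depth * std::sin(th);
      out[j] += a * std::sin(two_pi * f * t + p) * mod;
    }
  }
  return out;
}
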