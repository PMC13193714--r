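#include <Rcpp.h>
using namespace Rcpp;

// Per-sample synthesis of the two fluorescence channels.
//
// Both bleach decays and the Ornstein-Uhlenbeck motion artifact obey
// exact one-step recursions on the uniform grid, so the whole session is
// a single O(n) pass:
//   bleach[i]  = bleach[i-1] * exp(-dt/tau)
//   motion[i]  = a * motion[i-1] + sd * sqrt(1-a^2) * N(0,1),
//     a = exp(-dt/tau_m), motion[0] ~ N(0, sd^2)  (stationary start)
// Draws come from R's RNG, so results are reproducible under set.seed().
//
// [[Rcpp::export]]
List sim_channels_cpp(int n, double dt,
                      NumericVector bleach_level, NumericVector bleach_tau,
                      double motion_sd, double motion_tau,
                      NumericVector noise_sd, double coupling,
                      NumericVector dff_pct) {
  NumericVector f465(n), f405(n), motion(n), bleach_s(n), bleach_i(n);
  const double as = std::exp(-dt / bleach_tau[0]);
  const double ai = std::exp(-dt / bleach_tau[1]);
  const double am = std::exp(-dt / motion_tau);
  const double msd = motion_sd * std::sqrt(1.0 - am * am);
  const double ns = noise_sd[0], ni = noise_sd[1];
  const bool has_motion = motion_sd > 0.0;
  const bool has_ns = ns > 0.0, has_ni = ni > 0.0;

  double bs = bleach_level[0], bi = bleach_level[1];
  double m = has_motion ? norm_rand() * motion_sd : 0.0;

  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      bs *= as;
      bi *= ai;
      if (has_motion) m = am * m + msd * norm_rand();
    }
    bleach_s[i] = bs;
    bleach_i[i] = bi;
    motion[i] = m;
    double e465 = has_ns ? ns * norm_rand() : 0.0;
    double e405 = has_ni ? ni * norm_rand() : 0.0;
    f465[i] = bs * (1.0 + dff_pct[i] / 100.0) + m + e465;
    f405[i] = bi + coupling * m + e405;
  }
  return List::create(_["f465"] = f465, _["f405"] = f405,
                      _["motion"] = motion, _["bleach_s"] = bleach_s,
                      _["bleach_i"] = bleach_i);
}
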