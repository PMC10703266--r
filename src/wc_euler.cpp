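#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integration of the two-population Wilson-Cowan system
//   tau dE/dt = -E + S(rho_e + c E - a I + k Stim)
//   tau dI/dt = -I + S(rho_i + b E - g I)
// with optional first-order adaptation of the excitatory tonic input,
//   d rho_e/dt = -adapt_rate (rho_e - rho0(t)).
//
// `stim` and `rho0` are sampled on the dt grid; length-1 vectors are treated
// as constants so silent runs do not allocate n_steps doubles. State is
// recorded every `record_every` steps (sample 0 first).
//
// [[Rcpp::export]]
List wc_euler_cpp(int n_steps, double dt,
                  double a, double b, double c, double g,
                  double tau, double k,
                  double rho_i, double rho_e0,
                  NumericVector stim, NumericVector rho0,
                  double adapt_rate,
                  double E0, double I0,
                  int record_every) {
  const bool stim_const = (stim.size() == 1);
  const bool rho0_const = (rho0.size() == 1);
  if (!stim_const && stim.size() < n_steps)
    stop("`stim` must have length 1 or at least n_steps");
  if (!rho0_const && rho0.size() < n_steps)
    stop("`rho0` must have length 1 or at least n_steps");

  const int n_rec = (n_steps - 1) / record_every + 1;
  NumericVector Erec(n_rec), Irec(n_rec), Rrec(n_rec);

  double E = E0, I = I0, rho_e = rho_e0;
  const double inv_tau = 1.0 / tau;
  int j = 0;
  for (int i = 0; i < n_steps; ++i) {
    if (i % record_every == 0) {
      Erec[j] = E; Irec[j] = I; Rrec[j] = rho_e;
      ++j;
    }
    const double s  = stim_const ? stim[0] : stim[i];
    const double r0 = rho0_const ? rho0[0] : rho0[i];
    const double xe = rho_e + c * E - a * I + k * s;
    const double xi = rho_i + b * E - g * I;
    const double dE = (-E + 1.0 / (1.0 + std::exp(-xe))) * inv_tau;
    const double dI = (-I + 1.0 / (1.0 + std::exp(-xi))) * inv_tau;
    E += dt * dE;
    I += dt * dI;
    if (adapt_rate > 0.0) rho_e += dt * (-adapt_rate * (rho_e - r0));
    if (!std::isfinite(E) || !std::isfinite(I))
      stop("state diverged at step %d (t = %.4f s)", i, i * dt);
  }
  return List::create(_["E"] = Erec, _["I"] = Irec, _["rho_e"] = Rrec,
                      _["E_final"] = E, _["I_final"] = I,
                      _["rho_e_final"] = rho_e);
}
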