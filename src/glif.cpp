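#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler simulation of the GLIF model with spike-triggered adaptation
// current and moving threshold.
//
// Membrane:   C dV/dt = -gL (V - EL) - sum_j eta(t - t_j) + I(t)
// Intensity:  lambda(t) = lambda0 * exp((V - VT(t)) / deltaV)   [Hz]
// Threshold:  VT(t) = VT_star + sum_j gamma(t - t_j)
// Spike in a step of dt with probability 1 - exp(-lambda dt).
//
// eta_kern / gamma_kern are the kernels sampled at elapsed times m*dt,
// m = 1..L (a spike contributes from the following sample onward). After a
// spike V is clamped to V_reset for t_ref ms and integration resumes from
// V_reset. Uses R's RNG so results are reproducible under set.seed().
//
// [[Rcpp::export]]
List glif_forward_cpp(NumericVector I, double dt, double C, double gL,
                      double EL, double V_reset, double VT_star,
                      double deltaV, double lambda0, double t_ref,
                      NumericVector eta_kern, NumericVector gamma_kern,
                      double V0, bool return_threshold) {
  const int n = I.size();
  const int n_ref = (int) std::ceil(t_ref / dt);
  NumericVector V(n), eta_sum(n);
  NumericVector VT;
  std::vector<double> gamma_sum;
  if (return_threshold) VT = NumericVector(n);
  gamma_sum.assign(n, 0.0);
  std::vector<int> spikes;
  const int Le = eta_kern.size(), Lg = gamma_kern.size();
  const double dt_s = dt / 1000.0; // lambda is in Hz
  double v = V0;
  int ref_until = -1;
  bool rate_warned = false;

  for (int t = 0; t < n; ++t) {
    if (t <= ref_until) {
      v = V_reset;
      V[t] = v;
      if (return_threshold) VT[t] = VT_star + gamma_sum[t];
      // integration resumes from V_reset at the end of the clamp window
      if (t == ref_until)
        v += dt * (-gL * (v - EL) - eta_sum[t] + I[t]) / C;
      continue;
    }
    V[t] = v;
    double thr = VT_star + gamma_sum[t];
    if (return_threshold) VT[t] = thr;
    double lam = lambda0 * std::exp((v - thr) / deltaV);
    double p = lam * dt_s;
    if (p > 0.2 && !rate_warned) rate_warned = true;
    if (p > 0) {
      double ps = 1.0 - std::exp(-p);
      if (unif_rand() < ps) {
        spikes.push_back(t);
        ref_until = t + n_ref;
        // deposit kernels from the next sample onward
        for (int m = 1; m <= Le && t + m < n; ++m)
          eta_sum[t + m] += eta_kern[m - 1];
        for (int m = 1; m <= Lg && t + m < n; ++m)
          gamma_sum[t + m] += gamma_kern[m - 1];
        v = V_reset;
        continue;
      }
    }
    // Euler step (ms units: gL [nS], C [pF] -> gL/C in 1/ms when nS/pF)
    v += dt * (-gL * (v - EL) - eta_sum[t] + I[t]) / C;
  }

  List out = List::create(_["V"] = V,
                          _["spike_idx"] = wrap(spikes),
                          _["eta_sum"] = eta_sum,
                          _["rate_warning"] = rate_warned);
  if (return_threshold) out["VT"] = VT;
  return out;
}

// Deterministic subthreshold integration of the GLIF membrane equation
// given observed spike times: between spikes forward Euler, at each spike
// the voltage is clamped to V_reset for t_ref and integration resumes.
// Used by the threshold-fitting step and the subthreshold R^2.
//
// [[Rcpp::export]]
NumericVector glif_subthreshold_cpp(NumericVector I, double dt, double C,
                                    double gL, double EL, double V_reset,
                                    double t_ref, IntegerVector spike_idx,
                                    NumericVector eta_kern, double V0) {
  const int n = I.size();
  const int n_ref = (int) std::ceil(t_ref / dt);
  NumericVector V(n);
  std::vector<double> eta_sum(n, 0.0);
  const int Le = eta_kern.size();
  for (int j = 0; j < spike_idx.size(); ++j) {
    int s = spike_idx[j];
    for (int m = 1; m <= Le && s + m < n; ++m)
      eta_sum[s + m] += eta_kern[m - 1];
  }
  double v = V0;
  int k = 0, nspk = spike_idx.size();
  int ref_until = -1;
  for (int t = 0; t < n; ++t) {
    if (k < nspk && t == spike_idx[k]) {
      V[t] = v;              // value at the spike sample is pre-reset
      ref_until = t + n_ref;
      v = V_reset;
      ++k;
      continue;
    }
    if (t <= ref_until) {
      v = V_reset; V[t] = v;
      if (t == ref_until)
        v += dt * (-gL * (v - EL) - eta_sum[t] + I[t]) / C;
      continue;
    }
    V[t] = v;
    v += dt * (-gL * (v - EL) - eta_sum[t] + I[t]) / C;
  }
  return V;
}

// One-pass sufficient statistics for the threshold Poisson-GLM Newton step:
// given Z (bins x q) and theta, returns sum(exp(Z theta)), Z' exp(..) and,
// if want_hess, the weighted Gram matrix Z' diag(exp(..)) Z.
//
// [[Rcpp::export]]
List poisson_glm_stats_cpp(NumericMatrix Z, NumericVector theta,
                           bool want_hess) {
  const int n = Z.nrow(), q = Z.ncol();
  // column-major passes for cache-friendly access on long thin designs
  std::vector<double> e(n, 0.0);
  const double *z = REAL(Z);
  for (int j = 0; j < q; ++j) {
    const double th = theta[j];
    const double *col = z + (size_t) j * n;
    for (int i = 0; i < n; ++i) e[i] += th * col[i];
  }
  double sum_e = 0.0;
  for (int i = 0; i < n; ++i) { e[i] = std::exp(e[i]); sum_e += e[i]; }
  NumericVector g(q);
  NumericMatrix H(q, q);
  for (int j = 0; j < q; ++j) {
    const double *col = z + (size_t) j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += e[i] * col[i];
    g[j] = s;
  }
  if (want_hess) {
    for (int j = 0; j < q; ++j) {
      const double *cj = z + (size_t) j * n;
      for (int l = j; l < q; ++l) {
        const double *cl = z + (size_t) l * n;
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += e[i] * cj[i] * cl[i];
        H(j, l) = s; H(l, j) = s;
      }
    }
  }
  return List::create(_["sum_exp"] = sum_e, _["zte"] = g, _["hess"] = H);
}
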