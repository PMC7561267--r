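#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Discrete no-flux Laplacian: interior D*(c[j+1]+c[j-1]-2c[j]); at the ends
// the missing neighbour is dropped (zero-flux, conservative: output sums to 0).
static inline void laplacian_noflux_inplace(const std::vector<double>& c,
                                            double D, std::vector<double>& out) {
  const int L = (int)c.size();
  if (L == 1) { out[0] = 0.0; return; }
  out[0] = D * (c[1] - c[0]);
  for (int j = 1; j < L - 1; ++j)
    out[j] = D * (c[j + 1] + c[j - 1] - 2.0 * c[j]);
  out[L - 1] = D * (c[L - 2] - c[L - 1]);
}

struct FHNKinetics {
  double c_th, inh_w, w_slope, w_offset, w_tau;
  inline double f(double c, double w) const {
    return -c * (c - 1.0) * (c - c_th) - inh_w * w;
  }
  inline double g(double c, double w) const {
    return (c - w_slope * w - w_offset) / w_tau;
  }
};

// One classical RK4 step of the full lattice with stimulus current I held
// constant over the step (the pulse is piecewise constant on the time grid).
static void rk4_step(std::vector<double>& c, std::vector<double>& w,
                     const FHNKinetics& kin, double D, double I, double dt,
                     std::vector<double>& lap,
                     std::vector<double>& k1c, std::vector<double>& k1w,
                     std::vector<double>& k2c, std::vector<double>& k2w,
                     std::vector<double>& k3c, std::vector<double>& k3w,
                     std::vector<double>& k4c, std::vector<double>& k4w,
                     std::vector<double>& tc, std::vector<double>& tw) {
  const int L = (int)c.size();
  laplacian_noflux_inplace(c, D, lap);
  for (int j = 0; j < L; ++j) {
    k1c[j] = kin.f(c[j], w[j]) + lap[j] + I;
    k1w[j] = kin.g(c[j], w[j]);
    tc[j] = c[j] + 0.5 * dt * k1c[j];
    tw[j] = w[j] + 0.5 * dt * k1w[j];
  }
  laplacian_noflux_inplace(tc, D, lap);
  for (int j = 0; j < L; ++j) {
    k2c[j] = kin.f(tc[j], tw[j]) + lap[j] + I;
    k2w[j] = kin.g(tc[j], tw[j]);
  }
  for (int j = 0; j < L; ++j) {
    tc[j] = c[j] + 0.5 * dt * k2c[j];
    tw[j] = w[j] + 0.5 * dt * k2w[j];
  }
  laplacian_noflux_inplace(tc, D, lap);
  for (int j = 0; j < L; ++j) {
    k3c[j] = kin.f(tc[j], tw[j]) + lap[j] + I;
    k3w[j] = kin.g(tc[j], tw[j]);
  }
  for (int j = 0; j < L; ++j) {
    tc[j] = c[j] + dt * k3c[j];
    tw[j] = w[j] + dt * k3w[j];
  }
  laplacian_noflux_inplace(tc, D, lap);
  for (int j = 0; j < L; ++j) {
    k4c[j] = kin.f(tc[j], tw[j]) + lap[j] + I;
    k4w[j] = kin.g(tc[j], tw[j]);
  }
  const double h6 = dt / 6.0;
  for (int j = 0; j < L; ++j) {
    c[j] += h6 * (k1c[j] + 2.0 * k2c[j] + 2.0 * k3c[j] + k4c[j]);
    w[j] += h6 * (k1w[j] + 2.0 * k2w[j] + 2.0 * k3w[j] + k4w[j]);
  }
}

//' @noRd
// [[Rcpp::export(name = ".fhn_run_core")]]
List fhn_run_core(NumericVector c0, NumericVector w0,
                  double c_th, double D, double inhibitor_weight,
                  double w_slope, double w_offset, double w_timescale,
                  double dt, double period, double pulse_duration,
                  double amplitude, int n_beats,
                  double alpha, double c_ref, double prev_peak_init,
                  double blowup_bound, bool keep_field) {
  const int L = c0.size();
  FHNKinetics kin{c_th, inhibitor_weight, w_slope, w_offset, w_timescale};

  const int steps_per_beat = (int)std::llround(period / dt);
  const int pulse_steps = (int)std::llround(pulse_duration / dt);
  if (steps_per_beat < 1) stop("pacing period shorter than one time step");
  if (pulse_steps < 1 || pulse_steps >= steps_per_beat)
    stop("pulse duration must lie strictly inside the beat on the time grid");

  std::vector<double> c(c0.begin(), c0.end()), w(w0.begin(), w0.end());
  std::vector<double> lap(L), k1c(L), k1w(L), k2c(L), k2w(L),
      k3c(L), k3w(L), k4c(L), k4w(L), tc(L), tw(L);

  NumericMatrix field(keep_field ? n_beats : 1, keep_field ? L : 1);
  NumericVector gpeaks(n_beats);
  std::vector<double> site_peak(L);

  double prev_peak = prev_peak_init;
  for (int n = 0; n < n_beats; ++n) {
    const double I_amp = amplitude * (1.0 + alpha * (prev_peak - c_ref));
    std::fill(site_peak.begin(), site_peak.end(), -HUGE_VAL);
    double gmax = -HUGE_VAL;
    for (int s = 0; s < steps_per_beat; ++s) {
      const double I = (s < pulse_steps) ? I_amp : 0.0;
      rk4_step(c, w, kin, D, I, dt, lap, k1c, k1w, k2c, k2w,
               k3c, k3w, k4c, k4w, tc, tw);
      double mean = 0.0;
      for (int j = 0; j < L; ++j) {
        const double cj = c[j];
        if (cj > site_peak[j]) site_peak[j] = cj;
        mean += cj;
      }
      mean /= L;
      if (mean > gmax) gmax = mean;
    }
    for (int j = 0; j < L; ++j) {
      if (!(std::fabs(c[j]) < blowup_bound) ||
          !(std::fabs(site_peak[j]) < blowup_bound))
        stop("numerical divergence at beat %d (|c| exceeded %g)", n + 1,
             blowup_bound);
      if (keep_field) field(n, j) = site_peak[j];
    }
    gpeaks[n] = gmax;
    prev_peak = gmax;
  }

  return List::create(_["beat_peak_field"] = keep_field ? field : NumericMatrix(0, 0),
                      _["global_peaks"] = gpeaks,
                      _["c_final"] = NumericVector(c.begin(), c.end()),
                      _["w_final"] = NumericVector(w.begin(), w.end()));
}
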