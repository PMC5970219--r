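#include <Rcpp.h>
using namespace Rcpp;

// Inner loop of the developmental plasticity simulation.
//
// Per step: voltage -> threshold-linear rate -> excitatory update (Hebbian
// with per-synapse uniform multiplicative noise, or homeostatic synaptic
// scaling) -> inhibitory magnitude update -> bounds and L1 normalisation.
// Synaptic noise is drawn from R's RNG (ON weights first, then OFF), so a
// pure-R reference loop with the same seed reproduces the trajectory
// exactly.
//
// rule: 0 = Hebbian (+ noise, + excitatory L1 renormalisation),
//       1 = synaptic scaling (no Hebbian term, no excitatory renorm).
// snap_steps: sorted 1-based step counts after which to record weights
// (0 records the initial state).
// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericMatrix x_on, NumericMatrix x_off,
              NumericVector w_on_e0, NumericVector w_off_e0,
              NumericVector m_on0, NumericVector m_off0,
              double theta, double alpha_e, double alpha_i, double rho,
              double eta_bound, double excit_l1, double inhib_l1,
              double w_min, double w_max, double scaling_factor,
              bool use_inhib, bool plastic_inhib, int rule, int inhib_norm,
              int inhib_rule, IntegerVector snap_steps) {
  const int n_steps = x_on.nrow();
  const int N = x_on.ncol();
  if (x_off.nrow() != n_steps || x_off.ncol() != N)
    stop("ON and OFF trace dimensions differ");

  std::vector<double> w_on_e(w_on_e0.begin(), w_on_e0.end());
  std::vector<double> w_off_e(w_off_e0.begin(), w_off_e0.end());
  std::vector<double> m_on(m_on0.begin(), m_on0.end());
  std::vector<double> m_off(m_off0.begin(), m_off0.end());

  const int n_snap = snap_steps.size();
  NumericMatrix snap_on_e(n_snap, N), snap_off_e(n_snap, N),
      snap_on_i(n_snap, N), snap_off_i(n_snap, N);
  int snap_idx = 0;
  double sum_y = 0.0, scaling_mean = 0.0;
  long scaling_n = 0;

  auto record = [&](int row) {
    for (int i = 0; i < N; ++i) {
      snap_on_e(row, i) = w_on_e[i];
      snap_off_e(row, i) = w_off_e[i];
      snap_on_i(row, i) = -m_on[i];
      snap_off_i(row, i) = -m_off[i];
    }
  };
  while (snap_idx < n_snap && snap_steps[snap_idx] == 0) {
    record(snap_idx);
    ++snap_idx;
  }

  auto renorm_e = [&](std::vector<double>& w) {
    if (rule == 1) return;  // scaling replaces bounding and normalisation
    double s = 0.0;
    for (int i = 0; i < N; ++i) {
      if (w[i] < w_min) w[i] = w_min;
      if (w[i] > w_max) w[i] = w_max;
      s += w[i];
    }
    if (s <= 0.0)
      stop("excitatory weight class collapsed to zero during simulation");
    const double f = excit_l1 / s;
    for (int i = 0; i < N; ++i) w[i] *= f;
  };
  // inhib_norm: 0 = exact L1 (rescale any nonzero class to inhib_l1),
  //             1 = cap (rescale only when the class sum exceeds inhib_l1,
  //                 so inhibition grows gradually from its zero init)
  auto renorm_i = [&](std::vector<double>& m) {
    double s = 0.0;
    for (int i = 0; i < N; ++i) s += m[i];
    if (s <= 0.0) return;
    if (inhib_norm == 1 && s <= inhib_l1) return;
    const double f = inhib_l1 / s;
    for (int i = 0; i < N; ++i) m[i] *= f;
  };

  for (int t = 0; t < n_steps; ++t) {
    // membrane voltage and rate
    double u = 0.0;
    for (int i = 0; i < N; ++i) {
      const double xo = x_on(t, i), xf = x_off(t, i);
      u += w_on_e[i] * xo + w_off_e[i] * xf;
      if (use_inhib) u -= m_on[i] * xo + m_off[i] * xf;
    }
    const double y = (u > theta) ? (u - theta) : 0.0;
    sum_y += y;

    if (rule == 0) {
      for (int i = 0; i < N; ++i)
        w_on_e[i] += alpha_e * x_on(t, i) * y +
            R::runif(-eta_bound, eta_bound) * w_on_e[i];
      for (int i = 0; i < N; ++i)
        w_off_e[i] += alpha_e * x_off(t, i) * y +
            R::runif(-eta_bound, eta_bound) * w_off_e[i];
    } else {
      double fac = 1.0;
      if (y > scaling_mean) fac = 1.0 - scaling_factor;
      else if (y < scaling_mean) fac = 1.0 + scaling_factor;
      for (int i = 0; i < N; ++i) {
        w_on_e[i] *= fac;
        w_off_e[i] *= fac;
      }
      ++scaling_n;
      scaling_mean += (y - scaling_mean) / scaling_n;
    }

    if (use_inhib && plastic_inhib) {
      // inhib_rule 0 ("magnitude"): magnitudes grow when y > rho
      // (co-tuning); 1 ("literal"): the printed update applied to the
      // negative weights, so inhibition withdraws from channels that
      // drive firing (sideband inhibition).
      const double sgn = (inhib_rule == 0) ? 1.0 : -1.0;
      for (int i = 0; i < N; ++i) {
        m_on[i] += sgn * alpha_i * x_on(t, i) * (y - rho);
        if (m_on[i] < 0.0) m_on[i] = 0.0;
        m_off[i] += sgn * alpha_i * x_off(t, i) * (y - rho);
        if (m_off[i] < 0.0) m_off[i] = 0.0;
      }
    }

    renorm_e(w_on_e);
    renorm_e(w_off_e);
    if (use_inhib && plastic_inhib) {
      renorm_i(m_on);
      renorm_i(m_off);
    }

    while (snap_idx < n_snap && snap_steps[snap_idx] == t + 1) {
      record(snap_idx);
      ++snap_idx;
    }
  }

  return List::create(
      _["w_on_e"] = NumericVector(w_on_e.begin(), w_on_e.end()),
      _["w_off_e"] = NumericVector(w_off_e.begin(), w_off_e.end()),
      _["w_on_i"] = -NumericVector(m_on.begin(), m_on.end()),
      _["w_off_i"] = -NumericVector(m_off.begin(), m_off.end()),
      _["snap_on_e"] = snap_on_e, _["snap_off_e"] = snap_off_e,
      _["snap_on_i"] = snap_on_i, _["snap_off_i"] = snap_off_i,
      _["mean_rate"] = sum_y / n_steps);
}
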