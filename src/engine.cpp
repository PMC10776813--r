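#include <Rcpp.h>
using namespace Rcpp;

// Half-sarcomere trace integrator.
//
// Operator-split step, identical to the R reference advance():
//   1. explicit Euler for activated actin (floored at cb, capped at 1),
//   2. exponential Euler per strain bin for bound myosin with the
//      attachment flux frozen over the step,
//   3. mass-conserving linear-interpolation advection of the bound
//      distribution by the imposed length increment.
//
// All per-bin rate coefficients are precomputed by the R wrapper because
// they depend only on the (fixed) strain grid and dt:
//   attach_coeff = f(dx) * w(dx)         [s^-1]
//   g            = g(dx)                 [s^-1]
//   decay        = exp(-g dt)
//   gain         = (1 - decay) / g       (dt where g == 0)
//
// length_nm (the commanded length) and ca_molar are sampled on the dt
// grid (length n); the state is recorded at every sample, sample 0 being
// the initial state.
//
// Slack handling: the commanded length is an upper bound on the realized
// half-sarcomere length. If imposing it would make total stress
// negative, the fibre buckles and sits at its zero-stress length
// (closed form: stress is linear in the advection shift), carrying zero
// stress until the command re-engages it.
// [[Rcpp::export]]
List sim_fibre_cpp(NumericVector length_nm,
                   NumericVector ca_molar,
                   double dt,
                   double k_on, double k_off, double k_coop,
                   NumericVector centres,
                   double bin_width,
                   NumericVector attach_coeff,
                   NumericVector g_rate,
                   NumericVector decay,
                   NumericVector gain,
                   double cb_scale,          // 1e-9 * cb_density * cb_stiffness
                   double power_stroke,
                   double passive_stiffness,
                   double length_slack,
                   double l_thin, double l_thick, double l_bare,
                   double actin0,
                   NumericVector bound0,
                   int dist_stride,
                   bool allow_slack) {
  const int n = length_nm.size();
  const int nb = centres.size();
  if (ca_molar.size() != n) stop("length and calcium series differ in size");

  std::vector<double> bound(bound0.begin(), bound0.end());
  std::vector<double> tmp(nb);
  double A = actin0;

  NumericVector actin(n), cb_attached(n), stress(n), n_overlap(n);
  NumericVector len_real(n);
  const double ov_denom = l_thick - l_bare;
  double L = length_nm[0];   // realized half-sarcomere length
  len_real[0] = L;

  int nsnap = (dist_stride > 0) ? (n - 1) / dist_stride + 1 : 0;
  NumericMatrix snaps(nsnap, nb);
  int isnap = 0;

  double lost_total = 0.0;   // mass forcibly detached at the grid edge
  double edge_max = 0.0;     // worst outer-bin occupancy seen

  auto overlap = [&](double L) {
    double raw = (l_thin - (L - l_thick)) / ov_denom;
    return raw < 0.0 ? 0.0 : (raw > 1.0 ? 1.0 : raw);
  };
  auto record = [&](int i) {
    double cb = 0.0, sx = 0.0;
    for (int j = 0; j < nb; ++j) {
      cb += bound[j];
      sx += (centres[j] + power_stroke) * bound[j];
    }
    actin[i] = A;
    cb_attached[i] = cb;
    len_real[i] = L;
    n_overlap[i] = overlap(L);
    stress[i] = cb_scale * sx + passive_stiffness * (L - length_slack);
    if (dist_stride > 0 && i % dist_stride == 0) {
      for (int j = 0; j < nb; ++j) snaps(isnap, j) = bound[j];
      ++isnap;
    }
    return cb;
  };

  double cb = record(0);

  for (int i = 0; i < n - 1; ++i) {
    const double nov = n_overlap[i];
    const double detached = 1.0 - cb;
    double avail = A - cb;
    if (avail < 0.0) avail = 0.0;

    // thin filament: explicit Euler with cooperativity ratios zero when
    // the overlap vanishes
    double dA;
    if (nov <= 0.0) {
      dA = -k_off * (A - cb);
    } else {
      dA = k_on * ca_molar[i] * (nov - A) * (1.0 + k_coop * A / nov) -
           k_off * (A - cb) * (1.0 + k_coop * (nov - A) / nov);
    }
    A += dt * dA;
    if (A < cb) A = cb;
    if (A > 1.0) A = 1.0;

    // thick filament: exponential Euler per bin
    for (int j = 0; j < nb; ++j) {
      bound[j] = bound[j] * decay[j] +
        attach_coeff[j] * detached * avail * gain[j];
    }

    // advection by the realized length increment (slack-limited)
    double delta = length_nm[i + 1] - L;
    if (allow_slack) {
      double cb_now = 0.0, sx = 0.0;
      for (int j = 0; j < nb; ++j) {
        cb_now += bound[j];
        sx += (centres[j] + power_stroke) * bound[j];
      }
      const double slope = cb_scale * cb_now + passive_stiffness;
      const double s_cmd = cb_scale * sx +
        passive_stiffness * (L - length_slack) + slope * delta;
      if (s_cmd < 0.0 && slope > 0.0) delta -= s_cmd / slope;
    }
    const double shift = delta / bin_width;
    if (shift != 0.0) {
      const double kf = std::floor(shift);
      const int k = (int)kf;
      const double frac = shift - kf;
      std::fill(tmp.begin(), tmp.end(), 0.0);
      for (int j = 0; j < nb; ++j) {
        const double m = bound[j];
        if (m == 0.0) continue;
        const int d1 = j + k;
        if (d1 >= 0 && d1 < nb) tmp[d1] += (1.0 - frac) * m;
        else lost_total += (1.0 - frac) * m;
        if (frac > 0.0) {
          const int d2 = d1 + 1;
          if (d2 >= 0 && d2 < nb) tmp[d2] += frac * m;
          else lost_total += frac * m;
        }
      }
      bound.assign(tmp.begin(), tmp.end());
      if (bound[0] > edge_max) edge_max = bound[0];
      if (bound[nb - 1] > edge_max) edge_max = bound[nb - 1];
    }
    L += delta;

    cb = record(i + 1);
  }

  return List::create(
    _["length_real"] = len_real,
    _["actin_activated"] = actin,
    _["cb_attached"] = cb_attached,
    _["n_overlap"] = n_overlap,
    _["stress"] = stress,
    _["bound_final"] = NumericVector(bound.begin(), bound.end()),
    _["forced_detached"] = lost_total,
    _["edge_occupancy"] = edge_max,
    _["distribution"] = snaps);
}
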