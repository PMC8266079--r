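#include <Rcpp.h>
using namespace Rcpp;

// Delayed-feedback linearized inverted pendulum, fixed-step semi-implicit
// Euler. State is the COM deviation x (m, relative to the base of support)
// and its velocity v. The reactive ankle moment is generated from the
// *recorded* state delay_steps samples ago (ring buffer == recorded series),
// so the feedback relation between the emitted series is exact by
// construction, independent of integration error:
//
//   dT_nd[k] = kp[k] * x[k-d]/l + kv[k] * v[k-d]/sqrt(g*l)
//   a[k]     = (g/l) * (x[k] - kp[k]*x[k-d]) - sqrt(g/l)*kv[k]*v[k-d]
//              + pert_acc[k]
//
// reset_idx (1-based sample indices) marks heel strikes where the
// base-of-support frame switches: x <- reset_pos * x, v <- reset_vel * v
// before the sample is recorded. Integration aborts when |x| exceeds guard.
// [[Rcpp::export]]
List ip_simulate_cpp(int n, double dt, double g, double l,
                     int delay_steps,
                     NumericVector kp_t, NumericVector kv_t,
                     NumericVector pert_acc,
                     double reset_pos, double reset_vel,
                     IntegerVector reset_idx,
                     double x0, double v0, double guard) {
  if (kp_t.size() != n || kv_t.size() != n || pert_acc.size() != n)
    stop("gain/perturbation schedules must have length n");
  NumericVector xr(n), vr(n), tnd(n);
  const double om2 = g / l, om = std::sqrt(g / l), sgl = std::sqrt(g * l);
  std::vector<bool> is_reset(n, false);
  for (int i = 0; i < reset_idx.size(); ++i) {
    int k = reset_idx[i] - 1;
    if (k >= 0 && k < n) is_reset[k] = true;
  }
  double x = x0, v = v0;
  int fail_step = -1;
  for (int k = 0; k < n; ++k) {
    if (is_reset[k]) { x *= reset_pos; v *= reset_vel; }
    xr[k] = x; vr[k] = v;
    double xd = (k >= delay_steps) ? xr[k - delay_steps] : 0.0;
    double vd = (k >= delay_steps) ? vr[k - delay_steps] : 0.0;
    tnd[k] = kp_t[k] * xd / l + kv_t[k] * vd / sgl;
    double a = om2 * (x - kp_t[k] * xd) - om * kv_t[k] * vd + pert_acc[k];
    v += dt * a;
    x += dt * v;
    if (std::abs(x) > guard) { fail_step = k + 1; break; }
  }
  return List::create(_["x"] = xr, _["v"] = vr, _["moment_nd"] = tnd,
                      _["ok"] = (fail_step < 0), _["fail_step"] = fail_step);
}
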