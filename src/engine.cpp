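#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closed-loop plant under delayed PD control:
//   I * theta''(t) = sat(tau_des(t)) + grav_coef * sin(theta(t))
//   tau_des(t) = 0                                   for 0 < t < t_sm
//              = kp*(theta_ref - theta(t - t_sm))
//                + kd*(-omega(t - t_sm)) + tau_ss    for t >= t_sm
//
// Integrated by the method of steps with a fixed-step classical RK4 whose
// step h = t_sm / steps_per_delay divides the delay exactly, so every
// derivative discontinuity (propagating from the deadtime switch at t_sm)
// falls on a grid node and no RK4 step straddles it.  The delayed state at
// stage times lands either on a stored node or on a step midpoint, which is
// reconstructed by cubic Hermite interpolation from the stored state and
// its derivative (O(h^4), consistent with RK4).

static inline double clamp_tau(double tau_des, double tau_iso) {
  // tau_iso may be +Inf (no saturation); comparisons are then never true
  if (tau_des > tau_iso) return tau_iso;
  if (tau_des < -tau_iso) return -tau_iso;
  return tau_des;
}

// [[Rcpp::export]]
List sim_feedback_cpp(double inertia, double t_sm, double kp, double kd,
                      double tau_ss, double tau_iso, double theta_ref,
                      double theta0, double omega0, double grav_coef,
                      double horizon, int steps_per_delay) {
  const int n = steps_per_delay;
  const double h = t_sm / n;
  // round the horizon up to a whole number of delay intervals
  int K = (int)std::ceil(horizon / t_sm - 1e-12);
  if (K < 1) K = 1;
  const int N = K * n;

  NumericVector t(N + 1), th(N + 1), om(N + 1), acc(N + 1), tau(N + 1);
  th[0] = theta0;
  om[0] = omega0;
  tau[0] = 0.0;  // deadtime regime at t = 0
  acc[0] = (tau[0] + grav_coef * std::sin(theta0)) / inertia;

  bool diverged = false;
  int last = N;

  for (int i = 0; i < N; ++i) {
    t[i] = i * h;
    const bool pd = (i >= n);  // controller active on [t_sm, horizon)

    // applied torque at the three distinct stage times of this step
    double tau1, taum, tau2;
    if (!pd) {
      tau1 = taum = tau2 = 0.0;
    } else {
      const int j = i - n;  // delayed node index for stage 1
      // stage 1: delayed state at node j
      tau1 = clamp_tau(kp * (theta_ref - th[j]) - kd * om[j] + tau_ss, tau_iso);
      // stages 2/3: delayed state at the midpoint of [j, j+1] (Hermite)
      const double thm = 0.5 * (th[j] + th[j + 1]) + h / 8.0 * (om[j] - om[j + 1]);
      const double omm = 0.5 * (om[j] + om[j + 1]) + h / 8.0 * (acc[j] - acc[j + 1]);
      taum = clamp_tau(kp * (theta_ref - thm) - kd * omm + tau_ss, tau_iso);
      // stage 4: delayed state at node j + 1 (already computed: j + 1 <= i)
      tau2 = clamp_tau(kp * (theta_ref - th[j + 1]) - kd * om[j + 1] + tau_ss,
                       tau_iso);
    }

    const double th_i = th[i], om_i = om[i];
    const double k1t = om_i;
    const double k1o = (tau1 + grav_coef * std::sin(th_i)) / inertia;
    const double k2t = om_i + 0.5 * h * k1o;
    const double k2o = (taum + grav_coef * std::sin(th_i + 0.5 * h * k1t)) / inertia;
    const double k3t = om_i + 0.5 * h * k2o;
    const double k3o = (taum + grav_coef * std::sin(th_i + 0.5 * h * k2t)) / inertia;
    const double k4t = om_i + h * k3o;
    const double k4o = (tau2 + grav_coef * std::sin(th_i + h * k3t)) / inertia;

    th[i + 1] = th_i + h / 6.0 * (k1t + 2.0 * k2t + 2.0 * k3t + k4t);
    om[i + 1] = om_i + h / 6.0 * (k1o + 2.0 * k2o + 2.0 * k3o + k4o);
    t[i + 1] = (i + 1) * h;

    if (!std::isfinite(th[i + 1]) || !std::isfinite(om[i + 1]) ||
        std::fabs(th[i + 1]) > 1e6 || std::fabs(om[i + 1]) > 1e9) {
      diverged = true;
      last = i;  // keep only the finite prefix
      break;
    }

    // stored node torque/acceleration use the right-limit regime so that the
    // Hermite lookup for later intervals sees the derivative of the interval
    // that starts at this node
    const bool pd_next = (i + 1 >= n);
    if (!pd_next) {
      tau[i + 1] = 0.0;
    } else {
      const int j2 = i + 1 - n;
      tau[i + 1] = clamp_tau(kp * (theta_ref - th[j2]) - kd * om[j2] + tau_ss,
                             tau_iso);
    }
    acc[i + 1] = (tau[i + 1] + grav_coef * std::sin(th[i + 1])) / inertia;
  }
  if (!diverged) t[N] = N * h;

  Range keep(0, last);
  return List::create(_["t"] = t[keep], _["theta"] = th[keep],
                      _["omega"] = om[keep], _["tau_act"] = tau[keep],
                      _["diverged"] = diverged);
}

// Cubic Hermite evaluation of a scalar y(t) on [t0, t0 + h] from endpoint
// values and derivatives.
static inline double hermite(double s, double h, double y0, double d0,
                             double y1, double d1) {
  const double s2 = s * s, s3 = s2 * s;
  return (2 * s3 - 3 * s2 + 1) * y0 + (s3 - 2 * s2 + s) * h * d0 +
         (-2 * s3 + 3 * s2) * y1 + (s3 - s2) * h * d1;
}

// Bang-bang feedforward response:
//   tau_act(t) = 0                          0 < t < t_sm
//              = +direction * tau_iso       t_sm < t < t_switch
//              = -direction * tau_iso       t > t_switch
// integrated segment-by-segment with RK4 (torque constant per segment, so
// the only discontinuities are the segment boundaries, which are nodes).
// The run terminates at the first zero-crossing of omega after t_switch,
// located on the cubic Hermite interpolant by bisection.
// [[Rcpp::export]]
List sim_feedforward_cpp(double inertia, double t_sm, double t_switch,
                         double direction, double tau_iso, double theta0,
                         double omega0, double grav_coef, double horizon,
                         double h_target) {
  const double bounds[4] = {0.0, t_sm, t_switch, horizon};
  const double taus[3] = {0.0, direction * tau_iso, -direction * tau_iso};

  std::vector<double> t, th, om, acc, tauv;
  t.push_back(0.0); th.push_back(theta0); om.push_back(omega0);
  tauv.push_back(0.0);
  acc.push_back((0.0 + grav_coef * std::sin(theta0)) / inertia);

  bool event = false, diverged = false;
  double t_end = NA_REAL, theta_end = NA_REAL;

  for (int seg = 0; seg < 3 && !event && !diverged; ++seg) {
    const double a = bounds[seg], b = bounds[seg + 1];
    if (b <= a) continue;
    const int m = std::max(1, (int)std::ceil((b - a) / h_target - 1e-12));
    const double h = (b - a) / m;
    const double tq = taus[seg];

    for (int i = 0; i < m; ++i) {
      const double th_i = th.back(), om_i = om.back(), t_i = t.back();
      const double k1t = om_i;
      const double k1o = (tq + grav_coef * std::sin(th_i)) / inertia;
      const double k2t = om_i + 0.5 * h * k1o;
      const double k2o = (tq + grav_coef * std::sin(th_i + 0.5 * h * k1t)) / inertia;
      const double k3t = om_i + 0.5 * h * k2o;
      const double k3o = (tq + grav_coef * std::sin(th_i + 0.5 * h * k2t)) / inertia;
      const double k4t = om_i + h * k3o;
      const double k4o = (tq + grav_coef * std::sin(th_i + h * k3t)) / inertia;

      const double th1 = th_i + h / 6.0 * (k1t + 2 * k2t + 2 * k3t + k4t);
      const double om1 = om_i + h / 6.0 * (k1o + 2 * k2o + 2 * k3o + k4o);
      const double t1 = t_i + h;

      if (!std::isfinite(th1) || !std::isfinite(om1) ||
          std::fabs(th1) > 1e6 || std::fabs(om1) > 1e9) {
        diverged = true;
        break;
      }

      const double a1 = (tq + grav_coef * std::sin(th1)) / inertia;

      // event check only after the switch (segment 2); a genuine crossing,
      // not a rest state that never left zero
      if (seg == 2 &&
          ((om_i > 0.0 && om1 <= 0.0) || (om_i < 0.0 && om1 >= 0.0))) {
        const double a0 = (tq + grav_coef * std::sin(th_i)) / inertia;
        double lo = 0.0, hi = 1.0;
        double flo = om_i;
        for (int it = 0; it < 80; ++it) {
          const double mid = 0.5 * (lo + hi);
          const double fm = hermite(mid, h, om_i, a0, om1, a1);
          if ((flo <= 0 && fm <= 0) || (flo >= 0 && fm >= 0)) {
            lo = mid; flo = fm;
          } else {
            hi = mid;
          }
        }
        const double s = 0.5 * (lo + hi);
        t_end = t_i + s * h;
        // theta'(t) = omega, so the Hermite for theta uses omega as slope
        theta_end = hermite(s, h, th_i, om_i, th1, om1);
        const double om_end = hermite(s, h, om_i, a0, om1, a1);
        t.push_back(t_end); th.push_back(theta_end); om.push_back(om_end);
        tauv.push_back(tq); acc.push_back((tq + grav_coef * std::sin(theta_end)) / inertia);
        event = true;
        break;
      }

      t.push_back(t1); th.push_back(th1); om.push_back(om1);
      tauv.push_back(tq); acc.push_back(a1);
    }
  }

  return List::create(_["t"] = wrap(t), _["theta"] = wrap(th),
                      _["omega"] = wrap(om), _["tau_act"] = wrap(tauv),
                      _["event"] = event, _["diverged"] = diverged,
                      _["t_end"] = t_end, _["theta_end"] = theta_end);
}
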