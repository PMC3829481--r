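// Microscopic simulators for the globally coupled phase network:
//   dtheta_i/dt = F(theta_i, gamma_i, u),  du/dt = -beta*u + beta*nu(t),
// nu(t) the population delta train (each spike kicks u by beta/N), a neuron
// spiking when its phase crosses pi (wrap by -2*pi).
//
// Event-driven mode (linear_phase, constant I >= 0, gamma nodes >= 0): u is
// piecewise exponential between spikes, so each neuron's phase advance over
// dt is the closed form I*dt + gamma*u*(1 - exp(-beta*dt))/beta. Neurons
// sharing a gamma value advance identically, so their cyclic firing order is
// fixed: per gamma group only the head neuron needs a crossing-time root
// solve (safeguarded Newton, tolerance 1e-12 time units).
//
// Fixed-step mode: within a step u decays exactly; linear_phase advances in
// closed form, the theta model by classical RK4 against the known u(s).
// Crossings are located inside the step and each spike's exact exponential
// contribution to u (and, for linear_phase, to every phase) is superposed.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>
using namespace Rcpp;

static const double TWOPI = 2.0 * M_PI;

static inline double wrap_pm_pi(double x) {
  return x - TWOPI * std::floor((x + M_PI) / TWOPI);
}

// integral of u over [0, dt] for u(s) = u0 * exp(-beta*s)
static inline double decay_integral(double u0, double beta, double dt) {
  return u0 * (-std::expm1(-beta * dt)) / beta;
}

// Solve I*dt + g*u*(1-exp(-beta*dt))/beta = D for dt >= 0 (monotone in dt).
// Returns R_PosInf if no crossing is possible.
static double crossing_time(double D, double I, double g, double u,
                            double beta) {
  if (D <= 0.0) return 0.0;
  double gu = g * u;
  if (I <= 0.0) {
    // bounded advance gu/beta; closed form when reachable
    if (gu <= 0.0) return R_PosInf;
    double arg = 1.0 - beta * D / gu;
    if (arg <= 0.0) return R_PosInf;
    return -std::log(arg) / beta;
  }
  double lo = D / (I + std::max(gu, 0.0));  // advance <= (I + gu)*dt
  double hi = D / I;                        // advance >= I*dt
  double dt = lo;
  for (int it = 0; it < 100; ++it) {
    double e = std::exp(-beta * dt);
    double f = I * dt + gu * (1.0 - e) / beta - D;
    if (f > 0.0) hi = dt; else lo = dt;
    double fp = I + gu * e;
    double step = f / fp;
    double nxt = dt - step;
    if (!(nxt > lo && nxt < hi)) nxt = 0.5 * (lo + hi);
    if (std::fabs(nxt - dt) < 1e-13 * (1.0 + dt)) { dt = nxt; break; }
    dt = nxt;
  }
  return dt;
}

struct Group {
  double gamma;
  std::vector<int> order;   // neuron indices, sorted by theta0 descending
  std::vector<double> theta0;
  long fired = 0;           // spikes emitted so far by this group
  double threshold(long c) const {
    long n = (long)order.size();
    return M_PI + TWOPI * (double)(c / n) - theta0[c % n];
  }
};

// [[Rcpp::export(name = ".sim_event_driven")]]
List sim_event_driven(NumericVector theta0, NumericVector gamma, double u0,
                      double beta, double I, double T,
                      NumericVector sample_times, bool record_spikes,
                      bool record_phases) {
  const int N = theta0.size();
  const int S = sample_times.size();

  // group neurons by gamma value
  std::vector<double> uniq(gamma.begin(), gamma.end());
  std::sort(uniq.begin(), uniq.end());
  uniq.erase(std::unique(uniq.begin(), uniq.end()), uniq.end());
  const int G = (int)uniq.size();
  std::vector<Group> groups(G);
  for (int g = 0; g < G; ++g) groups[g].gamma = uniq[g];
  {
    std::vector<std::vector<int> > members(G);
    for (int i = 0; i < N; ++i) {
      int g = (int)(std::lower_bound(uniq.begin(), uniq.end(), gamma[i]) -
                    uniq.begin());
      members[g].push_back(i);
    }
    for (int g = 0; g < G; ++g) {
      std::vector<int>& m = members[g];
      std::stable_sort(m.begin(), m.end(), [&](int a, int b) {
        if (theta0[a] != theta0[b]) return theta0[a] > theta0[b];
        return a < b;  // deterministic tie-break by neuron index
      });
      groups[g].order = m;
      groups[g].theta0.resize(m.size());
      for (size_t j = 0; j < m.size(); ++j) groups[g].theta0[j] = theta0[m[j]];
    }
  }

  double t = 0.0, u = u0, U = 0.0;  // U = integral of u from 0 to t
  const double kick = beta / (double)N;

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  NumericVector u_out(S);
  NumericMatrix phase_out(record_phases ? S : 0, record_phases ? N : 0);
  int next_sample = 0;
  long n_events = 0;

  auto advance_to = [&](double tnew) {
    double dt = tnew - t;
    if (dt <= 0.0) return;
    U += decay_integral(u, beta, dt);
    u *= std::exp(-beta * dt);
    t = tnew;
  };
  auto record_sample = [&](int s) {
    u_out[s] = u;
    if (record_phases) {
      for (int g = 0; g < G; ++g) {
        double A = I * t + groups[g].gamma * U;
        const Group& G1 = groups[g];
        for (size_t j = 0; j < G1.order.size(); ++j) {
          phase_out(s, G1.order[j]) = wrap_pm_pi(G1.theta0[j] + A);
        }
      }
    }
  };

  while (true) {
    // earliest provisional crossing over the group heads
    double best_dt = R_PosInf;
    int best_g = -1;
    for (int g = 0; g < G; ++g) {
      Group& G1 = groups[g];
      double A = I * t + G1.gamma * U;
      double D = G1.threshold(G1.fired) - A;
      double dtg = crossing_time(D, I, G1.gamma, u, beta);
      if (dtg < best_dt ||
          (dtg == best_dt && best_g >= 0 &&
           G1.order[G1.fired % G1.order.size()] <
               groups[best_g].order[groups[best_g].fired %
                                    groups[best_g].order.size()])) {
        best_dt = dtg;
        best_g = g;
      }
    }
    double t_spike = (best_g >= 0 && best_dt < R_PosInf) ? t + best_dt
                                                         : R_PosInf;

    // emit samples that precede the next spike
    while (next_sample < S && sample_times[next_sample] <= t_spike &&
           sample_times[next_sample] <= T) {
      advance_to(sample_times[next_sample]);
      record_sample(next_sample);
      ++next_sample;
    }
    if (t_spike > T || best_g < 0) break;

    advance_to(t_spike);
    Group& G1 = groups[best_g];
    int who = G1.order[G1.fired % G1.order.size()];
    if (record_spikes) {
      spike_id.push_back(who + 1);
      spike_t.push_back(t);
    }
    G1.fired += 1;
    u += kick;
    ++n_events;
    if (n_events % 1048576 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["u"] = u_out,
                      _["spike_id"] = wrap(spike_id),
                      _["spike_time"] = wrap(spike_t),
                      _["phases"] = phase_out,
                      _["n_events"] = (double)n_events,
                      _["u_final"] = u,
                      _["t_final"] = t);
}

// theta-model speed
static inline double theta_speed(double th, double base) {
  return 1.0 - std::cos(th) + (1.0 + std::cos(th)) * base;
}

// [[Rcpp::export(name = ".sim_fixed_step")]]
List sim_fixed_step(NumericVector theta0, NumericVector gamma, double u0,
                    double beta, NumericVector drive_t, NumericVector drive_v,
                    bool drive_constant, int kind, double dt, double T,
                    NumericVector sample_times, bool record_spikes,
                    bool record_phases) {
  const int N = theta0.size();
  const int S = sample_times.size();
  const double kick = beta / (double)N;
  const int nsteps = (int)std::ceil(T / dt - 1e-9);

  auto I_at = [&](double tt) -> double {
    if (drive_constant) return drive_v[0];
    int n = drive_t.size();
    if (tt <= drive_t[0]) return drive_v[0];
    if (tt >= drive_t[n - 1]) return drive_v[n - 1];
    int lo = (int)(std::upper_bound(drive_t.begin(), drive_t.end(), tt) -
                   drive_t.begin()) - 1;
    double w = (tt - drive_t[lo]) / (drive_t[lo + 1] - drive_t[lo]);
    return drive_v[lo] * (1.0 - w) + drive_v[lo + 1] * w;
  };

  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> th_new(N), sp0(N), sp1(N);
  double u = u0, t = 0.0;

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  NumericVector u_out(S);
  NumericMatrix phase_out(record_phases ? S : 0, record_phases ? N : 0);
  int next_sample = 0;
  long n_events = 0;

  // advance one neuron from time t over tau <= h with u(s) = u*exp(-beta*s)
  auto advance_phase = [&](double th0, double g, double tau) -> double {
    if (tau <= 0.0) return th0;
    if (kind == 0) {
      double Iint = drive_constant
        ? drive_v[0] * tau
        : 0.5 * (I_at(t) + I_at(t + tau)) * tau;  // trapezoid on the step
      return th0 + Iint + g * decay_integral(u, beta, tau);
    }
    // classical RK4, u and I evaluated exactly at stage times
    double b0 = I_at(t) + g * u;
    double bh = I_at(t + 0.5 * tau) + g * u * std::exp(-beta * 0.5 * tau);
    double b1 = I_at(t + tau) + g * u * std::exp(-beta * tau);
    double k1 = theta_speed(th0, b0);
    double k2 = theta_speed(th0 + 0.5 * tau * k1, bh);
    double k3 = theta_speed(th0 + 0.5 * tau * k2, bh);
    double k4 = theta_speed(th0 + tau * k3, b1);
    return th0 + tau / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
  };

  struct Crossing { double tau; int who; };

  for (int step = 0; step < nsteps; ++step) {
    double h = std::min(dt, T - t);
    if (h <= 0.0) break;

    for (int i = 0; i < N; ++i) th_new[i] = advance_phase(th[i], gamma[i], h);

    // locate upward crossings of pi inside the step
    std::vector<Crossing> cross;
    for (int i = 0; i < N; ++i) {
      if (th_new[i] >= M_PI && th[i] < M_PI) {
        double tau;
        if (kind == 0) {
          double D = M_PI - th[i];
          tau = crossing_time(D, I_at(t), gamma[i], u, beta);
          if (!(tau >= 0.0) || tau > h) tau = h * (M_PI - th[i]) /
                                              (th_new[i] - th[i]);
        } else {
          tau = h * (M_PI - th[i]) / (th_new[i] - th[i]);  // secant
          // one bisection refinement pass against the RK4 dense advance
          double lo = 0.0, hi = h;
          for (int it = 0; it < 30; ++it) {
            double mid = 0.5 * (lo + hi);
            if (advance_phase(th[i], gamma[i], mid) >= M_PI) hi = mid;
            else lo = mid;
          }
          tau = 0.5 * (lo + hi);
        }
        cross.push_back({tau, i});
      }
    }
    std::sort(cross.begin(), cross.end(), [](const Crossing& a,
                                             const Crossing& b) {
      if (a.tau != b.tau) return a.tau < b.tau;
      return a.who < b.who;
    });

    // superpose each spike's exponential kick on u (exact) and, for
    // linear_phase, its contribution to every phase (exact by linearity);
    // for the theta model the phase correction uses the end-of-step gain
    // factor (1 + cos(theta))/... at first order in h.
    double u_end = u * std::exp(-beta * h);
    for (const Crossing& c : cross) {
      double rem = h - c.tau;
      u_end += kick * std::exp(-beta * rem);
      double uint = decay_integral(kick, beta, rem);  // integral of the kick
      for (int i = 0; i < N; ++i) {
        double gain = (kind == 0) ? gamma[i]
                                  : gamma[i] * (1.0 + std::cos(th_new[i]));
        th_new[i] += gain * uint;
      }
      if (record_spikes) {
        spike_id.push_back(c.who + 1);
        spike_t.push_back(t + c.tau);
      }
      ++n_events;
    }
    for (const Crossing& c : cross) th_new[c.who] -= TWOPI;

    // samples inside (t, t+h]
    while (next_sample < S && sample_times[next_sample] <= t + h + 1e-12 &&
           sample_times[next_sample] >= t - 1e-12) {
      double ts = sample_times[next_sample];
      double tau = std::max(0.0, std::min(h, ts - t));
      double us = u * std::exp(-beta * tau);
      for (const Crossing& c : cross) {
        if (c.tau <= tau) us += kick * std::exp(-beta * (tau - c.tau));
      }
      u_out[next_sample] = us;
      if (record_phases) {
        for (int i = 0; i < N; ++i) {
          double thi = advance_phase(th[i], gamma[i], tau);
          for (const Crossing& c : cross) {
            if (c.tau <= tau) {
              double gain = (kind == 0)
                ? gamma[i] : gamma[i] * (1.0 + std::cos(thi));
              thi += gain * decay_integral(kick, beta, tau - c.tau);
            }
            if (c.who == i && c.tau <= tau) thi -= TWOPI;
          }
          phase_out(next_sample, i) = wrap_pm_pi(thi);
        }
      }
      ++next_sample;
    }

    th.swap(th_new);
    u = u_end;
    t += h;
    if (step % 65536 == 0) Rcpp::checkUserInterrupt();
  }

  // flush samples that fell on the final time up to rounding drift
  while (next_sample < S && sample_times[next_sample] <= t + 1e-9) {
    u_out[next_sample] = u;
    if (record_phases) {
      for (int i = 0; i < N; ++i) {
        phase_out(next_sample, i) = wrap_pm_pi(th[i]);
      }
    }
    ++next_sample;
  }

  NumericVector th_out(N);
  for (int i = 0; i < N; ++i) th_out[i] = wrap_pm_pi(th[i]);

  return List::create(_["u"] = u_out,
                      _["spike_id"] = wrap(spike_id),
                      _["spike_time"] = wrap(spike_t),
                      _["phases"] = phase_out,
                      _["n_events"] = (double)n_events,
                      _["u_final"] = u,
                      _["t_final"] = t,
                      _["theta_final"] = th_out);
}

// [[Rcpp::export(name = ".phase_histogram")]]
NumericMatrix phase_histogram(NumericVector phases, NumericVector gamma,
                              NumericVector gamma_nodes,
                              NumericVector gamma_weights, int M) {
  const int N = phases.size();
  const int Q = gamma_nodes.size();
  const double dtheta = TWOPI / (double)M;
  NumericMatrix out(M, Q);
  for (int i = 0; i < N; ++i) {
    double th = wrap_pm_pi(phases[i]);
    int m = (int)std::lround((th + M_PI) / dtheta) % M;  // node-centered bin
    // nearest gamma node
    int q = 0;
    double best = std::fabs(gamma[i] - gamma_nodes[0]);
    for (int j = 1; j < Q; ++j) {
      double d = std::fabs(gamma[i] - gamma_nodes[j]);
      if (d < best) { best = d; q = j; }
    }
    out(m, q) += 1.0;
  }
  for (int q = 0; q < Q; ++q) {
    double denom = (double)N * dtheta * gamma_weights[q];
    for (int m = 0; m < M; ++m) out(m, q) /= denom;
  }
  return out;
}
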