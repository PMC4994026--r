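// Fixed-step RK4 integrator for a network of canonical-microcircuit (CMC)
// neural-mass sources with delayed intrinsic and extrinsic coupling.
//
// State layout per source: [v_ss, v_sp, v_ii, v_dp] then currents, populations
// in the order ss = 0, sp = 1, ii = 2, dp = 3.
//
// All synaptic coupling (intrinsic and extrinsic) acts through delayed firing
// rates held in a history buffer sampled on the integration grid; values
// between grid points are linearly interpolated.  Because delays are constant
// per edge, lookup offsets and interpolation weights are precomputed per
// (edge, RK substep).  Delays shorter than the substep offset are clamped to
// it (i.e. effective delays are at least ~dt); the origin (resting) history
// is identically zero firing.
//
// Every coupling term is delayed, so within a step the dynamics are linear in
// the state, which keeps RK4 cheap and accurate at dt on the order of 1 ms.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double sig(double v, double r) {
  return 1.0 / (1.0 + std::exp(-r * v)) - 0.5;
}

namespace {

// precomputed delayed-lookup: value at step s = w0*buf[s+iq] + w1*buf[s+iq+1]
struct Lag {
  int iq;
  double w0, w1;
};

Lag make_lag(double delay, double sub, double dt) {
  double q = (sub - delay) / dt;
  if (q > 0.0) q = 0.0; // clamp: delay must cover the substep offset
  int iq = (int)std::floor(q);
  double w1 = q - iq;
  return {iq, 1.0 - w1, w1};
}

struct Edge {
  int to, from;
  double w_a, w_b; // weights onto the two target populations
  Lag lag[3];
};

} // namespace

// [[Rcpp::export(name = ".cmc_integrate_cpp")]]
List cmc_integrate_cpp(int n_sources,
                       NumericMatrix g,        // 10 x n intrinsic magnitudes
                       NumericMatrix tau,      // 4 x n time constants (ms)
                       double slope,           // sigmoid slope r (1/mV)
                       NumericVector gain_sp,  // n, multiplies sp->sp magnitude
                       NumericMatrix A_f_ss,   // n x n forward, onto ss (row = target)
                       NumericMatrix A_f_dp,   // n x n forward, onto dp
                       NumericMatrix A_b_sp,   // n x n backward, onto sp
                       NumericMatrix A_b_ii,   // n x n backward, onto ii
                       NumericMatrix D,        // n x n extrinsic delays (ms)
                       NumericVector D_self,   // n intrinsic (self) delays (ms)
                       NumericVector C,        // n input gains
                       double onset, double dispersion, double amplitude,
                       double t0, double t_end, double dt,
                       double v_bound,
                       NumericVector out_times) {
  const int n = n_sources;
  const int npop = 4 * n;
  const int nsteps = (int)std::ceil((t_end - t0) / dt - 1e-9);
  const double sub[3] = {0.0, 0.5 * dt, dt};

  // extrinsic edge lists with precomputed lags
  std::vector<Edge> fwd, bwd;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (A_f_ss(i, j) != 0.0 || A_f_dp(i, j) != 0.0) {
        Edge e{i, j, A_f_ss(i, j), A_f_dp(i, j), {}};
        for (int h = 0; h < 3; ++h) e.lag[h] = make_lag(D(i, j), sub[h], dt);
        fwd.push_back(e);
      }
      if (A_b_sp(i, j) != 0.0 || A_b_ii(i, j) != 0.0) {
        Edge e{i, j, A_b_sp(i, j), A_b_ii(i, j), {}};
        for (int h = 0; h < 3; ++h) e.lag[h] = make_lag(D(i, j), sub[h], dt);
        bwd.push_back(e);
      }
    }

  // intrinsic (self-delay) lags per source
  std::vector<Lag> self_lag(3 * n);
  for (int s = 0; s < n; ++s)
    for (int h = 0; h < 3; ++h)
      self_lag[3 * s + h] = make_lag(D_self[s], sub[h], dt);

  std::vector<double> kap(npop), gm(10 * n), gsp(n), cin(n);
  for (int s = 0; s < n; ++s) {
    for (int p = 0; p < 4; ++p) kap[4 * s + p] = 1.0 / tau(p, s);
    for (int e = 0; e < 10; ++e) gm[10 * s + e] = g(e, s);
    gsp[s] = gain_sp[s];
    cin[s] = C[s];
  }

  // input bump precomputed on the half-step grid
  std::vector<double> u(2 * nsteps + 1);
  const double two_disp2 = 2.0 * dispersion * dispersion;
  for (int k = 0; k <= 2 * nsteps; ++k) {
    double tt = t0 + 0.5 * dt * k;
    u[k] = amplitude * std::exp(-(tt - onset) * (tt - onset) / two_disp2);
  }

  // firing history, zero before and at t0 (resting origin)
  std::vector<double> hist((size_t)(nsteps + 2) * npop, 0.0);

  const int nstate = 2 * npop;
  std::vector<double> x(nstate, 0.0), aff(npop), k1(nstate), k2(nstate),
      k3(nstate), k4(nstate), xt(nstate);
  std::vector<double> vall((size_t)npop * (nsteps + 1), 0.0);

  // delayed firing of population p at (step s, substep lag l)
  auto look = [&](int p, int s, const Lag &l) -> double {
    int idx = s + l.iq;
    if (idx < 0) return 0.0;
    const double *a = &hist[(size_t)idx * npop + p];
    return l.w0 * a[0] + l.w1 * a[npop];
  };

  auto afferent = [&](int s_step, int h) {
    for (int s = 0; s < n; ++s) {
      const Lag &l = self_lag[3 * s + h];
      const double Sss = look(4 * s + 0, s_step, l);
      const double Ssp = look(4 * s + 1, s_step, l);
      const double Sii = look(4 * s + 2, s_step, l);
      const double Sdp = look(4 * s + 3, s_step, l);
      const double *G = &gm[10 * s];
      aff[4 * s + 0] = -G[0] * Sss - G[1] * Ssp - G[2] * Sii;
      aff[4 * s + 1] = -G[6] * gsp[s] * Ssp + G[7] * Sss;
      aff[4 * s + 2] = -G[3] * Sii + G[4] * Sss + G[5] * Sdp;
      aff[4 * s + 3] = -G[8] * Sii - G[9] * Sdp;
    }
    for (const Edge &e : fwd) {
      const double S = look(4 * e.from + 1, s_step, e.lag[h]); // presyn sp
      aff[4 * e.to + 0] += e.w_a * S;
      aff[4 * e.to + 3] += e.w_b * S;
    }
    for (const Edge &e : bwd) {
      const double S = look(4 * e.from + 3, s_step, e.lag[h]); // presyn dp
      aff[4 * e.to + 1] -= e.w_a * S;
      aff[4 * e.to + 2] -= e.w_b * S;
    }
    const double uu = u[2 * s_step + h];
    if (uu != 0.0)
      for (int s = 0; s < n; ++s) aff[4 * s] += cin[s] * uu;
  };

  auto deriv = [&](const std::vector<double> &st, std::vector<double> &out) {
    for (int p = 0; p < npop; ++p) {
      const double k = kap[p];
      out[p] = st[npop + p];
      out[npop + p] = k * aff[p] - 2.0 * k * st[npop + p] - k * k * st[p];
    }
  };

  for (int step = 0; step < nsteps; ++step) {
    afferent(step, 0);
    deriv(x, k1);
    for (int q = 0; q < nstate; ++q) xt[q] = x[q] + 0.5 * dt * k1[q];
    afferent(step, 1);
    deriv(xt, k2);
    for (int q = 0; q < nstate; ++q) xt[q] = x[q] + 0.5 * dt * k2[q];
    deriv(xt, k3); // same midpoint afferent
    for (int q = 0; q < nstate; ++q) xt[q] = x[q] + dt * k3[q];
    afferent(step, 2);
    deriv(xt, k4);
    const double d6 = dt / 6.0;
    for (int q = 0; q < nstate; ++q)
      x[q] += d6 * (k1[q] + 2.0 * k2[q] + 2.0 * k3[q] + k4[q]);

    double *h1 = &hist[(size_t)(step + 1) * npop];
    double *vrow = &vall[(size_t)(step + 1) * npop];
    for (int p = 0; p < npop; ++p) {
      const double v = x[p];
      if (!std::isfinite(v) || std::fabs(v) > v_bound)
        return List::create(_["diverged"] = true, _["source"] = p / 4 + 1,
                            _["time"] = t0 + (step + 1) * dt);
      h1[p] = sig(v, slope);
      vrow[p] = v;
    }
  }

  // sample the emitted series on the requested output grid (linear interp)
  const int nt = out_times.size();
  NumericMatrix vout(npop, nt);
  for (int k = 0; k < nt; ++k) {
    double uu = (out_times[k] - t0) / dt;
    if (uu < 0.0) uu = 0.0;
    if (uu > nsteps) uu = nsteps;
    int i0 = (int)std::floor(uu);
    if (i0 == nsteps) i0 = nsteps - 1;
    const double w = uu - i0;
    const double *a = &vall[(size_t)i0 * npop];
    for (int p = 0; p < npop; ++p)
      vout(p, k) = (1.0 - w) * a[p] + w * a[p + npop];
  }

  return List::create(_["diverged"] = false, _["v"] = vout);
}
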