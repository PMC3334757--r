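// Fast trajectory and marginal-likelihood engine for the bicarbonate
// turnover model.  The ODE  dB/dt = kin - kout * E(t) * B  with
// E(t) = 1 + emax * A(t)/(A(t) + a50)  and A(t) a superposition of iv
// boluses is linear but non-autonomous.  Between dose events A(t) is a
// single decaying exponential, so the integrating-factor exponent
//   H(t) = kout * [ t + (emax/kelim) * log((A0+a50)/(A(t)+a50)) ]
// is available in closed form; only the outer integral of exp(H) needs
// quadrature (fixed-node Gauss-Legendre on short sub-intervals).
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 10-point Gauss-Legendre nodes/weights on [-1, 1]
static const double GLX[10] = {
  -0.9739065285171717, -0.8650633666889845, -0.6794095682990244,
  -0.4333953941292472, -0.1488743389816312,  0.1488743389816312,
   0.4333953941292472,  0.6794095682990244,  0.8650633666889845,
   0.9739065285171717};
static const double GLW[10] = {
  0.0666713443086881, 0.1494513491505806, 0.2190863625159820,
  0.2692667193099963, 0.2955242247147529, 0.2955242247147529,
  0.2692667193099963, 0.2190863625159820, 0.1494513491505806,
  0.0666713443086881};

// Integrating-factor exponent increment over [a, a+dt] when the body
// amount at a is A0 (decaying at rate kelim within the interval).
static inline double dH(double dt, double A0, double kout, double a50,
                        double emax, double kelim) {
  double h = kout * dt;
  if (A0 > 0.0 && emax != 0.0) {
    double At = A0 * std::exp(-kelim * dt);
    h += kout * (emax / kelim) * std::log((A0 + a50) / (At + a50));
  }
  return h;
}

// Advance B from interval start (amount A0) by dt; kin = bicar0 * kout
// refers to the subject's own equilibrium.  The quadrature integrand is
// written as exp(H(s) - H(dt)) <= 1 so arbitrarily fast elimination
// (large kout during optimization) cannot overflow.
static double advance_B(double B, double A0, double dt, double kin,
                        double kout, double a50, double emax, double kelim,
                        double hmax) {
  if (dt <= 0.0) return B;
  int nsub = (int)std::ceil(dt / hmax);
  if (nsub < 1) nsub = 1;
  double h = dt / nsub;
  double Ht = dH(dt, A0, kout, a50, emax, kelim);
  double I = 0.0;
  for (int s = 0; s < nsub; ++s) {
    double lo = s * h, half = 0.5 * h, mid = lo + half;
    for (int q = 0; q < 10; ++q) {
      double u = mid + half * GLX[q];
      double e = dH(u, A0, kout, a50, emax, kelim) - Ht;
      I += GLW[q] * half * std::exp(e);
    }
  }
  return std::exp(-Ht) * B + kin * I;
}

// Trajectory at sorted, non-negative output times.  Dose times/amounts
// are iv boluses; a dose at exactly an output time is included (B is
// continuous, so the output value is unaffected by the convention).
static void traj_core(const std::vector<double>& times,
                      const std::vector<double>& dt_,
                      const std::vector<double>& da_,
                      double bicar0, double kout, double a50, double emax,
                      double kelim, double hmax, double* out) {
  size_t nt = times.size(), nd = dt_.size();
  // event walk: merge dose times and output times
  double t = 0.0, B = bicar0, A = 0.0;
  double kin = bicar0 * kout;
  size_t id = 0, io = 0;
  // doses at t <= 0 applied immediately
  while (id < nd && dt_[id] <= 0.0) { A += da_[id]; ++id; }
  while (io < nt) {
    double tnext = times[io];
    bool is_dose = false;
    if (id < nd && dt_[id] < tnext) { tnext = dt_[id]; is_dose = true; }
    double step = tnext - t;
    if (step > 0.0) {
      B = advance_B(B, A, step, kin, kout, a50, emax, kelim, hmax);
      A *= std::exp(-kelim * step);
      t = tnext;
    }
    if (is_dose) {
      A += da_[id]; ++id;
    } else {
      // apply any dose at exactly this output time before recording A-state,
      // B itself is continuous
      out[io] = B; ++io;
      while (id < nd && dt_[id] <= t + 1e-15) { A += da_[id]; ++id; }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_trajectory(NumericVector times, NumericVector dose_t,
                             NumericVector dose_a, double bicar0,
                             double kout, double a50, double emax,
                             double kelim, double hmax = 0.5) {
  std::vector<double> tt(times.begin(), times.end());
  std::vector<double> dt(dose_t.begin(), dose_t.end());
  std::vector<double> da(dose_a.begin(), dose_a.end());
  NumericVector out(times.size());
  traj_core(tt, dt, da, bicar0, kout, a50, emax, kelim, hmax, REAL(out));
  return out;
}

// K trajectories at shared design, per-row individual parameters.
// [[Rcpp::export]]
NumericMatrix cpp_traj_matrix(NumericVector times, NumericVector dose_t,
                              NumericVector dose_a, NumericVector bicar0,
                              NumericVector kout, double a50, double emax,
                              double kelim, double hmax = 0.5) {
  int K = bicar0.size(), m = times.size();
  std::vector<double> tt(times.begin(), times.end());
  std::vector<double> dt(dose_t.begin(), dose_t.end());
  std::vector<double> da(dose_a.begin(), dose_a.end());
  NumericMatrix out(K, m);
  std::vector<double> row(m);
  for (int k = 0; k < K; ++k) {
    traj_core(tt, dt, da, bicar0[k], kout[k], a50, emax, kelim, hmax,
              row.data());
    for (int j = 0; j < m; ++j) out(k, j) = row[j];
  }
  return out;
}

// ---- marginal likelihood -------------------------------------------------
//
// The trajectory is exactly linear in the baseline: B(t) = b0 * q(t; kout)
// with q the trajectory started at baseline 1 (since kin = b0 * kout).
// The subject marginal likelihood
//   L_i = int int p(y | b0 e^{eta1} q(eta2)) phi(eta1; om1) phi(eta2; om2)
// is therefore computed as a dense deterministic grid over eta2 (whose
// conditional posterior can be strongly non-Gaussian: the bounded Emax
// effect creates likelihood plateaus in the elimination rate), with the
// expensive trajectory q evaluated once per grid point, nested with
// adaptive Gauss-Hermite quadrature over eta1 (conditionally
// well-behaved) using analytic derivatives.

struct Subject {
  std::vector<double> tobs, y, dt, da;
  double b0typ, kouttyp;
};

static const double LOG2PI = 1.8378770664093453;

// log of inner integral over eta1 given q(eta2), by mode-centered
// Gauss-Hermite; also returns the posterior mean of eta1 given eta2.
static double inner_eta1(const Subject& s, const std::vector<double>& q,
                         double om1, double sig,
                         const std::vector<double>& ghz,
                         const std::vector<double>& ghw,
                         double* emean1) {
  size_t m = s.y.size();
  // a_j(eta1) = y_j / (sig * b0typ * q_j) * exp(-eta1); z_j = a_j - 1/sig
  std::vector<double> a0(m);
  double base = 0.0; // sum of -log(sig * b0typ * q_j) terms at eta1 = 0
  for (size_t j = 0; j < m; ++j) {
    a0[j] = s.y[j] / (sig * s.b0typ * q[j]);
    base += -std::log(sig * s.b0typ * q[j]);
  }
  double inv_sig = 1.0 / sig, iom2 = 1.0 / (om1 * om1);
  auto h_of = [&](double e1) {
    double h = base - m * e1 - 0.5 * LOG2PI * m;
    for (size_t j = 0; j < m; ++j) {
      double z = a0[j] * std::exp(-e1) - inv_sig;
      h += -0.5 * z * z;
    }
    h += -0.5 * LOG2PI - std::log(om1) - 0.5 * e1 * e1 * iom2;
    return h;
  };
  // Newton with analytic first/second derivatives
  double e1 = 0.0;
  double d2 = -1.0;
  for (int it = 0; it < 60; ++it) {
    double g1 = -(double)m - e1 * iom2, g2 = -iom2;
    for (size_t j = 0; j < m; ++j) {
      double aj = a0[j] * std::exp(-e1);
      double zj = aj - inv_sig;
      g1 += zj * aj;
      g2 += -aj * aj - zj * aj;
    }
    d2 = g2;
    if (g2 > -1e-10) { // safeguarded curvature (expected information)
      double fisher = iom2;
      for (size_t j = 0; j < m; ++j) {
        double aj = a0[j] * std::exp(-e1);
        fisher += aj * aj;
      }
      g2 = -fisher;
    }
    double step = -g1 / g2;
    if (step > 1.0) step = 1.0; else if (step < -1.0) step = -1.0;
    e1 += step;
    if (std::fabs(g1) < 1e-12 || std::fabs(step) < 1e-12) break;
  }
  if (d2 > -1e-10) d2 = -1e-10;
  double sh = 1.0 / std::sqrt(-d2);
  int Q = (int)ghz.size();
  double hmode = h_of(e1);
  double sm = 0.0, sme = 0.0;
  for (int k = 0; k < Q; ++k) {
    double ek = e1 + M_SQRT2 * sh * ghz[k];
    double t = ghw[k] * std::exp(h_of(ek) - hmode + ghz[k] * ghz[k]);
    sm += t;
    sme += t * ek;
  }
  *emean1 = sme / sm;
  return std::log(M_SQRT2 * sh) + hmode + std::log(sm);
}

// [[Rcpp::export]]
List cpp_marginal_ll(List subjects, NumericVector theta, double emax,
                     double kelim, NumericVector gh_z, NumericVector gh_w,
                     int grid_points = 160, double grid_width = 7.5,
                     double hmax = 0.5) {
  int n = subjects.size();
  double tvb0 = theta[0], bsaps = theta[1], bchl = theta[2],
         thcort = theta[3], tvkout = theta[4], fur50 = theta[5],
         a50 = theta[6], om1 = theta[7], om2 = theta[8], sig = theta[9];
  std::vector<double> ghz(gh_z.begin(), gh_z.end());
  std::vector<double> ghw(gh_w.begin(), gh_w.end());
  int G = grid_points;
  double total = 0.0;
  NumericMatrix etas(n, 2);
  // midpoint grid on the prior scale: eta2 = om2 * s, s in (-w, w)
  std::vector<double> sgrid(G), logprior2(G);
  double hstep = 2.0 * grid_width / G;
  for (int g = 0; g < G; ++g) {
    double sg = -grid_width + (g + 0.5) * hstep;
    sgrid[g] = sg;
    logprior2[g] = -0.5 * LOG2PI - 0.5 * sg * sg; // std normal in s
  }
  for (int i = 0; i < n; ++i) {
    List si = subjects[i];
    Subject s;
    NumericVector tobs = si["tobs"], y = si["y"], dt = si["dt"], da = si["da"];
    s.tobs.assign(tobs.begin(), tobs.end());
    s.y.assign(y.begin(), y.end());
    s.dt.assign(dt.begin(), dt.end());
    s.da.assign(da.begin(), da.end());
    double saps = si["saps2"], chl = si["chloride"], furo = si["furo"];
    int cort = si["cort"];
    s.b0typ = tvb0 * std::pow(saps / 50.0, bsaps) *
              std::pow(chl / 100.0, bchl) * (cort ? thcort : 1.0);
    s.kouttyp = tvkout * (1.0 - furo / (furo + fur50));
    size_t m = s.tobs.size();
    std::vector<double> q(m);
    std::vector<double> lterm(G), em1(G);
    double mx = -INFINITY;
    for (int g = 0; g < G; ++g) {
      double eta2 = om2 * sgrid[g];
      double kouti = s.kouttyp * std::exp(eta2);
      traj_core(s.tobs, s.dt, s.da, 1.0, kouti, a50, emax, kelim, hmax,
                q.data());
      bool ok = true;
      for (size_t j = 0; j < m; ++j)
        if (!std::isfinite(q[j]) || q[j] <= 0.0) ok = false;
      double t;
      if (ok) {
        double e1mean;
        t = logprior2[g] + inner_eta1(s, q, om1, sig, ghz, ghw, &e1mean);
        em1[g] = e1mean;
      } else {
        t = -INFINITY; em1[g] = 0.0;
      }
      lterm[g] = t;
      if (t > mx) mx = t;
    }
    // midpoint rule in s (the prior-standardized eta2)
    double sm = 0.0, sm2 = 0.0, sm1 = 0.0;
    for (int g = 0; g < G; ++g) {
      double w = std::exp(lterm[g] - mx);
      sm += w;
      sm2 += w * (om2 * sgrid[g]);
      sm1 += w * em1[g];
    }
    total += mx + std::log(sm * hstep);
    etas(i, 0) = sm1 / sm;       // posterior mean of eta1
    etas(i, 1) = sm2 / sm;       // posterior mean of eta2
  }
  return List::create(Named("loglik") = total, Named("etas") = etas);
}
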