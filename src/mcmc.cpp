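// MCMC engine for the two-state switching first-difference CRW state-space
// model. One sampler serves both the per-individual (single track) and the
// joint-estimation (multiple tracks, shared movement parameters) forms.
//
// Update scheme per sweep:
//   1. behavioural states b: exact forward-filtering backward-sampling,
//      with process densities as emissions (states enter only the process);
//   2. transition probabilities alpha: Beta conditional draw from pooled
//      transition counts, Metropolis-corrected for the stationary-
//      distribution term attached to b[1];
//   3. gamma, theta, Sigma: random-walk Metropolis, adaptive during burn-in;
//   4. psi (per individual, t-error tracks): random-walk Metropolis;
//   5. latent locations x_t: per-time random-walk Metropolis (skipped when
//      observations are error-free and x is observed exactly).
// Adaptation of proposal scales is frozen at the end of burn-in.
//
// All randomness comes from R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double dnorm2_log(double rx, double ry, double sx, double sy,
                                double rho) {
  double om = 1.0 - rho * rho;
  double zx = rx / sx, zy = ry / sy;
  double q = (zx * zx - 2.0 * rho * zx * zy + zy * zy) / om;
  return -std::log(2.0 * M_PI * sx * sy) - 0.5 * std::log(om) - 0.5 * q;
}

// location-scale t log density
static inline double dt_ls_log(double r, double scale, double nu) {
  double z = r / scale;
  return R::lgammafn(0.5 * (nu + 1.0)) - R::lgammafn(0.5 * nu) -
         0.5 * std::log(nu * M_PI) - std::log(scale) -
         0.5 * (nu + 1.0) * std::log1p(z * z / nu);
}

static inline double logsumexp2(double a, double b) {
  double m = (a > b) ? a : b;
  if (!std::isfinite(m)) return m;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// half-t(3) log prior on a positive scale (normalising constant dropped)
static inline double half_t3_log(double s, double A) {
  double z = s / A;
  return -2.0 * std::log1p(z * z / 3.0);
}

struct Par {
  double g[2];    // move persistence per state
  double th[2];   // turn angle per state
  double a1, a2;  // P(stay transient), P(ARS -> transient)
  double sx, sy, rho;  // process SDs (km) and correlation
};

struct Track {
  NumericMatrix y;       // n_obs x 2 observed locations
  std::vector<int> tidx; // 0-based latent interval per observation
  std::vector<double> j; // fraction of step elapsed before observation
  NumericMatrix tau;     // n_obs x 2 per-observation t scales
  std::vector<double> nu;
  int T;
  int obs_code;          // 0 none, 1 gaussian, 2 t
  NumericMatrix x;       // current latent path T x 2
  std::vector<int> b;    // current states, 0/1
  std::vector<std::vector<int>> touch; // obs indices involving x[t]
  double anc0[2], anc1[2];             // anchors for x1, x2 priors
};

// process log density of step t (t >= 2) under a given state
static inline double proc_term(const Track &tr, int t, int state,
                               const Par &p) {
  double dx = tr.x(t, 0) - tr.x(t - 1, 0);
  double dy = tr.x(t, 1) - tr.x(t - 1, 1);
  double px = tr.x(t - 1, 0) - tr.x(t - 2, 0);
  double py = tr.x(t - 1, 1) - tr.x(t - 2, 1);
  double c = std::cos(p.th[state]), s = std::sin(p.th[state]);
  double g = p.g[state];
  double mx = g * (c * px - s * py), my = g * (s * px + c * py);
  return dnorm2_log(dx - mx, dy - my, p.sx, p.sy, p.rho);
}

static double proc_ll_track(const Track &tr, const Par &p) {
  double ll = 0.0;
  for (int t = 2; t < tr.T; ++t) ll += proc_term(tr, t, tr.b[t], p);
  return ll;
}

// observation log density for obs i of a track (regime-specific)
static inline double obs_term(const Track &tr, int i, double psi,
                              double osx, double osy, double orho) {
  int t = tr.tidx[i];
  double jj = tr.j[i];
  double mx, my;
  if (jj > 0.0) {
    mx = (1.0 - jj) * tr.x(t, 0) + jj * tr.x(t + 1, 0);
    my = (1.0 - jj) * tr.x(t, 1) + jj * tr.x(t + 1, 1);
  } else {
    mx = tr.x(t, 0);
    my = tr.x(t, 1);
  }
  if (tr.obs_code == 1)
    return dnorm2_log(tr.y(i, 0) - mx, tr.y(i, 1) - my, osx, osy, orho);
  return dt_ls_log(tr.y(i, 0) - mx, psi * tr.tau(i, 0), tr.nu[i]) +
         dt_ls_log(tr.y(i, 1) - my, psi * tr.tau(i, 1), tr.nu[i]);
}

static double obs_ll_track(const Track &tr, double psi, double osx,
                           double osy, double orho) {
  if (tr.obs_code == 0) return 0.0;
  double ll = 0.0;
  for (int i = 0; i < tr.y.nrow(); ++i)
    ll += obs_term(tr, i, psi, osx, osy, orho);
  return ll;
}

static inline void stationary(const Par &p, double pi0[2]) {
  double s1 = 1.0 - p.a1, s2 = p.a2;  // switch rates out of states 0, 1
  if (s1 + s2 <= 0.0) {  // absorbing in both states: any mix is stationary
    pi0[0] = 0.5; pi0[1] = 0.5;
    return;
  }
  pi0[0] = s2 / (s1 + s2);
  pi0[1] = s1 / (s1 + s2);
}

// exact conditional draw of the state sequence (FFBS)
static void ffbs_track(Track &tr, const Par &p, std::vector<double> &lfwd) {
  int T = tr.T;
  double lA[2][2] = {{std::log(p.a1), std::log(1.0 - p.a1)},
                     {std::log(p.a2), std::log(1.0 - p.a2)}};
  double pi0[2];
  stationary(p, pi0);
  lfwd.resize(2 * T);
  for (int k = 0; k < 2; ++k) {
    lfwd[k] = std::log(pi0[k]);  // t = 0, no emission
  }
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < 2; ++k) {
      double em = (t >= 2) ? proc_term(tr, t, k, p) : 0.0;
      lfwd[2 * t + k] = em + logsumexp2(lfwd[2 * (t - 1)] + lA[0][k],
                                        lfwd[2 * (t - 1) + 1] + lA[1][k]);
    }
  }
  // backward sampling
  double l0 = lfwd[2 * (T - 1)], l1 = lfwd[2 * (T - 1) + 1];
  double p1 = 1.0 / (1.0 + std::exp(l0 - l1));
  tr.b[T - 1] = (R::unif_rand() < p1) ? 1 : 0;
  for (int t = T - 2; t >= 0; --t) {
    int nb = tr.b[t + 1];
    double w0 = lfwd[2 * t] + lA[0][nb];
    double w1 = lfwd[2 * t + 1] + lA[1][nb];
    double pr1 = 1.0 / (1.0 + std::exp(w0 - w1));
    tr.b[t] = (R::unif_rand() < pr1) ? 1 : 0;
  }
}

// local posterior terms touched by a move of x[t]
static double local_ll_x(const Track &tr, int t, const Par &p, double psi,
                         double osx, double osy, double orho,
                         double xinit_sd) {
  double ll = 0.0;
  for (int s = t; s <= t + 2; ++s)
    if (s >= 2 && s < tr.T) ll += proc_term(tr, s, tr.b[s], p);
  for (size_t k = 0; k < tr.touch[t].size(); ++k)
    ll += obs_term(tr, tr.touch[t][k], psi, osx, osy, orho);
  if (t == 0)
    ll += dnorm2_log(tr.x(0, 0) - tr.anc0[0], tr.x(0, 1) - tr.anc0[1],
                     xinit_sd, xinit_sd, 0.0);
  if (t == 1)
    ll += dnorm2_log(tr.x(1, 0) - tr.anc1[0], tr.x(1, 1) - tr.anc1[1],
                     xinit_sd, xinit_sd, 0.0);
  return ll;
}

struct Adapt {
  double lscale;
  int acc = 0, tries = 0, batch = 0;
  explicit Adapt(double s) : lscale(std::log(s)) {}
  double scale() const { return std::exp(lscale); }
  void update(double target) {
    ++batch;
    double rate = tries ? (double)acc / tries : 0.0;
    double delta = std::min(0.1, 1.0 / std::sqrt((double)batch));
    lscale += (rate > target) ? delta : -delta;
    acc = 0;
    tries = 0;
  }
};

// [[Rcpp::export]]
List run_switch_mcmc_cpp(List tracks, List init, List priors, List fixed,
                         int n_iter, int n_burnin, int thin) {
  int M = tracks.size();
  std::vector<Track> trs(M);
  for (int m = 0; m < M; ++m) {
    List tl = tracks[m];
    Track &tr = trs[m];
    tr.y = as<NumericMatrix>(tl["y"]);
    tr.tidx = as<std::vector<int>>(tl["tidx0"]);
    tr.j = as<std::vector<double>>(tl["j"]);
    tr.T = as<int>(tl["T"]);
    tr.obs_code = as<int>(tl["obs_code"]);
    tr.x = clone(as<NumericMatrix>(tl["x0"]));
    IntegerVector b0 = tl["b0"];
    tr.b.resize(tr.T);
    for (int t = 0; t < tr.T; ++t) tr.b[t] = b0[t] - 1;
    if (tr.obs_code == 2) {
      tr.tau = as<NumericMatrix>(tl["tau"]);
      tr.nu = as<std::vector<double>>(tl["nu"]);
    }
    tr.touch.assign(tr.T, std::vector<int>());
    for (int i = 0; i < tr.y.nrow(); ++i) {
      tr.touch[tr.tidx[i]].push_back(i);
      if (tr.j[i] > 0.0) tr.touch[tr.tidx[i] + 1].push_back(i);
    }
    NumericVector a0 = tl["anchor1"], a1 = tl["anchor2"];
    tr.anc0[0] = a0[0]; tr.anc0[1] = a0[1];
    tr.anc1[0] = a1[0]; tr.anc1[1] = a1[1];
  }

  Par p;
  {
    NumericVector g = init["gamma"], th = init["theta"], al = init["alpha"],
                  sg = init["sigma"];
    p.g[0] = g[0]; p.g[1] = g[1];
    p.th[0] = th[0]; p.th[1] = th[1];
    p.a1 = al[0]; p.a2 = al[1];
    p.sx = sg[0]; p.sy = sg[1]; p.rho = sg[2];
  }
  std::vector<double> psi = as<std::vector<double>>(init["psi"]);

  double A_sig = as<double>(priors["sigma_scale"]);
  double psi_max = as<double>(priors["psi_max"]);
  double th1_lo = as<double>(priors["theta1_lo"]),
         th1_hi = as<double>(priors["theta1_hi"]);
  double th2_lo = as<double>(priors["theta2_lo"]),
         th2_hi = as<double>(priors["theta2_hi"]);
  double xinit_sd = as<double>(priors["xinit_sd"]);

  double osx = 1.0, osy = 1.0, orho = 0.0;
  if (fixed.containsElementNamed("omega_sd")) {
    NumericVector om = fixed["omega_sd"];
    osx = om[0]; osy = om[1]; orho = om[2];
  }

  bool any_x = false, any_psi = false;
  for (int m = 0; m < M; ++m) {
    if (trs[m].obs_code != 0) any_x = true;
    if (trs[m].obs_code == 2) any_psi = true;
  }

  // adaptive proposal scales
  Adapt ad_g1(0.05), ad_g2(0.05), ad_th1(0.10), ad_th2(0.10), ad_sig(0.10);
  std::vector<Adapt> ad_psi(M, Adapt(0.10));
  double x_scale0 = as<double>(fixed["x_scale0"]);
  std::vector<Adapt> ad_x(M, Adapt(x_scale0));

  // retained draws: every thin-th post-burn-in iteration, counted so that
  // n_ret = floor((n_iter - n_burnin) / thin)
  int n_ret = (n_iter - n_burnin) / thin;
  int n_psi = M;
  int npar = 9 + n_psi;
  NumericMatrix out_par(n_ret, npar);
  List out_states(M), out_xmean(M);
  std::vector<IntegerMatrix> smat(M);
  std::vector<NumericMatrix> xacc(M);
  for (int m = 0; m < M; ++m) {
    smat[m] = IntegerMatrix(n_ret, trs[m].T);
    xacc[m] = NumericMatrix(trs[m].T, 2);
  }

  std::vector<double> lfwd;
  int ffbs_fail = 0;
  int ridx = 0;
  const int batch_len = 50;

  for (int it = 0; it < n_iter; ++it) {
    bool adapting = it < n_burnin;

    // 1. states
    for (int m = 0; m < M; ++m) ffbs_track(trs[m], p, lfwd);

    // 2. alpha: Beta conditional from pooled counts, MH-corrected for the
    //    stationary initial-state term
    {
      int n00 = 0, n01 = 0, n10 = 0, n11 = 0;
      for (int m = 0; m < M; ++m)
        for (int t = 1; t < trs[m].T; ++t) {
          int a = trs[m].b[t - 1], b = trs[m].b[t];
          if (a == 0) { if (b == 0) ++n00; else ++n01; }
          else        { if (b == 0) ++n10; else ++n11; }
        }
      double a1p = R::rbeta(1.0 + n00, 1.0 + n01);
      double a2p = R::rbeta(1.0 + n10, 1.0 + n11);
      Par pp = p;
      pp.a1 = a1p; pp.a2 = a2p;
      double pi_cur[2], pi_prop[2];
      stationary(p, pi_cur);
      stationary(pp, pi_prop);
      double lr = 0.0;
      for (int m = 0; m < M; ++m)
        lr += std::log(pi_prop[trs[m].b[0]]) - std::log(pi_cur[trs[m].b[0]]);
      if (std::log(R::unif_rand()) < lr) { p.a1 = a1p; p.a2 = a2p; }
    }

    // helper: process log lik over all tracks for trial parameters
    auto proc_ll_all = [&](const Par &q) {
      double ll = 0.0;
      for (int m = 0; m < M; ++m) ll += proc_ll_track(trs[m], q);
      return ll;
    };

    // 3a. gamma (ordered: 0 <= g2 < g1 <= 1; prior density 1/g1)
    {
      double cur_ll = proc_ll_all(p);
      double g1p = p.g[0] + ad_g1.scale() * R::norm_rand();
      ++ad_g1.tries;
      if (g1p > p.g[1] && g1p <= 1.0) {
        Par q = p; q.g[0] = g1p;
        double nll = proc_ll_all(q);
        double lr = nll - cur_ll - std::log(g1p) + std::log(p.g[0]);
        if (std::log(R::unif_rand()) < lr) { p = q; cur_ll = nll;
          ++ad_g1.acc; }
      }
      double g2p = p.g[1] + ad_g2.scale() * R::norm_rand();
      ++ad_g2.tries;
      if (g2p >= 0.0 && g2p < p.g[0]) {
        Par q = p; q.g[1] = g2p;
        double lr = proc_ll_all(q) - cur_ll;
        if (std::log(R::unif_rand()) < lr) { p = q; ++ad_g2.acc; }
      }
    }

    // 3b. theta (uniform priors on state-specific ranges)
    {
      double cur_ll = proc_ll_all(p);
      double t1p = p.th[0] + ad_th1.scale() * R::norm_rand();
      ++ad_th1.tries;
      if (t1p > th1_lo && t1p < th1_hi) {
        Par q = p; q.th[0] = t1p;
        double nll = proc_ll_all(q);
        if (std::log(R::unif_rand()) < nll - cur_ll) {
          p = q; cur_ll = nll; ++ad_th1.acc;
        }
      }
      double t2p = p.th[1] + ad_th2.scale() * R::norm_rand();
      ++ad_th2.tries;
      if (t2p > th2_lo && t2p < th2_hi) {
        Par q = p; q.th[1] = t2p;
        double nll = proc_ll_all(q);
        if (std::log(R::unif_rand()) < nll - cur_ll) {
          p = q; ++ad_th2.acc;
        }
      }
    }

    // 3c. Sigma: joint move on (log sx, log sy, atanh rho);
    //     half-t(3) priors on the SDs, uniform on the correlation
    {
      double cur_ll = proc_ll_all(p);
      double s = ad_sig.scale();
      double lsx = std::log(p.sx) + s * R::norm_rand();
      double lsy = std::log(p.sy) + s * R::norm_rand();
      double zr = std::atanh(p.rho) + s * R::norm_rand();
      Par q = p;
      q.sx = std::exp(lsx); q.sy = std::exp(lsy); q.rho = std::tanh(zr);
      ++ad_sig.tries;
      // Jacobians: d sx / d log sx = sx; d rho / d z = 1 - rho^2
      double lp_cur = half_t3_log(p.sx, A_sig) + half_t3_log(p.sy, A_sig) +
                      std::log(p.sx) + std::log(p.sy) +
                      std::log1p(-p.rho * p.rho);
      double lp_prop = half_t3_log(q.sx, A_sig) + half_t3_log(q.sy, A_sig) +
                       std::log(q.sx) + std::log(q.sy) +
                       std::log1p(-q.rho * q.rho);
      double lr = proc_ll_all(q) + lp_prop - cur_ll - lp_cur;
      if (std::log(R::unif_rand()) < lr) { p = q; ++ad_sig.acc; }
    }

    // 4. psi per individual (t-error tracks only; uniform (0, psi_max))
    if (any_psi) {
      for (int m = 0; m < M; ++m) {
        if (trs[m].obs_code != 2) continue;
        double cur = obs_ll_track(trs[m], psi[m], osx, osy, orho);
        double pp = psi[m] + ad_psi[m].scale() * R::norm_rand();
        ++ad_psi[m].tries;
        if (pp > 0.0 && pp < psi_max) {
          double nll = obs_ll_track(trs[m], pp, osx, osy, orho);
          if (std::log(R::unif_rand()) < nll - cur) {
            psi[m] = pp; ++ad_psi[m].acc;
          }
        }
      }
    }

    // 5. latent locations
    if (any_x) {
      for (int m = 0; m < M; ++m) {
        Track &tr = trs[m];
        if (tr.obs_code == 0) continue;
        double s = ad_x[m].scale();
        for (int t = 0; t < tr.T; ++t) {
          double ox = tr.x(t, 0), oy = tr.x(t, 1);
          double cur = local_ll_x(tr, t, p, psi[m], osx, osy, orho,
                                  xinit_sd);
          tr.x(t, 0) = ox + s * R::norm_rand();
          tr.x(t, 1) = oy + s * R::norm_rand();
          double prop = local_ll_x(tr, t, p, psi[m], osx, osy, orho,
                                   xinit_sd);
          ++ad_x[m].tries;
          if (std::log(R::unif_rand()) < prop - cur) {
            ++ad_x[m].acc;
          } else {
            tr.x(t, 0) = ox; tr.x(t, 1) = oy;
          }
        }
      }
    }

    // adaptation (burn-in only)
    if (adapting && (it + 1) % batch_len == 0) {
      ad_g1.update(0.44); ad_g2.update(0.44);
      ad_th1.update(0.44); ad_th2.update(0.44);
      ad_sig.update(0.30);
      for (int m = 0; m < M; ++m) {
        if (trs[m].obs_code == 2) ad_psi[m].update(0.44);
        if (trs[m].obs_code != 0) ad_x[m].update(0.30);
      }
    }

    // storage
    if (it >= n_burnin && (it - n_burnin + 1) % thin == 0 && ridx < n_ret) {
      out_par(ridx, 0) = p.g[0]; out_par(ridx, 1) = p.g[1];
      out_par(ridx, 2) = p.th[0]; out_par(ridx, 3) = p.th[1];
      out_par(ridx, 4) = p.a1; out_par(ridx, 5) = p.a2;
      out_par(ridx, 6) = p.sx; out_par(ridx, 7) = p.sy;
      out_par(ridx, 8) = p.rho;
      for (int m = 0; m < M; ++m) out_par(ridx, 9 + m) = psi[m];
      for (int m = 0; m < M; ++m) {
        for (int t = 0; t < trs[m].T; ++t) {
          smat[m](ridx, t) = trs[m].b[t] + 1;
          xacc[m](t, 0) += trs[m].x(t, 0);
          xacc[m](t, 1) += trs[m].x(t, 1);
        }
      }
      ++ridx;
    }
  }

  for (int m = 0; m < M; ++m) {
    if (n_ret > 0) {
      for (int t = 0; t < trs[m].T; ++t) {
        xacc[m](t, 0) /= n_ret;
        xacc[m](t, 1) /= n_ret;
      }
    }
    out_states[m] = smat[m];
    out_xmean[m] = xacc[m];
  }

  return List::create(
      _["params"] = out_par, _["states"] = out_states,
      _["x_mean"] = out_xmean, _["n_retained"] = n_ret,
      _["ffbs_fail"] = ffbs_fail,
      _["scales"] = NumericVector::create(
          _["gamma1"] = ad_g1.scale(), _["gamma2"] = ad_g2.scale(),
          _["theta1"] = ad_th1.scale(), _["theta2"] = ad_th2.scale(),
          _["sigma"] = ad_sig.scale()));
}

// Repeated exact conditional draws of the state sequence for a fixed path
// and fixed parameters (used for oracle checks and diagnostics).
// [[Rcpp::export]]
IntegerMatrix ffbs_draws_cpp(NumericMatrix x, NumericVector gamma,
                             NumericVector theta, NumericVector sigma,
                             NumericVector alpha, int n_draws) {
  Track tr;
  tr.x = x;
  tr.T = x.nrow();
  tr.obs_code = 0;
  tr.b.assign(tr.T, 0);
  Par p;
  p.g[0] = gamma[0]; p.g[1] = gamma[1];
  p.th[0] = theta[0]; p.th[1] = theta[1];
  p.a1 = alpha[0]; p.a2 = alpha[1];
  p.sx = sigma[0]; p.sy = sigma[1]; p.rho = sigma[2];
  IntegerMatrix out(n_draws, tr.T);
  std::vector<double> lfwd;
  for (int d = 0; d < n_draws; ++d) {
    ffbs_track(tr, p, lfwd);
    for (int t = 0; t < tr.T; ++t) out(d, t) = tr.b[t] + 1;
  }
  return out;
}
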