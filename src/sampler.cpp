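// Hierarchical effort-discounting choice model: log posterior with analytic
// gradients, and an adaptive No-U-Turn sampler (multinomial variant, diagonal
// metric, dual-averaging step size) operating on the unconstrained scale.
//
// Parameter vector layout (must match R side, see R/inference.R):
//   for each parameter family f in {kappa_self, [kappa_effect], log_beta,
//   [beta_effect]} (bracketed families present only for 2-kappa / 2-beta
//   models), a contiguous block [mu_f, log_sigma_f, z_f1 .. z_fS] where S is
//   the number of subjects.  Subject-level raw value: raw_fi = mu_f +
//   exp(log_sigma_f) * z_fi (non-centred parameterization).
//
// Links (unconstrained -> natural):
//   linear/parabolic : kappa = -softplus(raw)          (kappa <= 0)
//   hyperbolic       : kappa = -0.2 * logistic(raw)    (kappa in (-0.2, 0))
//   beta             : beta  = exp(raw)
// Effect coding applied on the raw scale: raw_other = raw_self + raw_effect.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct ChoiceData {
  std::vector<int> subj;    // 0-based subject index
  std::vector<int> recip;   // 0 = self, 1 = other
  std::vector<double> effort;   // 1..5
  std::vector<double> shock;    // -5..-1
  std::vector<int> choice;  // 1 = work, 0 = rest
  int n_subj;
  int n_trial;
  // trials aggregated into (subject, recipient, effort, shock) cells: the
  // likelihood only depends on per-cell work/total counts
  std::vector<int> c_subj, c_recip, c_work, c_tot;
  std::vector<double> c_effort, c_shock;

  void aggregate() {
    std::vector<int> work(n_subj * 2 * 25, 0), tot(n_subj * 2 * 25, 0);
    for (int t = 0; t < n_trial; ++t) {
      int e = (int)effort[t] - 1;       // 0..4
      int s = (int)shock[t] + 5;        // 0..4
      int idx = ((subj[t] * 2 + recip[t]) * 5 + e) * 5 + s;
      tot[idx] += 1;
      work[idx] += choice[t];
    }
    for (int i = 0; i < n_subj; ++i)
      for (int r = 0; r < 2; ++r)
        for (int e = 0; e < 5; ++e)
          for (int s = 0; s < 5; ++s) {
            int idx = ((i * 2 + r) * 5 + e) * 5 + s;
            if (tot[idx] == 0) continue;
            c_subj.push_back(i);
            c_recip.push_back(r);
            c_effort.push_back(e + 1.0);
            c_shock.push_back(s - 5.0);
            c_work.push_back(work[idx]);
            c_tot.push_back(tot[idx]);
          }
  }
};

struct ModelCfg {
  int shape;      // 0 linear, 1 parabolic, 2 hyperbolic
  bool two_kappa;
  bool two_beta;
  bool centered;  // centered (subject values) vs non-centered (z-scores)
  int n_fam() const { return 2 + (two_kappa ? 1 : 0) + (two_beta ? 1 : 0); }
};

inline double softplus(double x) {
  if (x > 30.0) return x;
  if (x < -30.0) return std::exp(x);
  return std::log1p(std::exp(x));
}
inline double logistic(double x) {
  if (x >= 0) { double e = std::exp(-x); return 1.0 / (1.0 + e); }
  double e = std::exp(x); return e / (1.0 + e);
}
// log(1/(1+exp(-x))) computed without overflow
inline double log_sigmoid(double x) {
  if (x < -30.0) return x;
  return -std::log1p(std::exp(-x));
}

ChoiceData as_data(const List& d) {
  ChoiceData out;
  IntegerVector s = d["subj"], r = d["recip"], c = d["choice"];
  NumericVector e = d["effort"], k = d["shock"];
  out.n_subj = as<int>(d["n_subj"]);
  out.n_trial = s.size();
  out.subj.assign(s.begin(), s.end());
  out.recip.assign(r.begin(), r.end());
  out.choice.assign(c.begin(), c.end());
  out.effort.assign(e.begin(), e.end());
  out.shock.assign(k.begin(), k.end());
  out.aggregate();
  return out;
}

ModelCfg as_model(const List& m) {
  ModelCfg cfg;
  cfg.shape = as<int>(m["shape"]);
  cfg.two_kappa = as<bool>(m["two_kappa"]);
  cfg.two_beta = as<bool>(m["two_beta"]);
  cfg.centered = m.containsElementNamed("centered") ? as<bool>(m["centered"])
                                                    : false;
  return cfg;
}

// family offsets in the parameter vector
struct Layout {
  int ks, keff, lb, beff;  // block starts; -1 if absent
  int S, dim;
  Layout(const ModelCfg& cfg, int S_) : S(S_) {
    int blk = S + 2, pos = 0;
    ks = pos; pos += blk;
    keff = cfg.two_kappa ? pos : -1; if (cfg.two_kappa) pos += blk;
    lb = pos; pos += blk;
    beff = cfg.two_beta ? pos : -1; if (cfg.two_beta) pos += blk;
    dim = pos;
  }
};

// kappa link and derivative wrt raw
inline void kappa_link(int shape, double raw, double& k, double& dk) {
  if (shape == 2) {  // hyperbolic
    double s = logistic(raw);
    k = -0.2 * s;
    dk = -0.2 * s * (1.0 - s);
  } else {
    k = -softplus(raw);
    dk = -logistic(raw);
  }
}

// delta SV (sv_work - sv_rest) and derivative wrt kappa; sv_rest = -6
inline void delta_sv(int shape, double kappa, double E, double shock,
                     double& d, double& dd_dk) {
  if (shape == 0) {            // linear
    d = shock + kappa * E + 6.0;
    dd_dk = E;
  } else if (shape == 1) {     // parabolic
    d = shock + kappa * E * E + 6.0;
    dd_dk = E * E;
  } else {                     // hyperbolic
    double den = 1.0 + kappa * E;
    d = shock / den + 6.0;
    dd_dk = -shock * E / (den * den);
  }
}

// log posterior and gradient; returns log posterior
double logpost_grad(const std::vector<double>& th, std::vector<double>& g,
                    const ChoiceData& dat, const ModelCfg& cfg,
                    const Layout& L) {
  const int S = L.S;
  std::fill(g.begin(), g.end(), 0.0);

  // unpack family blocks -> per-subject raw values
  auto raw_of = [&](int off, int i) {
    if (cfg.centered) return th[off + 2 + i];
    return th[off] + std::exp(th[off + 1]) * th[off + 2 + i];
  };

  std::vector<double> kself(S), kother(S), dks(S), dko(S);
  std::vector<double> bself(S), bother(S);
  for (int i = 0; i < S; ++i) {
    double r_ks = raw_of(L.ks, i);
    double r_keff = cfg.two_kappa ? raw_of(L.keff, i) : 0.0;
    kappa_link(cfg.shape, r_ks, kself[i], dks[i]);
    if (cfg.two_kappa) {
      kappa_link(cfg.shape, r_ks + r_keff, kother[i], dko[i]);
    } else {
      kother[i] = kself[i]; dko[i] = dks[i];
    }
    double r_lb = raw_of(L.lb, i);
    double r_beff = cfg.two_beta ? raw_of(L.beff, i) : 0.0;
    bself[i] = std::exp(r_lb);
    bother[i] = std::exp(r_lb + r_beff);
  }

  // per-subject gradient wrt raw values
  std::vector<double> g_rks(S, 0.0), g_rkeff(S, 0.0), g_rlb(S, 0.0),
      g_rbeff(S, 0.0);

  double lp = 0.0;
  const int n_cell = (int)dat.c_subj.size();
  for (int t = 0; t < n_cell; ++t) {
    int i = dat.c_subj[t];
    bool other = dat.c_recip[t] == 1;
    double kap = other ? kother[i] : kself[i];
    double bet = other ? bother[i] : bself[i];
    double n_work = dat.c_work[t], n_tot = dat.c_tot[t];
    double d, dd_dk;
    delta_sv(cfg.shape, kap, dat.c_effort[t], dat.c_shock[t], d, dd_dk);
    double u = bet * d;
    // one exp + one log1p per cell: p, log p(work), log p(rest)
    double p, lw, lr;
    if (u >= 0) {
      double e = std::exp(-u), l1 = std::log1p(e);
      p = 1.0 / (1.0 + e);
      lw = -l1;
      lr = -u - l1;
    } else {
      double e = std::exp(u), l1 = std::log1p(e);
      p = e / (1.0 + e);
      lw = u - l1;
      lr = -l1;
    }
    lp += n_work * lw + (n_tot - n_work) * lr;
    double gu = n_work - n_tot * p;  // d lp / d u
    double g_kap = gu * bet * dd_dk;
    double g_rawb = gu * d * bet;  // d beta/d raw = beta
    if (other) {
      g_rks[i] += g_kap * dko[i];
      if (cfg.two_kappa) g_rkeff[i] += g_kap * dko[i];
      g_rlb[i] += g_rawb;
      if (cfg.two_beta) g_rbeff[i] += g_rawb;
    } else {
      g_rks[i] += g_kap * dks[i];
      g_rlb[i] += g_rawb;
    }
  }

  // priors + map raw-gradients back to (mu, log_sigma, subject block)
  auto fam = [&](int off, const std::vector<double>& graw) {
    double mu = th[off], ls = th[off + 1], sig = std::exp(ls);
    lp += -0.5 * mu * mu;          // mu ~ N(0,1)
    lp += -0.5 * sig * sig + ls;   // sigma ~ half-N(0,1), + log-Jacobian
    g[off] += -mu;
    g[off + 1] += -sig * sig + 1.0;
    if (cfg.centered) {
      double inv_s2 = 1.0 / (sig * sig);
      for (int i = 0; i < S; ++i) {
        double d = th[off + 2 + i] - mu;   // theta_i ~ N(mu, sigma)
        lp += -0.5 * d * d * inv_s2 - ls;
        g[off + 2 + i] += -d * inv_s2 + graw[i];
        g[off] += d * inv_s2;
        g[off + 1] += d * d * inv_s2 - 1.0;
      }
    } else {
      double sum_g = 0.0, sum_gz = 0.0;
      for (int i = 0; i < S; ++i) {
        double z = th[off + 2 + i];
        lp += -0.5 * z * z;          // z ~ N(0,1)
        g[off + 2 + i] += -z + sig * graw[i];
        sum_g += graw[i];
        sum_gz += graw[i] * z;
      }
      g[off] += sum_g;
      g[off + 1] += sig * sum_gz;
    }
  };
  fam(L.ks, g_rks);
  if (cfg.two_kappa) fam(L.keff, g_rkeff);
  fam(L.lb, g_rlb);
  if (cfg.two_beta) fam(L.beff, g_rbeff);
  return lp;
}

// ---------------------------------------------------------------- NUTS ----

struct Hamiltonian {
  const ChoiceData& dat;
  const ModelCfg& cfg;
  const Layout& L;
  std::vector<double> inv_mass;  // ~ posterior variances
  long n_grad = 0;

  Hamiltonian(const ChoiceData& d, const ModelCfg& c, const Layout& l)
      : dat(d), cfg(c), L(l), inv_mass(l.dim, 1.0) {}

  double lp_grad(const std::vector<double>& q, std::vector<double>& g) {
    ++n_grad;
    return logpost_grad(q, g, dat, cfg, L);
  }
  double kinetic(const std::vector<double>& p) const {
    double k = 0.0;
    for (int j = 0; j < L.dim; ++j) k += inv_mass[j] * p[j] * p[j];
    return 0.5 * k;
  }
  void sample_momentum(std::vector<double>& p) const {
    for (int j = 0; j < L.dim; ++j)
      p[j] = R::rnorm(0.0, 1.0) / std::sqrt(inv_mass[j]);
  }
};

struct State {
  std::vector<double> q, p, grad;
  double lp;
};

void leapfrog(Hamiltonian& H, State& s, double eps) {
  const int D = s.q.size();
  for (int j = 0; j < D; ++j) s.p[j] += 0.5 * eps * s.grad[j];
  for (int j = 0; j < D; ++j) s.q[j] += eps * H.inv_mass[j] * s.p[j];
  s.lp = H.lp_grad(s.q, s.grad);
  for (int j = 0; j < D; ++j) s.p[j] += 0.5 * eps * s.grad[j];
}

inline double log_sum_exp(double a, double b) {
  double m = std::max(a, b);
  if (!std::isfinite(m)) return m;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

struct Tree {
  State minus, plus, prop;
  double log_w;     // multinomial weight of subtree
  bool ok;          // no u-turn, no divergence
  double sum_alpha; // accept-stat accumulator
  int n_alpha;
};

bool no_uturn(const Hamiltonian& H, const State& minus, const State& plus) {
  double a = 0.0, b = 0.0;
  for (size_t j = 0; j < minus.q.size(); ++j) {
    double dq = plus.q[j] - minus.q[j];
    a += dq * H.inv_mass[j] * minus.p[j];
    b += dq * H.inv_mass[j] * plus.p[j];
  }
  return a >= 0.0 && b >= 0.0;
}

void build_tree(Hamiltonian& H, const State& z, int depth, int dir, double eps,
                double H0, Tree& out, int& divergences) {
  if (depth == 0) {
    State s = z;
    leapfrog(H, s, dir * eps);
    double h = s.lp - H.kinetic(s.p);
    double dH = h - H0;
    if (!std::isfinite(dH) || dH < -1000.0) {
      ++divergences;
      out.ok = false;
      out.log_w = -INFINITY;
      out.minus = out.plus = out.prop = s;
      out.sum_alpha = 0.0; out.n_alpha = 1;
      return;
    }
    out.minus = out.plus = out.prop = s;
    out.log_w = dH;
    out.ok = true;
    out.sum_alpha = std::min(1.0, std::exp(dH));
    out.n_alpha = 1;
    return;
  }
  Tree first;
  build_tree(H, z, depth - 1, dir, eps, H0, first, divergences);
  if (!first.ok) { out = first; return; }
  Tree second;
  const State& edge = (dir == 1) ? first.plus : first.minus;
  build_tree(H, edge, depth - 1, dir, eps, H0, second, divergences);
  out.sum_alpha = first.sum_alpha + second.sum_alpha;
  out.n_alpha = first.n_alpha + second.n_alpha;
  out.minus = (dir == 1) ? first.minus : second.minus;
  out.plus = (dir == 1) ? second.plus : first.plus;
  out.log_w = log_sum_exp(first.log_w, second.log_w);
  if (!second.ok) { out.ok = false; out.prop = first.prop; return; }
  // multinomial sampling between subtrees
  double pr = std::exp(second.log_w - out.log_w);
  out.prop = (unif_rand() < pr) ? second.prop : first.prop;
  out.ok = no_uturn(H, out.minus, out.plus);
}

// one NUTS transition; returns accept-stat mean
double nuts_step(Hamiltonian& H, State& cur, double eps, int max_depth,
                 int& divergences, int& tree_depth) {
  H.sample_momentum(cur.p);
  double H0 = cur.lp - H.kinetic(cur.p);
  State minus = cur, plus = cur, prop = cur;
  double log_w = 0.0;  // weight of initial point relative to H0
  double sum_alpha = 0.0;
  int n_alpha = 0;
  tree_depth = 0;
  for (int depth = 0; depth < max_depth; ++depth) {
    int dir = (unif_rand() < 0.5) ? -1 : 1;
    Tree sub;
    build_tree(H, (dir == 1) ? plus : minus, depth, dir, eps, H0, sub,
               divergences);
    sum_alpha += sub.sum_alpha;
    n_alpha += sub.n_alpha;
    if (!sub.ok) break;
    // biased progressive sampling toward the new subtree
    double pr = std::exp(std::min(0.0, sub.log_w - log_w));
    if (unif_rand() < pr) prop = sub.prop;
    log_w = log_sum_exp(log_w, sub.log_w);
    if (dir == 1) plus = sub.plus; else minus = sub.minus;
    tree_depth = depth + 1;
    if (!no_uturn(H, minus, plus)) break;
  }
  cur = prop;
  return n_alpha > 0 ? sum_alpha / n_alpha : 0.0;
}

struct DualAvg {
  double mu, log_eps, log_eps_bar, h_bar;
  double gamma = 0.05, t0 = 10.0, kappa = 0.75, delta = 0.8;
  int m = 0;
  void init(double eps0) {
    mu = std::log(10.0 * eps0);
    log_eps = std::log(eps0);
    log_eps_bar = 0.0;
    h_bar = 0.0;
    m = 0;
  }
  void update(double alpha) {
    ++m;
    h_bar = (1.0 - 1.0 / (m + t0)) * h_bar + (delta - alpha) / (m + t0);
    log_eps = mu - std::sqrt((double)m) / gamma * h_bar;
    double w = std::pow((double)m, -kappa);
    log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
  }
  double eps() const { return std::exp(log_eps); }
  double eps_bar() const { return std::exp(log_eps_bar); }
};

double find_initial_eps(Hamiltonian& H, const State& init) {
  double eps = 0.1;
  State s = init;
  H.sample_momentum(s.p);
  std::vector<double> p0 = s.p;
  double H0 = s.lp - H.kinetic(s.p);
  State t = s;
  leapfrog(H, t, eps);
  double dH = (t.lp - H.kinetic(t.p)) - H0;
  if (!std::isfinite(dH)) dH = -1e10;
  int dir = dH > std::log(0.5) ? 1 : -1;
  for (int it = 0; it < 50; ++it) {
    eps = dir == 1 ? eps * 2.0 : eps * 0.5;
    t = s; t.p = p0;
    leapfrog(H, t, eps);
    dH = (t.lp - H.kinetic(t.p)) - H0;
    if (!std::isfinite(dH)) dH = -1e10;
    if ((dir == 1 && dH <= std::log(0.5)) || (dir == -1 && dH >= std::log(0.5)))
      break;
  }
  return eps;
}

}  // namespace

// [[Rcpp::export]]
List nuts_chain(List data, List model, NumericVector init, int n_warmup,
                int n_samples, int max_depth = 10,
                double adapt_delta = 0.8) {
  ChoiceData dat = as_data(data);
  ModelCfg cfg = as_model(model);
  Layout L(cfg, dat.n_subj);
  if ((int)init.size() != L.dim) stop("init has wrong length");

  Hamiltonian H(dat, cfg, L);
  State cur;
  cur.q.assign(init.begin(), init.end());
  cur.p.assign(L.dim, 0.0);
  cur.grad.assign(L.dim, 0.0);
  cur.lp = H.lp_grad(cur.q, cur.grad);
  if (!std::isfinite(cur.lp)) stop("non-finite log posterior at init");

  int divergences = 0, post_divergences = 0, tree_depth = 0;

  // Stan-style warmup windows: stepsize-only buffer, expanding metric
  // windows, terminal stepsize buffer.
  int init_buf = std::min(75, n_warmup / 4);
  int term_buf = std::min(50, n_warmup / 4);
  int window = 25;

  DualAvg da;
  da.delta = adapt_delta;
  da.init(find_initial_eps(H, cur));
  double eps = da.eps();

  std::vector<double> w_mean(L.dim, 0.0), w_m2(L.dim, 0.0);
  long w_n = 0;
  auto welford_add = [&](const std::vector<double>& q) {
    ++w_n;
    for (int j = 0; j < L.dim; ++j) {
      double d = q[j] - w_mean[j];
      w_mean[j] += d / w_n;
      w_m2[j] += d * (q[j] - w_mean[j]);
    }
  };
  auto welford_reset = [&]() {
    w_n = 0;
    std::fill(w_mean.begin(), w_mean.end(), 0.0);
    std::fill(w_m2.begin(), w_m2.end(), 0.0);
  };

  int next_window_end = init_buf + window;
  for (int it = 0; it < n_warmup; ++it) {
    eps = da.eps();
    double alpha = nuts_step(H, cur, eps, max_depth, divergences, tree_depth);
    da.update(alpha);
    bool in_metric_phase = it >= init_buf && it < n_warmup - term_buf;
    if (in_metric_phase) {
      welford_add(cur.q);
      bool window_done = (it + 1 == next_window_end) ||
                         (it + 1 == n_warmup - term_buf);
      if (window_done && w_n > 5) {
        for (int j = 0; j < L.dim; ++j) {
          double var = w_m2[j] / (w_n - 1);
          H.inv_mass[j] =
              var * ((double)w_n / (w_n + 5.0)) + 1e-3 * (5.0 / (w_n + 5.0));
        }
        welford_reset();
        window *= 2;
        next_window_end = it + 1 + window;
        // refresh the log posterior/gradient cache and restart stepsize
        cur.lp = H.lp_grad(cur.q, cur.grad);
        da.init(find_initial_eps(H, cur));
      }
    }
  }
  eps = da.eps_bar();

  NumericMatrix draws(n_samples, L.dim);
  IntegerVector depths(n_samples);
  double accept_sum = 0.0;
  for (int it = 0; it < n_samples; ++it) {
    accept_sum +=
        nuts_step(H, cur, eps, max_depth, post_divergences, tree_depth);
    depths[it] = tree_depth;
    for (int j = 0; j < L.dim; ++j) draws(it, j) = cur.q[j];
  }

  return List::create(
      _["draws"] = draws, _["step_size"] = eps,
      _["inv_mass"] = NumericVector(H.inv_mass.begin(), H.inv_mass.end()),
      _["divergences_warmup"] = divergences,
      _["divergences"] = post_divergences,
      _["mean_accept"] = accept_sum / std::max(1, n_samples),
      _["tree_depth"] = depths, _["n_grad"] = (double)H.n_grad);
}

// [[Rcpp::export]]
double logpost_cpp(List data, List model, NumericVector theta) {
  ChoiceData dat = as_data(data);
  ModelCfg cfg = as_model(model);
  Layout L(cfg, dat.n_subj);
  if ((int)theta.size() != L.dim) stop("theta has wrong length");
  std::vector<double> th(theta.begin(), theta.end()), g(L.dim);
  return logpost_grad(th, g, dat, cfg, L);
}

// [[Rcpp::export]]
NumericVector gradient_cpp(List data, List model, NumericVector theta) {
  ChoiceData dat = as_data(data);
  ModelCfg cfg = as_model(model);
  Layout L(cfg, dat.n_subj);
  if ((int)theta.size() != L.dim) stop("theta has wrong length");
  std::vector<double> th(theta.begin(), theta.end()), g(L.dim);
  logpost_grad(th, g, dat, cfg, L);
  return NumericVector(g.begin(), g.end());
}

// Pointwise log-likelihood matrix (draws x trials) for PSIS-LOO.
// [[Rcpp::export]]
NumericMatrix pointwise_loglik_cpp(NumericMatrix draws, List data,
                                   List model) {
  ChoiceData dat = as_data(data);
  ModelCfg cfg = as_model(model);
  Layout L(cfg, dat.n_subj);
  if (draws.ncol() != L.dim) stop("draws have wrong dimension");
  const int S = L.S, ndr = draws.nrow();
  NumericMatrix out(ndr, dat.n_trial);
  std::vector<double> kself(S), kother(S), bself(S), bother(S);
  for (int s = 0; s < ndr; ++s) {
    auto raw_at = [&](int off, int i) {
      if (cfg.centered) return draws(s, off + 2 + i);
      return draws(s, off) + std::exp(draws(s, off + 1)) * draws(s, off + 2 + i);
    };
    for (int i = 0; i < S; ++i) {
      double dk;
      double r_ks = raw_at(L.ks, i);
      kappa_link(cfg.shape, r_ks, kself[i], dk);
      if (cfg.two_kappa) {
        kappa_link(cfg.shape, r_ks + raw_at(L.keff, i), kother[i], dk);
      } else {
        kother[i] = kself[i];
      }
      double r_lb = raw_at(L.lb, i);
      bself[i] = std::exp(r_lb);
      if (cfg.two_beta) {
        bother[i] = std::exp(r_lb + raw_at(L.beff, i));
      } else {
        bother[i] = bself[i];
      }
    }
    for (int t = 0; t < dat.n_trial; ++t) {
      int i = dat.subj[t];
      bool other = dat.recip[t] == 1;
      double kap = other ? kother[i] : kself[i];
      double bet = other ? bother[i] : bself[i];
      double d, dd;
      delta_sv(cfg.shape, kap, dat.effort[t], dat.shock[t], d, dd);
      double u = bet * d;
      out(s, t) = dat.choice[t] ? log_sigmoid(u) : log_sigmoid(-u);
    }
  }
  return out;
}
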