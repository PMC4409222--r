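// Metropolis-within-Gibbs sampler for the normal/independent hierarchical
// model of differential expression.  All randomness goes through R's RNG so
// a single set.seed() call governs the whole chain.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// family codes shared with R/families.R
enum Family { FAM_NORMAL = 0, FAM_T = 1, FAM_SLASH = 2, FAM_CN = 3,
              FAM_LAPLACE = 4 };

static const double T_MH_STEP = 0.5;  // random walk sd on log t-df

// hyperprior settings: Gamma(shape, rate) on every precision (and on the
// slash/Laplace shapes), uniform(0, t_df_max) on the t degrees of freedom
struct Hyper { double shape, rate, t_df_max; };

// ---------------------------------------------------------------------------
// Truncated Gamma(shape, rate) on (0,1), exact.
// Rejection from Gamma when enough mass lies below 1, inverse cdf otherwise.
static double rtrunc_gamma01(double shape, double rate) {
  const double a = shape, b = rate;
  if (b < 1e-12) {
    // density ~ u^{a-1} on (0,1): inverse cdf directly
    return std::pow(R::unif_rand(), 1.0 / a);
  }
  if (b <= 2.0) {
    // Beta(a,1) proposal, accept with exp(-b u); acceptance >= exp(-b)
    for (int tries = 0; tries < 200; ++tries) {
      double u = std::pow(R::unif_rand(), 1.0 / a);
      if (std::log(R::unif_rand()) < -b * u) return (u > 0.0) ? u : 1e-300;
    }
  } else if ((b - a + 1.0) / std::sqrt(a) >= -0.5) {
    // ample mass below 1: rejection from the untruncated gamma
    for (int tries = 0; tries < 200; ++tries) {
      double x = R::rgamma(a, 1.0 / b);
      if (x < 1.0) return (x > 0.0) ? x : 1e-300;
    }
  } else if (a - 1.0 - b >= 1.0) {
    // mode above 1, mass piled at 1: exponential-tilt envelope from
    // log u <= u - 1, i.e. u^{a-1} e^{-b(u-1)} <= e^{(a-1-b)(u-1)}
    double c = a - 1.0 - b;
    double e0 = std::exp(-c);  // proposal: density ~ exp(c(u-1)) on (0,1)
    for (int tries = 0; tries < 200; ++tries) {
      double u = 1.0 + std::log(e0 + R::unif_rand() * (1.0 - e0)) / c;
      if (u <= 0.0) continue;
      double lacc = (a - 1.0) * (std::log(u) - (u - 1.0));
      if (std::log(R::unif_rand()) < lacc) return u;
    }
  }
  // narrow in-between band (or rejection cap): log-space inverse cdf,
  // immune to underflow of P(X <= 1)
  double scale = 1.0 / b;
  double lp1 = R::pgamma(1.0, a, scale, 1, 1);
  double u = R::qgamma(lp1 + std::log(R::unif_rand()), a, scale, 1, 1);
  if (!(u > 0.0)) u = 1e-300;
  if (u >= 1.0) u = 1.0 - 1e-12;
  return u;
}

// Inverse-Gaussian(mu, lambda) draw (Michael, Schucany & Haas).
static double rinvgauss(double mu, double lambda) {
  double z = R::norm_rand();
  double y = z * z;
  // larger root first (pure additions), smaller as mu^2 / x2: avoids the
  // catastrophic cancellation of the textbook smaller-root formula when
  // mu * y >> lambda
  double s = std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  double x2 = mu + (mu * mu * y + mu * s) / (2.0 * lambda);
  double x1 = mu * mu / x2;
  if (!(x1 > 0.0)) x1 = 1e-300;
  if (R::unif_rand() <= mu / (mu + x1)) return x1;
  return x2;
}

// One draw of the latent scale u given residual e, error precision tau and
// the family shape parameters.  Kernel: u^{1/2} exp(-u tau e^2/2) g(u; nu).
static double draw_scale_one(double e, double tau, int family,
                             const double *nu) {
  double e2t = tau * e * e;
  switch (family) {
  case FAM_NORMAL:
    return 1.0;
  case FAM_T: {
    double v = nu[0];
    return R::rgamma(0.5 * (v + 1.0), 2.0 / (v + e2t));
  }
  case FAM_SLASH: {
    double v = nu[0];
    return rtrunc_gamma01(v + 0.5, 0.5 * e2t);
  }
  case FAM_CN: {
    double lam = nu[0], gam = nu[1];
    // two-point conditional: log weights at u = gamma and u = 1
    double lw1 = std::log(lam) + 0.5 * std::log(gam) - 0.5 * gam * e2t;
    double lw2 = std::log1p(-lam) - 0.5 * e2t;
    double p1 = 1.0 / (1.0 + std::exp(lw2 - lw1));
    return (R::unif_rand() < p1) ? gam : 1.0;
  }
  case FAM_LAPLACE: {
    double v = nu[0];
    if (e2t < 1e-12) {
      // kernel u^{-3/2} exp(-v/u): 1/u ~ Gamma(1/2, rate v)
      double w = R::rgamma(0.5, 1.0 / v);
      if (!(w > 0.0)) w = 1e-300;
      return 1.0 / w;
    }
    double mu = std::sqrt(2.0 * v / e2t);
    return rinvgauss(mu, 2.0 * v);
  }
  }
  return 1.0;
}

// [[Rcpp::export(name = ".cpp_draw_scale")]]
NumericVector cpp_draw_scale(int n, double e, double tau, int family,
                             NumericVector nu) {
  NumericVector out(n);
  std::vector<double> nv(nu.begin(), nu.end());
  nv.resize(2, 1.0);
  for (int i = 0; i < n; ++i)
    out[i] = draw_scale_one(e, tau, family, nv.data());
  return out;
}

// ---------------------------------------------------------------------------
// log full conditional of the t degrees of freedom given latent scales,
// up to a constant: u_j ~ Gamma(v/2, rate v/2) iid.
static double t_df_logcond(double v, int n, double sum_log_u, double sum_u) {
  double h = 0.5 * v;
  return n * (h * std::log(h) - R::lgammafn(h)) + h * sum_log_u - h * sum_u;
}

struct ModelData {
  int N, n, k, P;
  const double *Y;           // N x n, column major
  IntegerVector grp;         // 0-based group per sample column
  IntegerMatrix block_of;    // P x k: block id of group g under pattern j
  IntegerMatrix prec_of;     // P x k: precision index of block b (slot b),
                             // -1 for unused slots; 0 = shared, 1..k = per-group
  IntegerVector nblocks;     // blocks per pattern
};

struct ChainState {
  NumericMatrix mu;       // N x k
  NumericMatrix u;        // N x n
  NumericVector tau_eps;  // N
  NumericMatrix nu;       // N x 2 (cols used depend on family)
  IntegerVector z;        // N, 0-based pattern index
  NumericVector p;        // P
  NumericVector tau_mu;   // k+1: [0] shared, [1..k] per-group
};

// Collapsed pattern draw + conjugate block-mean draw for one gene.
static void update_gene_pattern_mean(const ModelData &d, ChainState &st,
                                     int i, double *ag, double *cg,
                                     double *wrk) {
  const int k = d.k, P = d.P;
  const double te = st.tau_eps[i];
  for (int g = 0; g < k; ++g) { ag[g] = 0.0; cg[g] = 0.0; }
  for (int j = 0; j < d.n; ++j) {
    int g = d.grp[j];
    double uij = st.u(i, j);
    double y = d.Y[i + (size_t)d.N * j];
    ag[g] += uij;
    cg[g] += uij * y;
  }
  // log weight of each pattern with block means integrated out
  double maxw = -INFINITY;
  for (int jp = 0; jp < P; ++jp) {
    double lw = std::log(st.p[jp]);
    int nb = d.nblocks[jp];
    for (int b = 0; b < nb; ++b) {
      double A = 0.0, C = 0.0;
      for (int g = 0; g < k; ++g) {
        if (d.block_of(jp, g) == b) { A += ag[g]; C += cg[g]; }
      }
      A *= te; C *= te;
      double tb = st.tau_mu[d.prec_of(jp, b)];
      double post_prec = tb + A;
      lw += 0.5 * std::log(tb) - 0.5 * std::log(post_prec) +
            0.5 * C * C / post_prec;
    }
    wrk[jp] = lw;
    if (lw > maxw) maxw = lw;
  }
  double tot = 0.0;
  for (int jp = 0; jp < P; ++jp) { wrk[jp] = std::exp(wrk[jp] - maxw); tot += wrk[jp]; }
  double r = R::unif_rand() * tot, acc = 0.0;
  int zi = P - 1;
  for (int jp = 0; jp < P; ++jp) { acc += wrk[jp]; if (r <= acc) { zi = jp; break; } }
  st.z[i] = zi;
  // conjugate draw of each block mean, copied to member groups
  int nb = d.nblocks[zi];
  for (int b = 0; b < nb; ++b) {
    double A = 0.0, C = 0.0;
    for (int g = 0; g < k; ++g)
      if (d.block_of(zi, g) == b) { A += ag[g]; C += cg[g]; }
    A *= te; C *= te;
    double tb = st.tau_mu[d.prec_of(zi, b)];
    double post_prec = tb + A;
    double m = C / post_prec;
    double draw = R::norm_rand() / std::sqrt(post_prec) + m;
    for (int g = 0; g < k; ++g)
      if (d.block_of(zi, g) == b) st.mu(i, g) = draw;
  }
}

// One full Gibbs sweep over all unknowns.
static void gibbs_sweep(const ModelData &d, ChainState &st, int family,
                        const NumericVector &dirichlet_conc,
                        const Hyper &hy) {
  const int N = d.N, n = d.n, k = d.k, P = d.P;
  std::vector<double> ag(k), cg(k), wrk(P);

  // --- pattern indicators and means (collapsed over block means) ---
  for (int i = 0; i < N; ++i)
    update_gene_pattern_mean(d, st, i, ag.data(), cg.data(), wrk.data());

  // --- latent scales, then gene precisions and family shapes ---
  for (int i = 0; i < N; ++i) {
    double te = st.tau_eps[i];
    double nuv[2] = { st.nu(i, 0), st.nu(i, 1) };
    double sum_log_u = 0.0, sum_u = 0.0, sum_inv_u = 0.0;
    int m_cont = 0;           // contaminated-normal: draws at u = gamma
    double sse_cont = 0.0;    // sum e^2 over contaminated draws
    double sse_w = 0.0;       // sum u e^2 (for tau_eps)
    if (family != FAM_NORMAL) {
      for (int j = 0; j < n; ++j) {
        double e = d.Y[i + (size_t)N * j] - st.mu(i, d.grp[j]);
        double uij = draw_scale_one(e, te, family, nuv);
        st.u(i, j) = uij;
        sse_w += uij * e * e;
        switch (family) {
        case FAM_T:
          sum_log_u += std::log(uij); sum_u += uij; break;
        case FAM_SLASH:
          sum_log_u += std::log(uij); break;
        case FAM_LAPLACE:
          sum_inv_u += 1.0 / uij; break;
        case FAM_CN:
          if (uij != 1.0) { ++m_cont; sse_cont += e * e; }
          break;
        }
      }
    } else {
      for (int j = 0; j < n; ++j) {
        double e = d.Y[i + (size_t)N * j] - st.mu(i, d.grp[j]);
        sse_w += e * e;
      }
    }
    // tau_eps_i | rest ~ Gamma(1 + n/2, 0.005 + sum u e^2 / 2)
    st.tau_eps[i] =
        R::rgamma(hy.shape + 0.5 * n, 1.0 / (hy.rate + 0.5 * sse_w));

    // family shape parameters
    switch (family) {
    case FAM_T: {
      double v = nuv[0];
      double lv_new = std::log(v) + T_MH_STEP * R::norm_rand();
      double v_new = std::exp(lv_new);
      if (v_new < hy.t_df_max) {
        double la = t_df_logcond(v_new, n, sum_log_u, sum_u) + std::log(v_new)
                  - t_df_logcond(v, n, sum_log_u, sum_u) - std::log(v);
        if (std::log(R::unif_rand()) < la) st.nu(i, 0) = v_new;
      }
      break;
    }
    case FAM_SLASH:
      st.nu(i, 0) = R::rgamma(hy.shape + n, 1.0 / (hy.rate - sum_log_u));
      break;
    case FAM_LAPLACE:
      st.nu(i, 0) = R::rgamma(hy.shape + n, 1.0 / (hy.rate + sum_inv_u));
      break;
    case FAM_CN: {
      // lambda | . ~ Beta(1 + m, 1 + n - m)
      double lam = R::rbeta(1.0 + m_cont, 1.0 + (double)(n - m_cont));
      // gamma | . ~ Gamma(m/2 + 1, tau_eps sum_cont e^2 / 2) on (0,1)
      double gam = rtrunc_gamma01(0.5 * m_cont + 1.0,
                                  0.5 * st.tau_eps[i] * sse_cont);
      // guard the open-interval support
      if (lam < 1e-12) lam = 1e-12;
      if (lam > 1.0 - 1e-12) lam = 1.0 - 1e-12;
      if (gam > 1.0 - 1e-12) gam = 1.0 - 1e-12;
      st.nu(i, 0) = lam;
      // u = gamma^b: refresh contaminated entries under the new gamma
      double gam_old = nuv[1];
      st.nu(i, 1) = gam;
      for (int j = 0; j < n; ++j)
        if (st.u(i, j) == gam_old) st.u(i, j) = gam;
        else st.u(i, j) = 1.0;
      break;
    }
    default: break;
    }
  }

  // --- prior precisions of the means, pooled over current block structure ---
  {
    std::vector<double> ssq(k + 1, 0.0);
    std::vector<int> cnt(k + 1, 0);
    for (int i = 0; i < N; ++i) {
      int jp = st.z[i];
      int nb = d.nblocks[jp];
      for (int b = 0; b < nb; ++b) {
        int pi = d.prec_of(jp, b);
        // block mean: take it from any member group
        for (int g = 0; g < k; ++g) {
          if (d.block_of(jp, g) == b) {
            ssq[pi] += st.mu(i, g) * st.mu(i, g);
            cnt[pi] += 1;
            break;
          }
        }
      }
    }
    for (int pi = 0; pi <= k; ++pi)
      st.tau_mu[pi] = R::rgamma(hy.shape + 0.5 * cnt[pi],
                                1.0 / (hy.rate + 0.5 * ssq[pi]));
  }

  // --- pattern mixing probabilities: Dirichlet(conc + counts) ---
  {
    std::vector<double> g(P);
    std::vector<int> cnt(P, 0);
    for (int i = 0; i < N; ++i) ++cnt[st.z[i]];
    double tot = 0.0;
    for (int jp = 0; jp < P; ++jp) {
      g[jp] = R::rgamma(dirichlet_conc[jp] + cnt[jp], 1.0);
      if (!(g[jp] > 0.0)) g[jp] = 1e-300;
      tot += g[jp];
    }
    for (int jp = 0; jp < P; ++jp) st.p[jp] = g[jp] / tot;
  }
}

static ModelData make_data(const NumericMatrix &Y, const IntegerVector &grp,
                           const IntegerMatrix &block_of,
                           const IntegerMatrix &prec_of,
                           const IntegerVector &nblocks);
static ChainState make_state(List state);

// Conditional pattern probabilities (block means integrated out) for every
// gene, given the current latent scales, precisions and mixing weights.
// Deterministic; exposed so the collapsed update can be checked against an
// independent quadrature oracle.
// [[Rcpp::export(name = ".cpp_pattern_probs")]]
NumericMatrix cpp_pattern_probs(NumericMatrix Y, IntegerVector grp,
                                IntegerMatrix block_of, IntegerMatrix prec_of,
                                IntegerVector nblocks, NumericMatrix u,
                                NumericVector tau_eps, NumericVector tau_mu,
                                NumericVector p) {
  const int N = Y.nrow(), n = Y.ncol(), k = block_of.ncol(),
            P = block_of.nrow();
  NumericMatrix out(N, P);
  std::vector<double> ag(k), cg(k), lw(P);
  for (int i = 0; i < N; ++i) {
    for (int g = 0; g < k; ++g) { ag[g] = 0.0; cg[g] = 0.0; }
    for (int j = 0; j < n; ++j) {
      int g = grp[j];
      ag[g] += u(i, j);
      cg[g] += u(i, j) * Y(i, j);
    }
    double maxw = -INFINITY;
    for (int jp = 0; jp < P; ++jp) {
      double w = std::log(p[jp]);
      for (int b = 0; b < nblocks[jp]; ++b) {
        double A = 0.0, C = 0.0;
        for (int g = 0; g < k; ++g)
          if (block_of(jp, g) == b) { A += ag[g]; C += cg[g]; }
        A *= tau_eps[i]; C *= tau_eps[i];
        double tb = tau_mu[prec_of(jp, b)];
        w += 0.5 * std::log(tb) - 0.5 * std::log(tb + A) +
             0.5 * C * C / (tb + A);
      }
      lw[jp] = w;
      if (w > maxw) maxw = w;
    }
    double tot = 0.0;
    for (int jp = 0; jp < P; ++jp) { lw[jp] = std::exp(lw[jp] - maxw); tot += lw[jp]; }
    for (int jp = 0; jp < P; ++jp) out(i, jp) = lw[jp] / tot;
  }
  return out;
}

// Repeated pattern/mean draws from one fixed conditioning state: the
// sampling distribution of (z, mu) given everything else.
// [[Rcpp::export(name = ".cpp_pattern_mean_draws")]]
List cpp_pattern_mean_draws(NumericMatrix Y, IntegerVector grp,
                            IntegerMatrix block_of, IntegerMatrix prec_of,
                            IntegerVector nblocks, List state, int n_draws) {
  ModelData d = make_data(Y, grp, block_of, prec_of, nblocks);
  ChainState st = make_state(state);
  const int N = d.N, k = d.k;
  NumericMatrix mu0 = clone(st.mu);
  IntegerVector z0 = clone(st.z);
  IntegerMatrix z_draws(n_draws, N);
  NumericMatrix mu_draws(n_draws, (size_t)N * k);
  std::vector<double> ag(k), cg(k), wrk(d.P);
  for (int s = 0; s < n_draws; ++s) {
    for (int i = 0; i < N; ++i) st.z[i] = z0[i];
    for (int i = 0; i < N; ++i)
      for (int g = 0; g < k; ++g) st.mu(i, g) = mu0(i, g);
    for (int i = 0; i < N; ++i)
      update_gene_pattern_mean(d, st, i, ag.data(), cg.data(), wrk.data());
    for (int i = 0; i < N; ++i) {
      z_draws(s, i) = st.z[i] + 1;
      for (int g = 0; g < k; ++g) mu_draws(s, i + (size_t)N * g) = st.mu(i, g);
    }
  }
  return List::create(_["z"] = z_draws, _["mu"] = mu_draws);
}

// Random-walk Metropolis trace of the t degrees of freedom given latent
// scale sufficient statistics.
// [[Rcpp::export(name = ".cpp_t_df_mh")]]
NumericVector cpp_t_df_mh(double v0, int n, double sum_log_u, double sum_u,
                          int n_steps, double t_df_max) {
  NumericVector out(n_steps);
  double v = v0;
  for (int s = 0; s < n_steps; ++s) {
    double lv_new = std::log(v) + T_MH_STEP * R::norm_rand();
    double v_new = std::exp(lv_new);
    if (v_new < t_df_max) {
      double la = t_df_logcond(v_new, n, sum_log_u, sum_u) + std::log(v_new)
                - t_df_logcond(v, n, sum_log_u, sum_u) - std::log(v);
      if (std::log(R::unif_rand()) < la) v = v_new;
    }
    out[s] = v;
  }
  return out;
}

static ModelData make_data(const NumericMatrix &Y, const IntegerVector &grp,
                           const IntegerMatrix &block_of,
                           const IntegerMatrix &prec_of,
                           const IntegerVector &nblocks) {
  ModelData d;
  d.N = Y.nrow(); d.n = Y.ncol();
  d.k = block_of.ncol(); d.P = block_of.nrow();
  d.Y = Y.begin();
  d.grp = grp; d.block_of = block_of; d.prec_of = prec_of;
  d.nblocks = nblocks;
  return d;
}

static ChainState make_state(List state) {
  ChainState st;
  st.mu = as<NumericMatrix>(state["mu"]);
  st.u = as<NumericMatrix>(state["u"]);
  st.tau_eps = as<NumericVector>(state["tau_eps"]);
  st.nu = as<NumericMatrix>(state["nu"]);
  st.z = as<IntegerVector>(state["z"]);
  st.p = as<NumericVector>(state["p"]);
  st.tau_mu = as<NumericVector>(state["tau_mu"]);
  return st;
}

static List state_as_list(const ChainState &st) {
  return List::create(_["mu"] = st.mu, _["u"] = st.u,
                      _["tau_eps"] = st.tau_eps, _["nu"] = st.nu,
                      _["z"] = st.z, _["p"] = st.p, _["tau_mu"] = st.tau_mu);
}

// [[Rcpp::export(name = ".cpp_gibbs_sweep")]]
List cpp_gibbs_sweep(NumericMatrix Y, IntegerVector grp,
                     IntegerMatrix block_of, IntegerMatrix prec_of,
                     IntegerVector nblocks, List state, int family,
                     NumericVector dirichlet_conc, NumericVector hyper,
                     int nsweep) {
  ModelData d = make_data(Y, grp, block_of, prec_of, nblocks);
  ChainState st = make_state(state);
  Hyper hy = { hyper[0], hyper[1], hyper[2] };
  for (int s = 0; s < nsweep; ++s)
    gibbs_sweep(d, st, family, dirichlet_conc, hy);
  return state_as_list(st);
}

// Run one chain: sweep n_iter times, retain post-burn-in draws.
// pair_sep: P x npairs 0/1, whether pattern separates each group pair.
// [[Rcpp::export(name = ".cpp_run_chain")]]
List cpp_run_chain(NumericMatrix Y, IntegerVector grp, IntegerMatrix block_of,
                   IntegerMatrix prec_of, IntegerVector nblocks, List state,
                   int family, NumericVector dirichlet_conc,
                   NumericVector hyper, int n_iter, int n_burnin, int thin,
                   IntegerMatrix pair_sep, IntegerVector tau_trace_idx,
                   bool store_z, bool verbose) {
  ModelData d = make_data(Y, grp, block_of, prec_of, nblocks);
  ChainState st = make_state(state);
  Hyper hy = { hyper[0], hyper[1], hyper[2] };
  const int N = d.N, k = d.k, P = d.P;
  const int npairs = pair_sep.ncol();
  const int n_keep = (n_iter - n_burnin) / thin;
  const int ntr = tau_trace_idx.size();

  NumericMatrix p_trace(n_keep, P);
  NumericMatrix tau_mu_trace(n_keep, k + 1);
  NumericMatrix tau_eps_trace(n_keep, ntr);
  NumericVector dev_trace(n_keep);
  IntegerMatrix z_trace(store_z ? n_keep : 0, store_z ? N : 0);
  IntegerMatrix pattern_counts(N, P);
  NumericMatrix pair_prob(N, npairs);       // counts, normalized at the end
  NumericMatrix pair_diff_sum(N, npairs);   // running sum of mu_g - mu_g'

  // enumerate group pairs once, in (g < g') column-major order
  std::vector<int> pa(npairs), pb(npairs);
  {
    int q = 0;
    for (int g1 = 0; g1 < k; ++g1)
      for (int g2 = g1 + 1; g2 < k; ++g2) { pa[q] = g1; pb[q] = g2; ++q; }
  }

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    gibbs_sweep(d, st, family, dirichlet_conc, hy);
    if (it >= n_burnin && ((it - n_burnin) % thin == 0)) {
      for (int jp = 0; jp < P; ++jp) p_trace(kept, jp) = st.p[jp];
      for (int pi = 0; pi <= k; ++pi) tau_mu_trace(kept, pi) = st.tau_mu[pi];
      for (int t = 0; t < ntr; ++t)
        tau_eps_trace(kept, t) = st.tau_eps[tau_trace_idx[t] - 1];
      // conditional-on-u deviance, a scalar convergence summary
      double dev = 0.0;
      for (int i = 0; i < N; ++i) {
        double te = st.tau_eps[i];
        for (int j = 0; j < d.n; ++j) {
          double e = d.Y[i + (size_t)N * j] - st.mu(i, d.grp[j]);
          double prec = te * st.u(i, j);
          dev += std::log(prec) - prec * e * e;
        }
      }
      dev_trace[kept] = -(dev - d.n * (double)N * std::log(2.0 * M_PI));
      for (int i = 0; i < N; ++i) {
        int zi = st.z[i];
        if (store_z) z_trace(kept, i) = zi + 1;
        ++pattern_counts(i, zi);
        for (int q = 0; q < npairs; ++q) {
          pair_prob(i, q) += pair_sep(zi, q);
          pair_diff_sum(i, q) += st.mu(i, pa[q]) - st.mu(i, pb[q]);
        }
      }
      ++kept;
    }
    if (verbose && ((it + 1) % 1000 == 0))
      Rcpp::Rcout << "  iteration " << (it + 1) << "/" << n_iter << "\n";
    if ((it & 255) == 0) Rcpp::checkUserInterrupt();
  }
  for (int i = 0; i < N; ++i) {
    for (int q = 0; q < npairs; ++q) {
      pair_prob(i, q) /= n_keep;
      pair_diff_sum(i, q) /= n_keep;
    }
  }
  // non-finite guard: a diverged chain is reported, not silently kept
  for (int i = 0; i < N; ++i)
    if (!R_finite(st.tau_eps[i]) || !R_finite(st.mu(i, 0)))
      stop("non-finite state for gene %d after %d iterations", i + 1, n_iter);

  return List::create(
      _["p_trace"] = p_trace, _["tau_mu_trace"] = tau_mu_trace,
      _["tau_eps_trace"] = tau_eps_trace, _["deviance_trace"] = dev_trace,
      _["z_trace"] = z_trace, _["pattern_counts"] = pattern_counts,
      _["pair_prob"] = pair_prob, _["pair_mean_diff"] = pair_diff_sum,
      _["final_state"] = state_as_list(st), _["n_keep"] = n_keep);
}
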