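#include <Rcpp.h>
using namespace Rcpp;

// log(1 - exp(-lam)) for lam > 0, numerically stable on both ends
static inline double ph_log1mexp(double lam) {
  if (lam <= 0.0) return R_NegInf;
  if (lam > 37.0) return 0.0; // 1 - e^-lam == 1 in double precision
  if (lam > M_LN2) return std::log1p(-std::exp(-lam));
  return std::log(-std::expm1(-lam));
}

// log(1 + exp(x)) without overflow
static inline double ph_softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// mean of the zero-truncated Poisson, A(lam) = lam / (1 - exp(-lam))
static inline double ztp_mean(double lam) {
  if (lam < 1e-8) return 1.0 + 0.5 * lam;
  return lam / (-std::expm1(-lam));
}

// d A / d lam
static inline double ztp_mean_deriv(double lam) {
  if (lam < 1e-6) return 0.5 + lam / 12.0;
  double em = std::exp(-lam);
  double d = -std::expm1(-lam); // 1 - e^-lam
  return (d - lam * em) / (d * d);
}

// sparse view of the positive cells of the count matrix; the zero cells
// only ever contribute through per-sample aggregates
struct PosCells {
  std::vector<int> g, n, cnt;
  std::vector<double> lf;            // lgamma(cnt + 1)
  std::vector<int> row_start;        // CSR offsets per feature (rows sorted)
};

static PosCells scan_cells(const IntegerMatrix &counts,
                           const NumericMatrix &lfact) {
  int G = counts.nrow(), N = counts.ncol();
  PosCells pc;
  pc.row_start.assign(G + 1, 0);
  for (int g = 0; g < G; ++g)
    for (int n = 0; n < N; ++n)
      if (counts(g, n) > 0) ++pc.row_start[g + 1];
  for (int g = 0; g < G; ++g) pc.row_start[g + 1] += pc.row_start[g];
  int m = pc.row_start[G];
  pc.g.resize(m); pc.n.resize(m); pc.cnt.resize(m); pc.lf.resize(m);
  std::vector<int> fill(pc.row_start.begin(), pc.row_start.end() - 1);
  for (int g = 0; g < G; ++g)
    for (int n = 0; n < N; ++n)
      if (counts(g, n) > 0) {
        int at = fill[g]++;
        pc.g[at] = g; pc.n[at] = n;
        pc.cnt[at] = counts(g, n); pc.lf[at] = lfact(g, n);
      }
  return pc;
}

// Per-feature hurdle log density under every cluster.
// counts: G x N, lfact: lgamma(counts + 1), treat: 0-based treatment of
// sample, alpha: G x K, mu/gamma0/gamma1: K x I.
// [[Rcpp::export]]
NumericMatrix cpp_loglik_matrix(IntegerMatrix counts, NumericMatrix lfact,
                                NumericVector s, IntegerVector treat,
                                NumericMatrix alpha, NumericMatrix mu,
                                NumericMatrix gamma0, NumericMatrix gamma1) {
  int G = counts.nrow(), N = counts.ncol(), K = alpha.ncol();
  PosCells pc = scan_cells(counts, lfact);
  NumericMatrix out(G, K);
  std::vector<double> logq(N), log1mq(N), base(N);
  for (int k = 0; k < K; ++k) {
    double all_zero = 0.0; // log-density of an all-zero feature
    for (int n = 0; n < N; ++n) {
      int i = treat[n];
      double eta = gamma0(k, i) + gamma1(k, i) * s[n];
      logq[n] = -ph_softplus(-eta);
      log1mq[n] = -ph_softplus(eta);
      base[n] = s[n] + mu(k, i);
      all_zero += log1mq[n];
    }
    for (int g = 0; g < G; ++g) out(g, k) = all_zero;
    int m = pc.g.size();
    for (int c = 0; c < m; ++c) {
      int n = pc.n[c];
      double loglam = base[n] + alpha(pc.g[c], k);
      double lam = std::exp(loglam);
      out(pc.g[c], k) += logq[n] - log1mq[n] - ph_log1mexp(lam) +
        pc.cnt[c] * loglam - lam - pc.lf[c];
    }
  }
  return out;
}

// Weighted per-cluster log-likelihood l_k for a single cluster.
// [[Rcpp::export]]
double cpp_cluster_loglik(IntegerMatrix counts, NumericMatrix lfact,
                          NumericVector w, NumericVector s, IntegerVector treat,
                          NumericVector alpha_col, NumericVector mu_k,
                          NumericVector gamma0_k, NumericVector gamma1_k) {
  int G = counts.nrow(), N = counts.ncol();
  std::vector<double> logq(N), log1mq(N), base(N);
  double all_zero = 0.0;
  for (int n = 0; n < N; ++n) {
    int i = treat[n];
    double eta = gamma0_k[i] + gamma1_k[i] * s[n];
    logq[n] = -ph_softplus(-eta);
    log1mq[n] = -ph_softplus(eta);
    base[n] = s[n] + mu_k[i];
    all_zero += log1mq[n];
  }
  double tot = 0.0;
  for (int g = 0; g < G; ++g) {
    if (w[g] == 0.0) continue;
    double acc = all_zero;
    for (int n = 0; n < N; ++n) {
      int cnt = counts(g, n);
      if (cnt > 0) {
        double loglam = base[n] + alpha_col[g];
        double lam = std::exp(loglam);
        acc += logq[n] - log1mq[n] - ph_log1mexp(lam) +
          cnt * loglam - lam - lfact(g, n);
      }
    }
    tot += w[g] * acc;
  }
  return tot;
}

// One guarded Newton pass over alpha_gk (features with >=1 positive count and
// positive weight). Step-halved so the per-feature objective never decreases.
// [[Rcpp::export]]
NumericVector cpp_update_alpha(IntegerMatrix counts, NumericVector w,
                               NumericVector s, IntegerVector treat,
                               NumericVector alpha_col, NumericVector mu_k,
                               int max_halvings) {
  int G = counts.nrow(), N = counts.ncol();
  NumericVector out = clone(alpha_col);
  std::vector<double> base(N);
  for (int n = 0; n < N; ++n) base[n] = s[n] + mu_k[treat[n]];
  std::vector<int> pos; pos.reserve(N);
  std::vector<double> lam0(N), ll0(N);
  for (int g = 0; g < G; ++g) {
    if (w[g] <= 0.0) continue;
    pos.clear();
    for (int n = 0; n < N; ++n)
      if (counts(g, n) > 0) pos.push_back(n);
    if (pos.empty()) continue;
    double a = out[g];
    double grad = 0.0, hess = 0.0, f0 = 0.0;
    for (size_t m = 0; m < pos.size(); ++m) {
      int n = pos[m];
      double loglam = base[n] + a;
      double lam = std::exp(loglam);
      lam0[m] = lam; ll0[m] = loglam;
      int cnt = counts(g, n);
      grad += cnt - ztp_mean(lam);
      hess += lam * ztp_mean_deriv(lam);
      f0 += cnt * loglam - lam - ph_log1mexp(lam);
    }
    if (hess <= 0.0) continue;
    double step = grad / hess;
    if (step > 5.0) step = 5.0;
    if (step < -5.0) step = -5.0;
    for (int h = 0; h <= max_halvings; ++h) {
      double fac = std::exp(step), f1 = 0.0;
      for (size_t m = 0; m < pos.size(); ++m) {
        double lam = lam0[m] * fac;
        f1 += counts(g, pos[m]) * (ll0[m] + step) - lam - ph_log1mexp(lam);
      }
      if (f1 >= f0 - 1e-12) {
        out[g] = a + step;
        break;
      }
      step *= 0.5;
    }
  }
  return out;
}

// One guarded Newton pass over the treatment effects mu_ki (not re-centered;
// the caller re-centers and absorbs the shift into alpha). All treatments are
// processed in two sweeps over the positive cells; a treatment whose step
// fails the ascent check is re-evaluated alone while halving.
// [[Rcpp::export]]
NumericVector cpp_update_mu(IntegerMatrix counts, NumericVector w,
                            NumericVector s, IntegerVector treat,
                            NumericVector alpha_col, NumericVector mu_k,
                            int max_halvings) {
  int G = counts.nrow(), N = counts.ncol(), I = mu_k.size();
  NumericVector out = clone(mu_k);
  std::vector<double> grad(I, 0.0), hess(I, 0.0), f0(I, 0.0), f1(I, 0.0);
  // single sweep: gradient, curvature and current objective per treatment
  for (int g = 0; g < G; ++g) {
    double wg = w[g];
    if (wg <= 0.0) continue;
    for (int n = 0; n < N; ++n) {
      int cnt = counts(g, n);
      if (cnt == 0) continue;
      int i = treat[n];
      double loglam = s[n] + alpha_col[g] + out[i];
      double lam = std::exp(loglam);
      grad[i] += wg * (cnt - ztp_mean(lam));
      hess[i] += wg * lam * ztp_mean_deriv(lam);
      f0[i] += wg * (cnt * loglam - lam - ph_log1mexp(lam));
    }
  }
  std::vector<double> step(I);
  for (int i = 0; i < I; ++i) {
    step[i] = hess[i] > 0.0 ? grad[i] / hess[i] : 0.0;
    if (step[i] > 5.0) step[i] = 5.0;
    if (step[i] < -5.0) step[i] = -5.0;
  }
  // candidate objectives for all treatments in one sweep
  for (int g = 0; g < G; ++g) {
    double wg = w[g];
    if (wg <= 0.0) continue;
    for (int n = 0; n < N; ++n) {
      int cnt = counts(g, n);
      if (cnt == 0) continue;
      int i = treat[n];
      double loglam = s[n] + alpha_col[g] + out[i] + step[i];
      double lam = std::exp(loglam);
      f1[i] += wg * (cnt * loglam - lam - ph_log1mexp(lam));
    }
  }
  for (int i = 0; i < I; ++i) {
    if (hess[i] <= 0.0) continue; // no positive weighted counts here
    double st = step[i];
    if (f1[i] >= f0[i] - 1e-12) {
      out[i] += st;
      continue;
    }
    for (int h = 1; h <= max_halvings; ++h) {
      st *= 0.5;
      double fc = 0.0;
      for (int g = 0; g < G; ++g) {
        double wg = w[g];
        if (wg <= 0.0) continue;
        for (int n = 0; n < N; ++n) {
          if (treat[n] != i || counts(g, n) == 0) continue;
          double loglam = s[n] + alpha_col[g] + out[i] + st;
          double lam = std::exp(loglam);
          fc += wg * (counts(g, n) * loglam - lam - ph_log1mexp(lam));
        }
      }
      if (fc >= f0[i] - 1e-12) {
        out[i] += st;
        break;
      }
    }
  }
  return out;
}

// one guarded Newton step for (gamma0_i, gamma1_i) given per-sample
// aggregates; updates g0i/g1i in place. When the step would drive gamma1
// through its non-negativity bound, the problem is reduced to a 1-D Newton
// step in gamma0 with gamma1 pinned at 0 (active-set projection), so the
// iteration is stationary exactly at the constrained optimum.
static void gamma_newton(int N, const NumericVector &s,
                         const IntegerVector &treat,
                         const std::vector<double> &W1, double Wt, int i,
                         double &g0i, double &g1i, int max_halvings) {
  double f0 = 0.0, gr0 = 0.0, gr1 = 0.0, h00 = 0.0, h01 = 0.0, h11 = 0.0;
  bool has = false;
  for (int n = 0; n < N; ++n) {
    if (treat[n] != i) continue;
    has = true;
    double eta = g0i + g1i * s[n];
    double pr = 1.0 / (1.0 + std::exp(-eta));
    double r = W1[n] - Wt * pr;
    f0 += W1[n] * eta - Wt * ph_softplus(eta);
    gr0 += r;
    gr1 += s[n] * r;
    double v = Wt * pr * (1.0 - pr);
    h00 += v; h01 += v * s[n]; h11 += v * s[n] * s[n];
  }
  if (!has || Wt <= 0.0) return;
  double det = h00 * h11 - h01 * h01;
  double st0, st1;
  if (det > 1e-12) {
    st0 = (h11 * gr0 - h01 * gr1) / det;
    st1 = (h00 * gr1 - h01 * gr0) / det;
  } else { // degenerate curvature (e.g. single s value): gradient step
    double sc = h00 > 1e-12 ? 1.0 / h00 : 1.0;
    st0 = sc * gr0; st1 = sc * gr1;
  }
  if (g1i + st1 < 0.0) { // constraint binds: 1-D step in gamma0 alone
    st1 = -g1i;
    st0 = h00 > 1e-12 ? gr0 / h00 : gr0;
  }
  for (int h = 0; h <= max_halvings; ++h) {
    double c0 = g0i + st0, c1 = g1i + st1;
    if (c0 > 12.0) c0 = 12.0;
    if (c0 < -12.0) c0 = -12.0;
    if (c1 < 0.0) c1 = 0.0;
    double f1 = 0.0;
    for (int n = 0; n < N; ++n) {
      if (treat[n] != i) continue;
      double eta = c0 + c1 * s[n];
      f1 += W1[n] * eta - Wt * ph_softplus(eta);
    }
    if (f1 >= f0 - 1e-12) {
      g0i = c0; g1i = c1;
      return;
    }
    st0 *= 0.5; st1 *= 0.5;
  }
}

// One guarded Newton pass over (gamma0_i, gamma1_i) for every treatment:
// weighted Bernoulli likelihood of the zero pattern on covariate s,
// aggregated per sample. gamma1 projected to >= 0, gamma0 clamped to
// [-12, 12], step halved until the objective does not decrease.
// [[Rcpp::export]]
List cpp_update_gamma(IntegerMatrix counts, NumericVector w, NumericVector s,
                      IntegerVector treat, NumericVector gamma0_k,
                      NumericVector gamma1_k, int max_halvings) {
  int G = counts.nrow(), N = counts.ncol();
  int I = gamma0_k.size();
  NumericVector g0 = clone(gamma0_k), g1 = clone(gamma1_k);
  // weighted positive / total mass per sample
  std::vector<double> W1(N, 0.0);
  double Wt = 0.0;
  for (int g = 0; g < G; ++g) {
    double wg = w[g];
    if (wg == 0.0) continue;
    Wt += wg;
    for (int n = 0; n < N; ++n)
      if (counts(g, n) > 0) W1[n] += wg;
  }
  for (int i = 0; i < I; ++i)
    gamma_newton(N, s, treat, W1, Wt, i, g0[i], g1[i], max_halvings);
  return List::create(_["gamma0"] = g0, _["gamma1"] = g1);
}

// truncated-Poisson building blocks from lam and dd = 1 - exp(-lam)
static inline double tp_logdd(double lg, double L, double dd) {
  return (L < 1e-10) ? lg : std::log(dd);
}
static inline double tp_mean(double L, double dd) {
  return (L < 1e-12) ? 1.0 : L / dd;
}
static inline double tp_mean_d(double L, double dd) {
  if (L < 1e-6) return 0.5 + L / 12.0;
  double em = 1.0 - dd;
  return (dd - L * em) / (dd * dd);
}
static inline double one_minus_exp_neg(double L) {
  return (L > 37.0) ? 1.0 : -std::expm1(-L);
}

// Whole M step (full variant) in one pass: for every cluster, the closed-form
// mixing proportion, then the guarded one-step updates of gamma, alpha and mu
// with the sum-to-zero re-centering of mu absorbed into alpha. Identical in
// exact arithmetic to chaining the single-cluster updates; posterior weights
// below wtol are dropped, which perturbs each cluster objective by far less
// than the EM monotonicity slack and lets the sweeps skip unrelated features.
// [[Rcpp::export]]
List cpp_m_step(IntegerMatrix counts, NumericMatrix lfact, NumericVector s,
                IntegerVector treat, NumericMatrix Z, NumericMatrix alpha,
                NumericMatrix mu, NumericMatrix gamma0, NumericMatrix gamma1,
                int max_halvings, double wtol) {
  int G = counts.nrow(), N = counts.ncol(), K = Z.ncol(), I = gamma0.ncol();
  PosCells pc = scan_cells(counts, lfact);
  int M = pc.row_start[G];
  NumericMatrix alpha_out = clone(alpha), mu_out = clone(mu);
  NumericMatrix g0_out = clone(gamma0), g1_out = clone(gamma1);
  NumericVector p(K);
  std::vector<double> wk(G), lam(M), dd(M), llm(M);
  std::vector<double> W1(N), base(N);
  std::vector<double> grI(I), heI(I), f0I(I), f1I(I), stI(I), facI(I);
  for (int k = 0; k < K; ++k) {
    double tot = 0.0, Wt = 0.0;
    for (int g = 0; g < G; ++g) {
      double z = Z(g, k);
      tot += z;
      wk[g] = (z < wtol) ? 0.0 : z;
      Wt += wk[g];
    }
    p[k] = tot / G;
    // gamma: per-sample weighted positive mass, then one Newton per treatment
    std::fill(W1.begin(), W1.end(), 0.0);
    for (int g = 0; g < G; ++g) {
      if (wk[g] <= 0.0) continue;
      for (int c = pc.row_start[g]; c < pc.row_start[g + 1]; ++c)
        W1[pc.n[c]] += wk[g];
    }
    for (int i = 0; i < I; ++i)
      gamma_newton(N, s, treat, W1, Wt, i, g0_out(k, i), g1_out(k, i),
                   max_halvings);
    // alpha: guarded Newton per active feature, cell state kept for mu
    for (int n = 0; n < N; ++n) base[n] = s[n] + mu_out(k, treat[n]);
    for (int g = 0; g < G; ++g) {
      if (wk[g] <= 0.0) continue;
      int c0 = pc.row_start[g], c1 = pc.row_start[g + 1];
      if (c0 == c1) continue;
      double a = alpha_out(g, k);
      double grad = 0.0, hess = 0.0, f0 = 0.0;
      for (int c = c0; c < c1; ++c) {
        double lg = base[pc.n[c]] + a;
        double L = std::exp(lg);
        double D = one_minus_exp_neg(L);
        llm[c] = lg; lam[c] = L; dd[c] = D;
        grad += pc.cnt[c] - tp_mean(L, D);
        hess += L * tp_mean_d(L, D);
        f0 += pc.cnt[c] * lg - L - tp_logdd(lg, L, D);
      }
      if (hess <= 0.0) continue;
      double step = grad / hess;
      if (step > 5.0) step = 5.0;
      if (step < -5.0) step = -5.0;
      for (int h = 0; h <= max_halvings; ++h) {
        double fac = std::exp(step), f1 = 0.0;
        for (int c = c0; c < c1; ++c) {
          double L1 = lam[c] * fac, lg1 = llm[c] + step;
          double D1 = one_minus_exp_neg(L1);
          f1 += pc.cnt[c] * lg1 - L1 - tp_logdd(lg1, L1, D1);
        }
        if (f1 >= f0 - 1e-12) {
          alpha_out(g, k) = a + step;
          for (int c = c0; c < c1; ++c) {
            lam[c] *= fac; llm[c] += step;
            dd[c] = one_minus_exp_neg(lam[c]);
          }
          break;
        }
        step *= 0.5;
      }
    }
    // mu: all treatments in two sweeps over the stored cell state
    std::fill(grI.begin(), grI.end(), 0.0);
    std::fill(heI.begin(), heI.end(), 0.0);
    std::fill(f0I.begin(), f0I.end(), 0.0);
    std::fill(f1I.begin(), f1I.end(), 0.0);
    for (int g = 0; g < G; ++g) {
      if (wk[g] <= 0.0) continue;
      double wg = wk[g];
      for (int c = pc.row_start[g]; c < pc.row_start[g + 1]; ++c) {
        int i = treat[pc.n[c]];
        double L = lam[c], D = dd[c];
        grI[i] += wg * (pc.cnt[c] - tp_mean(L, D));
        heI[i] += wg * L * tp_mean_d(L, D);
        f0I[i] += wg * (pc.cnt[c] * llm[c] - L - tp_logdd(llm[c], L, D));
      }
    }
    for (int i = 0; i < I; ++i) {
      stI[i] = heI[i] > 0.0 ? grI[i] / heI[i] : 0.0;
      if (stI[i] > 5.0) stI[i] = 5.0;
      if (stI[i] < -5.0) stI[i] = -5.0;
      facI[i] = std::exp(stI[i]);
    }
    for (int g = 0; g < G; ++g) {
      if (wk[g] <= 0.0) continue;
      double wg = wk[g];
      for (int c = pc.row_start[g]; c < pc.row_start[g + 1]; ++c) {
        int i = treat[pc.n[c]];
        double L1 = lam[c] * facI[i], lg1 = llm[c] + stI[i];
        double D1 = one_minus_exp_neg(L1);
        f1I[i] += wg * (pc.cnt[c] * lg1 - L1 - tp_logdd(lg1, L1, D1));
      }
    }
    for (int i = 0; i < I; ++i) {
      if (heI[i] <= 0.0) continue;
      double st = stI[i];
      if (f1I[i] >= f0I[i] - 1e-12) {
        mu_out(k, i) += st;
        continue;
      }
      for (int h = 1; h <= max_halvings; ++h) {
        st *= 0.5;
        double fac = std::exp(st), fc = 0.0;
        for (int g = 0; g < G; ++g) {
          if (wk[g] <= 0.0) continue;
          for (int c = pc.row_start[g]; c < pc.row_start[g + 1]; ++c) {
            if (treat[pc.n[c]] != i) continue;
            double L1 = lam[c] * fac, lg1 = llm[c] + st;
            double D1 = one_minus_exp_neg(L1);
            fc += wk[g] * (pc.cnt[c] * lg1 - L1 - tp_logdd(lg1, L1, D1));
          }
        }
        if (fc >= f0I[i] - 1e-12) {
          mu_out(k, i) += st;
          break;
        }
      }
    }
    // re-center mu, absorbing the shift into this cluster's alpha column
    double shift = 0.0;
    for (int i = 0; i < I; ++i) shift += mu_out(k, i);
    shift /= I;
    for (int i = 0; i < I; ++i) mu_out(k, i) -= shift;
    for (int g = 0; g < G; ++g) alpha_out(g, k) += shift;
  }
  return List::create(_["p"] = p, _["mu"] = mu_out, _["gamma0"] = g0_out,
                      _["gamma1"] = g1_out, _["alpha"] = alpha_out);
}

// Row-wise softmax of L + log(p) (log-sum-exp stabilized) plus the total
// mixture log-likelihood; the E step given the per-cluster density matrix.
// [[Rcpp::export]]
List cpp_posterior(NumericMatrix L, NumericVector logp, double temp) {
  int G = L.nrow(), K = L.ncol();
  NumericMatrix Z(G, K);
  double tot = 0.0;
  bool bad = false;
  for (int g = 0; g < G; ++g) {
    double m = R_NegInf;
    for (int k = 0; k < K; ++k) {
      double v = (L(g, k) + logp[k]) / temp;
      Z(g, k) = v;
      if (v > m) m = v;
    }
    if (!R_FINITE(m)) { bad = true; break; }
    double rs = 0.0;
    for (int k = 0; k < K; ++k) {
      double e = std::exp(Z(g, k) - m);
      Z(g, k) = e;
      rs += e;
    }
    for (int k = 0; k < K; ++k) Z(g, k) /= rs;
    tot += m + std::log(rs);
  }
  return List::create(_["Z"] = Z, _["loglik"] = tot, _["degenerate"] = bad);
}

// Pairwise (1 - tau_b) over the rows of a count matrix. Tie-corrected;
// a zero tau_b denominator (constant row) yields the uninformative distance 1.
// [[Rcpp::export]]
NumericMatrix cpp_tau_distance(IntegerMatrix x) {
  int G = x.nrow(), N = x.ncol();
  double n0 = N * (N - 1) / 2.0;
  // pairs tied within each row
  std::vector<double> nt(G, 0.0);
  for (int g = 0; g < G; ++g) {
    double t = 0.0;
    for (int u = 0; u < N; ++u)
      for (int v = u + 1; v < N; ++v)
        if (x(g, u) == x(g, v)) t += 1.0;
    nt[g] = t;
  }
  NumericMatrix D(G, G);
  for (int g = 0; g < G; ++g) {
    D(g, g) = 0.0;
    for (int h = g + 1; h < G; ++h) {
      double cd = 0.0;
      for (int u = 0; u < N; ++u) {
        for (int v = u + 1; v < N; ++v) {
          int dx = x(g, u) - x(g, v);
          int dy = x(h, u) - x(h, v);
          if (dx > 0) {
            if (dy > 0) cd += 1.0; else if (dy < 0) cd -= 1.0;
          } else if (dx < 0) {
            if (dy > 0) cd -= 1.0; else if (dy < 0) cd += 1.0;
          }
        }
      }
      double den = std::sqrt((n0 - nt[g]) * (n0 - nt[h]));
      double d = (den > 0.0) ? 1.0 - cd / den : 1.0;
      D(g, h) = d;
      D(h, g) = d;
    }
  }
  return D;
}
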