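// Adaptive Metropolis-within-Gibbs samplers for the C/IER latent response
// mixture models (item-level and screen-level response-time variants).
// The discrete attentiveness indicators are marginalized analytically;
// posterior membership probabilities are accumulated per retained draw.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const double L2PI = 1.8378770664093454836; // log(2*pi)

static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double lse2(double a, double b) {
  double m = a > b ? a : b;
  if (!std::isfinite(m)) return m;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// lognormal log density given lt = log(t)
static inline double lnorm_logdens(double lt, double mu, double sigma) {
  double z = (lt - mu) / sigma;
  return -lt - std::log(sigma) - 0.5 * L2PI - 0.5 * z * z;
}

// half-Cauchy(0, scale) log density for s > 0 (normalized on s > 0)
static inline double half_cauchy_log(double s, double scale) {
  return std::log(2.0 / (M_PI * scale)) - std::log1p((s / scale) * (s / scale));
}

// GPCM log probability of category k (0..K)
static inline double gpcm_logp(double eta, double v, const double* b, int K,
                               int k) {
  double cum = 0.0, mx = 0.0;
  std::vector<double> c(K + 1);
  c[0] = 0.0;
  for (int l = 1; l <= K; ++l) {
    cum += v * eta - b[l - 1];
    c[l] = cum;
    if (cum > mx) mx = cum;
  }
  double s = 0.0;
  for (int r = 0; r <= K; ++r) s += std::exp(c[r] - mx);
  return c[k] - mx - std::log(s);
}

static inline double middle_step(const double* b, int K) {
  if (K % 2 == 1) return b[(K - 1) / 2];
  return 0.5 * (b[K / 2 - 1] + b[K / 2]);
}

// Cholesky of a small dense matrix (row-major); returns false if not PD
static bool chol_small(const std::vector<double>& A, int d,
                       std::vector<double>& L) {
  L.assign(d * d, 0.0);
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * d + j];
      for (int k = 0; k < j; ++k) s -= L[i * d + k] * L[j * d + k];
      if (i == j) {
        if (s <= 1e-12) return false;
        L[i * d + i] = std::sqrt(s);
      } else {
        L[i * d + j] = s / L[j * d + j];
      }
    }
  }
  return true;
}

// MVN(0, Sigma) log density with Sigma = L L'
static double mvn_logdens(const double* x, const std::vector<double>& L,
                          int d) {
  std::vector<double> y(d);
  double q = 0.0, ldet = 0.0;
  for (int i = 0; i < d; ++i) {
    double s = x[i];
    for (int k = 0; k < i; ++k) s -= L[i * d + k] * y[k];
    y[i] = s / L[i * d + i];
    q += y[i] * y[i];
    ldet += std::log(L[i * d + i]);
  }
  return -0.5 * d * L2PI - ldet - 0.5 * q;
}

// Conditional distribution of the first coordinate of a zero-mean MVN
// given the rest: x1 | rest ~ N(w' rest, cvar). Returns false when the
// trailing block is not positive-definite.
static bool cond_first(const std::vector<double>& Sg, int d,
                       std::vector<double>& w, double& cvar) {
  int m = d - 1;
  std::vector<double> S22(m * m), s12(m), L22, y(m);
  for (int p = 0; p < m; ++p) {
    s12[p] = Sg[0 * d + (p + 1)];
    for (int q = 0; q < m; ++q) S22[p * m + q] = Sg[(p + 1) * d + (q + 1)];
  }
  if (!chol_small(S22, m, L22)) return false;
  for (int p = 0; p < m; ++p) {
    double s = s12[p];
    for (int k = 0; k < p; ++k) s -= L22[p * m + k] * y[k];
    y[p] = s / L22[p * m + p];
  }
  w.assign(m, 0.0);
  for (int p = m - 1; p >= 0; --p) {
    double s = y[p];
    for (int k = p + 1; k < m; ++k) s -= L22[k * m + p] * w[k];
    w[p] = s / L22[p * m + p];
  }
  cvar = Sg[0];
  for (int p = 0; p < m; ++p) cvar -= w[p] * s12[p];
  return cvar > 1e-12;
}

// Robbins-Monro proposal scale adaptation
struct Adapt {
  double ls;
  int n;
  Adapt() : ls(std::log(0.2)), n(0) {}
  double scale() const { return std::exp(ls); }
  void tune(bool acc, double target) {
    ++n;
    double step = std::min(0.25, 5.0 / std::sqrt((double)n));
    ls += step * ((acc ? 1.0 : 0.0) - target);
    if (ls < -12.0) ls = -12.0;
    if (ls > 4.0) ls = 4.0;
  }
};


// symmetric heavy-tailed proposal increment: occasional large jumps help
// traverse weakly identified ridges
static inline double rw_step(double scale) {
  double s = unif_rand() < 0.3 ? 4.0 * scale : scale;
  return s * norm_rand();
}

static inline bool mh_accept(double logratio) {
  if (logratio >= 0.0) return true;
  if (!std::isfinite(logratio)) return false;
  return std::log(unif_rand()) < logratio;
}

// ---------------------------------------------------------------------------
// Item-level model
// ---------------------------------------------------------------------------

struct ItemModel {
  int N, S, J, K, d;                 // d = 2 + S person dimensions
  std::vector<int> x;                // N*J, -1 missing
  std::vector<double> lt;            // N*J log RT
  std::vector<char> obs_t;           // N*J
  std::vector<int> scr;              // item -> screen
  std::vector<std::vector<int> > items_of;   // screen -> items
  // C/IER sufficient statistics per (i,s)
  std::vector<double> cnt;           // N*S*(K+1) response counts
  std::vector<double> ntC, slt, slt2;

  // parameters
  double sigma_psi, sigma_tau, sigma_A, sigma_C, gamma, beta_C;
  std::vector<double> iota, kappa, v, bstar, b;   // b: J*K
  std::vector<double> P;             // N*d person params (psi,tau,eta_1..S)
  std::vector<double> R;             // d*d correlation matrix
  double nsd, hc, lkj;               // prior settings
  std::vector<double> kalpha;        // Dirichlet concentrations for kappa

  // caches
  std::vector<double> a;             // N*J attentive per-item contribution
  std::vector<double> A, C, M;       // N*S
  std::vector<double> mvn_i;         // N
  std::vector<double> L;             // chol of Sigma
  double logdetR;

  void init_data(const IntegerMatrix& xm, const NumericMatrix& tm,
                 const IntegerVector& item_screen, int K_) {
    N = xm.nrow(); J = xm.ncol(); K = K_;
    S = 0;
    scr.assign(J, 0);
    for (int j = 0; j < J; ++j) {
      scr[j] = item_screen[j];
      if (scr[j] + 1 > S) S = scr[j] + 1;
    }
    d = 2 + S;
    items_of.assign(S, std::vector<int>());
    for (int j = 0; j < J; ++j) items_of[scr[j]].push_back(j);
    x.assign(N * J, -1);
    lt.assign(N * J, 0.0);
    obs_t.assign(N * J, 0);
    cnt.assign(N * S * (K + 1), 0.0);
    ntC.assign(N * S, 0.0);
    slt.assign(N * S, 0.0);
    slt2.assign(N * S, 0.0);
    for (int i = 0; i < N; ++i) {
      for (int j = 0; j < J; ++j) {
        int s = scr[j];
        if (xm(i, j) != NA_INTEGER) {
          x[i * J + j] = xm(i, j);
          cnt[(i * S + s) * (K + 1) + xm(i, j)] += 1.0;
        }
        if (!NumericMatrix::is_na(tm(i, j))) {
          double l = std::log(tm(i, j));
          lt[i * J + j] = l;
          obs_t[i * J + j] = 1;
          ntC[i * S + s] += 1.0;
          slt[i * S + s] += l;
          slt2[i * S + s] += l * l;
        }
      }
    }
  }

  void set_params(const List& init, const List& prior) {
    sigma_psi = as<double>(init["sigma_psi"]);
    sigma_tau = as<double>(init["sigma_tau"]);
    sigma_A = as<double>(init["sigma_A"]);
    sigma_C = as<double>(init["sigma_C"]);
    gamma = as<double>(init["gamma"]);
    beta_C = as<double>(init["beta_C"]);
    iota = as<std::vector<double> >(init["iota"]);
    kappa = as<std::vector<double> >(init["kappa"]);
    v = as<std::vector<double> >(init["v"]);
    bstar = as<std::vector<double> >(init["beta_star"]);
    NumericMatrix bm = init["b"];
    b.assign(J * K, 0.0);
    for (int j = 0; j < J; ++j)
      for (int k = 0; k < K; ++k) b[j * K + k] = bm(j, k);
    NumericMatrix pm = init["persons"];
    P.assign(N * d, 0.0);
    for (int i = 0; i < N; ++i)
      for (int c = 0; c < d; ++c) P[i * d + c] = pm(i, c);
    NumericMatrix rm = init["R"];
    R.assign(d * d, 0.0);
    for (int i = 0; i < d; ++i)
      for (int j2 = 0; j2 < d; ++j2) R[i * d + j2] = rm(i, j2);
    nsd = as<double>(prior["normal_sd"]);
    hc = as<double>(prior["half_cauchy_scale"]);
    lkj = as<double>(prior["lkj_shape"]);
    kalpha = as<std::vector<double> >(prior["kappa_alpha"]);
  }

  bool refresh_chol(double spsi, double stau, const std::vector<double>& Rm,
                    std::vector<double>& Lout, double& ldetR) {
    std::vector<double> Sg(d * d);
    std::vector<double> sd(d, 1.0);
    sd[0] = spsi; sd[1] = stau;
    for (int i = 0; i < d; ++i)
      for (int j = 0; j < d; ++j) Sg[i * d + j] = sd[i] * sd[j] * Rm[i * d + j];
    if (!chol_small(Sg, d, Lout)) return false;
    // log det(R) = log det(Sigma) - 2 sum log sd
    double ld = 0.0;
    for (int i = 0; i < d; ++i) ld += 2.0 * std::log(Lout[i * d + i]);
    for (int i = 0; i < d; ++i) ld -= 2.0 * std::log(sd[i]);
    ldetR = ld;
    return true;
  }

  double a_of(int i, int j, double tau, double eta) const {
    double out = 0.0;
    const double* bj = &b[j * K];
    int xi = x[i * J + j];
    if (xi >= 0) out += gpcm_logp(eta, v[j], bj, K, xi);
    if (obs_t[i * J + j]) {
      double o = middle_step(bj, K);
      double mu = (beta_C + bstar[j]) - tau - gamma * std::fabs(v[j] * eta - o);
      out += lnorm_logdens(lt[i * J + j], mu, sigma_A);
    }
    return out;
  }

  double C_of(int i, int s, double bC, double sC,
              const std::vector<double>& kap) const {
    double out = 0.0;
    const double* c = &cnt[(i * S + s) * (K + 1)];
    for (int k = 0; k <= K; ++k)
      if (c[k] > 0.0) out += c[k] * std::log(kap[k]);
    double nt = ntC[i * S + s];
    if (nt > 0.0) {
      double ss = slt2[i * S + s] - 2.0 * bC * slt[i * S + s] + nt * bC * bC;
      out += -nt * (0.5 * L2PI + std::log(sC)) - 0.5 * ss / (sC * sC)
             - slt[i * S + s];
    }
    return out;
  }

  double mix_of(int i, int s, double psi, double Ais, double Cis) const {
    double z = psi - iota[s];
    double lp1 = -log1pexp_(-z), lp0 = -log1pexp_(z);
    return lse2(lp1 + Ais, lp0 + Cis);
  }

  void recompute_all() {
    a.assign(N * J, 0.0);
    A.assign(N * S, 0.0);
    C.assign(N * S, 0.0);
    M.assign(N * S, 0.0);
    mvn_i.assign(N, 0.0);
    refresh_chol(sigma_psi, sigma_tau, R, L, logdetR);
    for (int i = 0; i < N; ++i) {
      double tau = P[i * d + 1];
      for (int j = 0; j < J; ++j) {
        double eta = P[i * d + 2 + scr[j]];
        a[i * J + j] = a_of(i, j, tau, eta);
        A[i * S + scr[j]] += a[i * J + j];
      }
      for (int s = 0; s < S; ++s) {
        C[i * S + s] = C_of(i, s, beta_C, sigma_C, kappa);
        M[i * S + s] = mix_of(i, s, P[i * d], A[i * S + s], C[i * S + s]);
      }
      mvn_i[i] = mvn_logdens(&P[i * d], L, d);
    }
  }

  double total_M() const {
    double s = 0.0;
    for (size_t k = 0; k < M.size(); ++k) s += M[k];
    return s;
  }
  double total_mvn() const {
    double s = 0.0;
    for (int i = 0; i < N; ++i) s += mvn_i[i];
    return s;
  }
};

// Full MCMC for the item-level model. One "iteration" = `thin` sweeps over
// all parameter blocks; the first `n_warmup` iterations adapt and are
// discarded.
// [[Rcpp::export]]
List mcmc_item_cpp(IntegerMatrix x, NumericMatrix t, IntegerVector item_screen,
                   int K, List init, List prior,
                   int n_iter, int n_warmup, int thin) {
  ItemModel md;
  md.init_data(x, t, item_screen, K);
  md.set_params(init, prior);
  md.recompute_all();
  const int N = md.N, S = md.S, J = md.J, d = md.d;
  const int npair = d * (d - 1) / 2;
  std::vector<std::pair<int, int> > pairs;
  for (int p = 0; p < d; ++p)
    for (int q = p + 1; q < d; ++q) pairs.push_back(std::make_pair(p, q));

  std::vector<Adapt> ad_person(N), ad_item(J), ad_iota(S), ad_rho(npair);
  std::vector<Adapt> ad_item_c(J * (K + 2));  // per-coordinate refinements
  std::vector<Adapt> ad_person_c(N * (size_t)S);  // per-trait refinements
  Adapt ad_gamma, ad_betaC, ad_sigA, ad_sigC, ad_sigpsi, ad_sigtau, ad_kap;
  // reparameterization moves along weakly identified directions
  Adapt ad_shift_pi, ad_scale_psi, ad_shift_bC_bs, ad_shift_tau_bC;
  std::vector<Adapt> ad_rho_nc(d - 1);   // interweaved psi-correlation moves

  int n_keep = n_iter - n_warmup;
  int P_npar = 6 + S + (K + 1) + npair + J + J + J * K + N * 2 + N * S;
  NumericMatrix draws(n_keep, P_npar);
  NumericMatrix pdelta0(N, S);
  std::fill(pdelta0.begin(), pdelta0.end(), 0.0);

  std::vector<double> a2(J), A2(S), M2(S);       // person scratch
  std::vector<double> ai2(N), Mi2(N);            // item scratch
  std::vector<double> ga2(N * (size_t)J), gA2(N * S), gC2(N * S), gM2(N * S);
  std::vector<double> L2(d * d);

  for (int iter = 0; iter < n_iter; ++iter) {
    bool warm = iter < n_warmup;
    for (int sub = 0; sub < thin; ++sub) {
      // --- person parameters ---------------------------------------------
      std::vector<double> csd(d, 1.0);
      csd[0] = md.sigma_psi; csd[1] = md.sigma_tau;
      for (int i = 0; i < N; ++i) {
        double sc = ad_person[i].scale();
        std::vector<double> pn(d);
        for (int c = 0; c < d; ++c)
          pn[c] = md.P[i * d + c] + sc * csd[c] * norm_rand();
        double cur = md.mvn_i[i], nw = mvn_logdens(&pn[0], md.L, d);
        for (int s = 0; s < S; ++s) { A2[s] = 0.0; cur += md.M[i * S + s]; }
        for (int j = 0; j < J; ++j) {
          double aa;
          {
            // evaluate with proposed person parameters
            double tau = pn[1], eta = pn[2 + md.scr[j]];
            aa = md.a_of(i, j, tau, eta);
          }
          a2[j] = aa;
          A2[md.scr[j]] += aa;
        }
        for (int s = 0; s < S; ++s) {
          M2[s] = md.mix_of(i, s, pn[0], A2[s], md.C[i * S + s]);
          nw += M2[s];
        }
        bool acc = mh_accept(nw - cur);
        if (acc) {
          for (int c = 0; c < d; ++c) md.P[i * d + c] = pn[c];
          for (int j = 0; j < J; ++j) md.a[i * J + j] = a2[j];
          for (int s = 0; s < S; ++s) {
            md.A[i * S + s] = A2[s];
            md.M[i * S + s] = M2[s];
          }
          md.mvn_i[i] = mvn_logdens(&md.P[i * d], md.L, d);
        }
        if (warm) ad_person[i].tune(acc, 0.25);
      }

      // --- per-trait person refinements -----------------------------------
      // scalar updates of eta_is: only the items of screen s enter
      for (int i = 0; i < N; ++i) {
        for (int s = 0; s < S; ++s) {
          Adapt& ad = ad_person_c[i * (size_t)S + s];
          double old = md.P[i * d + 2 + s];
          double nw = old + ad.scale() * norm_rand();
          double tau = md.P[i * d + 1];
          double Anew = md.A[i * S + s];
          int nj = md.items_of[s].size();
          for (int m2 = 0; m2 < nj; ++m2) {
            int j = md.items_of[s][m2];
            double anew = 0.0;
            {
              const double* bj = &md.b[j * K];
              int xi = md.x[i * J + j];
              if (xi >= 0) anew += gpcm_logp(nw, md.v[j], bj, K, xi);
              if (md.obs_t[i * J + j]) {
                double o = middle_step(bj, K);
                double mu = (md.beta_C + md.bstar[j]) - tau
                          - md.gamma * std::fabs(md.v[j] * nw - o);
                anew += lnorm_logdens(md.lt[i * J + j], mu, md.sigma_A);
              }
            }
            a2[j] = anew;
            Anew += anew - md.a[i * J + j];
          }
          double Mnew = md.mix_of(i, s, md.P[i * d], Anew, md.C[i * S + s]);
          std::vector<double> pn(&md.P[i * d], &md.P[i * d] + d);
          pn[2 + s] = nw;
          double lr = Mnew - md.M[i * S + s]
                    + mvn_logdens(&pn[0], md.L, d) - md.mvn_i[i];
          bool acc = mh_accept(lr);
          if (acc) {
            md.P[i * d + 2 + s] = nw;
            for (int m2 = 0; m2 < nj; ++m2) {
              int j = md.items_of[s][m2];
              md.a[i * J + j] = a2[j];
            }
            md.A[i * S + s] = Anew;
            md.M[i * S + s] = Mnew;
            md.mvn_i[i] = mvn_logdens(&md.P[i * d], md.L, d);
          }
          if (warm) ad.tune(acc, 0.44);
        }
      }

      // --- psi refresh from its conditional prior -------------------------
      // independence proposal q(psi | tau, eta) = the MVN conditional, so
      // the acceptance ratio reduces to the data likelihood ratio; for the
      // many respondents whose screens carry little attentiveness
      // information this yields near-global moves
      {
        // Sigma = D R D with D = diag(sigma_psi, sigma_tau, 1, ...)
        std::vector<double> Sg(d * d), sdv(d, 1.0);
        sdv[0] = md.sigma_psi; sdv[1] = md.sigma_tau;
        for (int p = 0; p < d; ++p)
          for (int q = 0; q < d; ++q)
            Sg[p * d + q] = sdv[p] * sdv[q] * md.R[p * d + q];
        int m = d - 1;
        std::vector<double> w;
        double cvar;
        if (cond_first(Sg, d, w, cvar)) {
          {
            double csd = std::sqrt(cvar);
            for (int i = 0; i < N; ++i) {
              double cmean = 0.0;
              for (int p = 0; p < m; ++p) cmean += w[p] * md.P[i * d + 1 + p];
              double psi_new = cmean + csd * norm_rand();
              double dl = 0.0;
              for (int s = 0; s < S; ++s) {
                M2[s] = md.mix_of(i, s, psi_new, md.A[i * S + s],
                                  md.C[i * S + s]);
                dl += M2[s] - md.M[i * S + s];
              }
              if (mh_accept(dl)) {
                md.P[i * d] = psi_new;
                for (int s = 0; s < S; ++s) md.M[i * S + s] = M2[s];
                md.mvn_i[i] = mvn_logdens(&md.P[i * d], md.L, d);
              }
            }
          }
        }
      }

      // --- item parameters (block per item) ------------------------------
      for (int j = 0; j < J; ++j) {
        double sc = ad_item[j].scale();
        double v_old = md.v[j], bs_old = md.bstar[j];
        std::vector<double> b_old(md.b.begin() + j * K,
                                  md.b.begin() + (j + 1) * K);
        double lv_new = std::log(v_old) + sc * norm_rand();
        double v_new = std::exp(lv_new);
        std::vector<double> b_new(K);
        for (int k = 0; k < K; ++k) b_new[k] = b_old[k] + sc * norm_rand();
        double bs_new = std::fabs(bs_old + sc * norm_rand());
        int s = md.scr[j];
        double lr = half_cauchy_log(v_new, md.hc) - half_cauchy_log(v_old, md.hc)
                  + std::log(v_new) - std::log(v_old);   // log-scale Jacobian
        for (int k = 0; k < K; ++k)
          lr += -0.5 * (b_new[k] * b_new[k] - b_old[k] * b_old[k]) /
                (md.nsd * md.nsd);
        lr += -0.5 * (bs_new * bs_new - bs_old * bs_old) / (md.nsd * md.nsd);
        // swap in, evaluate, swap back if rejected
        md.v[j] = v_new; md.bstar[j] = bs_new;
        for (int k = 0; k < K; ++k) md.b[j * K + k] = b_new[k];
        double dl = 0.0;
        for (int i = 0; i < N; ++i) {
          double tau = md.P[i * d + 1], eta = md.P[i * d + 2 + s];
          ai2[i] = md.a_of(i, j, tau, eta);
          double Anew = md.A[i * S + s] - md.a[i * J + j] + ai2[i];
          Mi2[i] = md.mix_of(i, s, md.P[i * d], Anew, md.C[i * S + s]);
          dl += Mi2[i] - md.M[i * S + s];
        }
        bool acc = mh_accept(lr + dl);
        if (acc) {
          for (int i = 0; i < N; ++i) {
            md.A[i * S + s] += ai2[i] - md.a[i * J + j];
            md.a[i * J + j] = ai2[i];
            md.M[i * S + s] = Mi2[i];
          }
        } else {
          md.v[j] = v_old; md.bstar[j] = bs_old;
          for (int k = 0; k < K; ++k) md.b[j * K + k] = b_old[k];
        }
        if (warm) ad_item[j].tune(acc, 0.25);
      }

      // --- per-coordinate item refinements --------------------------------
      // scalar follow-up moves with individually adapted scales; the joint
      // block above handles correlated moves, these pick up coordinates
      // with very different posterior scales
      for (int j = 0; j < J; ++j) {
        int s = md.scr[j];
        for (int cc = 0; cc < K + 2; ++cc) {
          Adapt& ad = ad_item_c[j * (K + 2) + cc];
          double sc = ad.scale();
          double v_old = md.v[j], bs_old = md.bstar[j];
          double b_old = 0.0;
          double lr = 0.0;
          if (cc == 0) {
            double nw = std::exp(std::log(v_old) + sc * norm_rand());
            lr = half_cauchy_log(nw, md.hc) - half_cauchy_log(v_old, md.hc)
               + std::log(nw) - std::log(v_old);
            md.v[j] = nw;
          } else if (cc <= K) {
            b_old = md.b[j * K + (cc - 1)];
            double nw = b_old + sc * norm_rand();
            lr = -0.5 * (nw * nw - b_old * b_old) / (md.nsd * md.nsd);
            md.b[j * K + (cc - 1)] = nw;
          } else {
            double nw = std::fabs(bs_old + sc * norm_rand());
            lr = -0.5 * (nw * nw - bs_old * bs_old) / (md.nsd * md.nsd);
            md.bstar[j] = nw;
          }
          double dl = 0.0;
          for (int i = 0; i < N; ++i) {
            double tau = md.P[i * d + 1], eta = md.P[i * d + 2 + s];
            ai2[i] = md.a_of(i, j, tau, eta);
            double Anew = md.A[i * S + s] - md.a[i * J + j] + ai2[i];
            Mi2[i] = md.mix_of(i, s, md.P[i * d], Anew, md.C[i * S + s]);
            dl += Mi2[i] - md.M[i * S + s];
          }
          bool acc = mh_accept(lr + dl);
          if (acc) {
            for (int i = 0; i < N; ++i) {
              md.A[i * S + s] += ai2[i] - md.a[i * J + j];
              md.a[i * J + j] = ai2[i];
              md.M[i * S + s] = Mi2[i];
            }
          } else {
            md.v[j] = v_old; md.bstar[j] = bs_old;
            if (cc >= 1 && cc <= K) md.b[j * K + (cc - 1)] = b_old;
          }
          if (warm) ad.tune(acc, 0.44);
        }
      }

      // --- screen attentiveness difficulties -----------------------------
      for (int s = 0; s < S; ++s) {
        double sc = ad_iota[s].scale();
        double old = md.iota[s], nw = old + sc * norm_rand();
        double lr = -0.5 * (nw * nw - old * old) / (md.nsd * md.nsd);
        md.iota[s] = nw;
        double dl = 0.0;
        for (int i = 0; i < N; ++i) {
          Mi2[i] = md.mix_of(i, s, md.P[i * d], md.A[i * S + s],
                             md.C[i * S + s]);
          dl += Mi2[i] - md.M[i * S + s];
        }
        bool acc = mh_accept(lr + dl);
        if (acc) {
          for (int i = 0; i < N; ++i) md.M[i * S + s] = Mi2[i];
        } else md.iota[s] = old;
        if (warm) ad_iota[s].tune(acc, 0.44);
      }

      // --- globals affecting the attentive RT component -------------------
      // lambda-style generic update: propose, full recompute of a/A (and C
      // when beta_C moves), compare total mixture log-likelihood
      for (int which = 0; which < 3; ++which) {
        Adapt& ad = which == 0 ? ad_gamma : (which == 1 ? ad_betaC : ad_sigA);
        double sc = ad.scale();
        double g_old = md.gamma, bC_old = md.beta_C, sA_old = md.sigma_A;
        double lr = 0.0;
        if (which == 0) {
          double nw = g_old + sc * norm_rand();
          lr += -0.5 * (nw * nw - g_old * g_old) / (md.nsd * md.nsd);
          md.gamma = nw;
        } else if (which == 1) {
          double nw = bC_old + sc * norm_rand();
          lr += -0.5 * (nw * nw - bC_old * bC_old) / (md.nsd * md.nsd);
          md.beta_C = nw;
        } else {
          double nw = std::exp(std::log(sA_old) + sc * norm_rand());
          lr += half_cauchy_log(nw, md.hc) - half_cauchy_log(sA_old, md.hc)
              + std::log(nw) - std::log(sA_old);
          md.sigma_A = nw;
        }
        double dl = 0.0;
        for (int i = 0; i < N; ++i) {
          double tau = md.P[i * d + 1];
          for (int s = 0; s < S; ++s) gA2[i * S + s] = 0.0;
          for (int j = 0; j < J; ++j) {
            double eta = md.P[i * d + 2 + md.scr[j]];
            ga2[i * (size_t)J + j] = md.a_of(i, j, tau, eta);
            gA2[i * S + md.scr[j]] += ga2[i * (size_t)J + j];
          }
          for (int s = 0; s < S; ++s) {
            gC2[i * S + s] = which == 1
              ? md.C_of(i, s, md.beta_C, md.sigma_C, md.kappa)
              : md.C[i * S + s];
            gM2[i * S + s] = md.mix_of(i, s, md.P[i * d], gA2[i * S + s],
                                       gC2[i * S + s]);
            dl += gM2[i * S + s] - md.M[i * S + s];
          }
        }
        bool acc = mh_accept(lr + dl);
        if (acc) {
          std::copy(ga2.begin(), ga2.end(), md.a.begin());
          std::copy(gA2.begin(), gA2.end(), md.A.begin());
          std::copy(gC2.begin(), gC2.end(), md.C.begin());
          std::copy(gM2.begin(), gM2.end(), md.M.begin());
        } else {
          md.gamma = g_old; md.beta_C = bC_old; md.sigma_A = sA_old;
        }
        if (warm) ad.tune(acc, 0.44);
      }

      // --- sigma_C --------------------------------------------------------
      {
        double sc = ad_sigC.scale();
        double old = md.sigma_C;
        double nw = std::exp(std::log(old) + sc * norm_rand());
        double lr = half_cauchy_log(nw, md.hc) - half_cauchy_log(old, md.hc)
                  + std::log(nw) - std::log(old);
        double dl = 0.0;
        for (int i = 0; i < N; ++i)
          for (int s = 0; s < S; ++s) {
            gC2[i * S + s] = md.C_of(i, s, md.beta_C, nw, md.kappa);
            gM2[i * S + s] = md.mix_of(i, s, md.P[i * d], md.A[i * S + s],
                                       gC2[i * S + s]);
            dl += gM2[i * S + s] - md.M[i * S + s];
          }
        bool acc = mh_accept(lr + dl);
        if (acc) {
          md.sigma_C = nw;
          std::copy(gC2.begin(), gC2.end(), md.C.begin());
          std::copy(gM2.begin(), gM2.end(), md.M.begin());
        }
        if (warm) ad_sigC.tune(acc, 0.44);
      }

      // --- kappa (softmax-parameterized block) ----------------------------
      {
        double sc = ad_kap.scale();
        std::vector<double> kn(K + 1);
        double mx = 0.0;
        std::vector<double> y(K + 1, 0.0);
        for (int k = 1; k <= K; ++k) {
          y[k] = std::log(md.kappa[k] / md.kappa[0]) + sc * norm_rand();
          if (y[k] > mx) mx = y[k];
        }
        double sum = 0.0;
        for (int k = 0; k <= K; ++k) sum += std::exp(y[k] - mx);
        for (int k = 0; k <= K; ++k) kn[k] = std::exp(y[k] - mx) / sum;
        double lr = 0.0;  // Dirichlet prior + softmax Jacobian
        for (int k = 0; k <= K; ++k)
          lr += md.kalpha[k] * (std::log(kn[k]) - std::log(md.kappa[k]));
        double dl = 0.0;
        for (int i = 0; i < N; ++i)
          for (int s = 0; s < S; ++s) {
            gC2[i * S + s] = md.C_of(i, s, md.beta_C, md.sigma_C, kn);
            gM2[i * S + s] = md.mix_of(i, s, md.P[i * d], md.A[i * S + s],
                                       gC2[i * S + s]);
            dl += gM2[i * S + s] - md.M[i * S + s];
          }
        bool acc = mh_accept(lr + dl);
        if (acc) {
          md.kappa = kn;
          std::copy(gC2.begin(), gC2.end(), md.C.begin());
          std::copy(gM2.begin(), gM2.end(), md.M.begin());
        }
        if (warm) ad_kap.tune(acc, 0.25);
      }

      // --- population SDs of attentiveness and speed ----------------------
      for (int which = 0; which < 2; ++which) {
        Adapt& ad = which == 0 ? ad_sigpsi : ad_sigtau;
        double sc = ad.scale();
        double old = which == 0 ? md.sigma_psi : md.sigma_tau;
        double nw = std::exp(std::log(old) + sc * norm_rand());
        double lr = half_cauchy_log(nw, md.hc) - half_cauchy_log(old, md.hc)
                  + std::log(nw) - std::log(old);
        double spsi = which == 0 ? nw : md.sigma_psi;
        double stau = which == 1 ? nw : md.sigma_tau;
        double ld2;
        if (!md.refresh_chol(spsi, stau, md.R, L2, ld2)) continue;
        double dl = 0.0;
        for (int i = 0; i < N; ++i)
          dl += mvn_logdens(&md.P[i * d], L2, d) - md.mvn_i[i];
        bool acc = mh_accept(lr + dl);
        if (acc) {
          if (which == 0) md.sigma_psi = nw; else md.sigma_tau = nw;
          md.L = L2; md.logdetR = ld2;
          for (int i = 0; i < N; ++i)
            md.mvn_i[i] = mvn_logdens(&md.P[i * d], md.L, d);
        }
        if (warm) ad.tune(acc, 0.44);
      }

      // --- correlation matrix (pairwise, LKJ prior) -----------------------
      for (int pq = 0; pq < npair; ++pq) {
        int p = pairs[pq].first, q = pairs[pq].second;
        double sc = ad_rho[pq].scale();
        double old = md.R[p * d + q];
        double nw = old + sc * norm_rand();
        bool acc = false;
        if (std::fabs(nw) < 1.0) {
          std::vector<double> Rn(md.R);
          Rn[p * d + q] = Rn[q * d + p] = nw;
          double ld2;
          if (md.refresh_chol(md.sigma_psi, md.sigma_tau, Rn, L2, ld2)) {
            double lr = (md.lkj - 1.0) * (ld2 - md.logdetR);
            double dl = 0.0;
            for (int i = 0; i < N; ++i)
              dl += mvn_logdens(&md.P[i * d], L2, d) - md.mvn_i[i];
            acc = mh_accept(lr + dl);
            if (acc) {
              md.R = Rn; md.L = L2; md.logdetR = ld2;
              for (int i = 0; i < N; ++i)
                md.mvn_i[i] = mvn_logdens(&md.P[i * d], md.L, d);
            }
          }
        }
        if (warm) ad_rho[pq].tune(acc, 0.44);
      }

      // --- interweaved psi-correlation updates ----------------------------
      // non-centered move: hold the standardized psi residuals fixed and
      // move one psi-involving correlation; psi travels with the
      // conditional distribution, so weakly informed correlations are not
      // pinned down by the currently imputed psi values
      for (int q = 1; q < d; ++q) {
        double sc = ad_rho_nc[q - 1].scale();
        double old = md.R[0 * d + q];
        double nw = old + sc * norm_rand();
        bool acc = false;
        if (std::fabs(nw) < 1.0) {
          std::vector<double> Rn(md.R);
          Rn[0 * d + q] = Rn[q * d + 0] = nw;
          double ld2;
          if (md.refresh_chol(md.sigma_psi, md.sigma_tau, Rn, L2, ld2)) {
            // conditional coefficients under current and proposed Sigma
            std::vector<double> Sg(d * d), Sgn(d * d), sdv(d, 1.0);
            sdv[0] = md.sigma_psi; sdv[1] = md.sigma_tau;
            for (int p = 0; p < d; ++p)
              for (int r2 = 0; r2 < d; ++r2) {
                Sg[p * d + r2] = sdv[p] * sdv[r2] * md.R[p * d + r2];
                Sgn[p * d + r2] = sdv[p] * sdv[r2] * Rn[p * d + r2];
              }
            std::vector<double> w0, w1;
            double cv0, cv1;
            if (cond_first(Sg, d, w0, cv0) && cond_first(Sgn, d, w1, cv1)) {
              double csd0 = std::sqrt(cv0), csd1 = std::sqrt(cv1);
              std::vector<double> psi_new(N);
              double dl = (md.lkj - 1.0) * (ld2 - md.logdetR);
              std::vector<double> Mn(N * (size_t)S);
              for (int i = 0; i < N; ++i) {
                double cm0 = 0.0, cm1 = 0.0;
                for (int p = 0; p < d - 1; ++p) {
                  cm0 += w0[p] * md.P[i * d + 1 + p];
                  cm1 += w1[p] * md.P[i * d + 1 + p];
                }
                double z = (md.P[i * d] - cm0) / csd0;
                psi_new[i] = cm1 + csd1 * z;
                for (int s = 0; s < S; ++s) {
                  Mn[i * S + s] = md.mix_of(i, s, psi_new[i],
                                            md.A[i * S + s],
                                            md.C[i * S + s]);
                  dl += Mn[i * S + s] - md.M[i * S + s];
                }
              }
              // in (z, R) coordinates the person prior reduces to N(z; 0, 1)
              // times the prior of the remaining coordinates, both
              // invariant here; only the likelihood and the LKJ factor move
              acc = mh_accept(dl);
              if (acc) {
                md.R = Rn; md.L = L2; md.logdetR = ld2;
                for (int i = 0; i < N; ++i) {
                  md.P[i * d] = psi_new[i];
                  md.mvn_i[i] = mvn_logdens(&md.P[i * d], md.L, d);
                  for (int s = 0; s < S; ++s)
                    md.M[i * S + s] = Mn[i * S + s];
                }
              }
            }
          }
        }
        if (warm) ad_rho_nc[q - 1].tune(acc, 0.44);
      }

      // --- ridge move: shift psi and iota jointly -------------------------
      // the likelihood depends on psi - iota only, so the data term is
      // invariant; only the person prior and the iota priors move
      {
        double del = rw_step(ad_shift_pi.scale());
        double lr = 0.0;
        for (int s = 0; s < S; ++s) {
          double nw = md.iota[s] + del;
          lr += -0.5 * (nw * nw - md.iota[s] * md.iota[s]) /
                (md.nsd * md.nsd);
        }
        std::vector<double> pn(d);
        double dmvn = 0.0;
        for (int i = 0; i < N; ++i) {
          for (int c = 0; c < d; ++c) pn[c] = md.P[i * d + c];
          pn[0] += del;
          dmvn += mvn_logdens(&pn[0], md.L, d) - md.mvn_i[i];
        }
        bool acc = mh_accept(lr + dmvn);
        if (acc) {
          for (int s = 0; s < S; ++s) md.iota[s] += del;
          for (int i = 0; i < N; ++i) {
            md.P[i * d] += del;
            md.mvn_i[i] = mvn_logdens(&md.P[i * d], md.L, d);
          }
          // M depends on psi - iota only: unchanged
        }
        if (warm) ad_shift_pi.tune(acc, 0.44);
      }

      // --- funnel move: rescale psi together with sigma_psi ---------------
      // iota travels along the ridge too: for screens deep in the
      // attentive regime the marginal C/IER rate behaves like
      // exp(iota + sigma_psi^2 / 2), so iota is shifted to keep it fixed
      {
        double eps = rw_step(ad_scale_psi.scale());
        double c0 = std::exp(eps);
        double spsi_new = md.sigma_psi * c0;
        double dio = -(spsi_new * spsi_new -
                       md.sigma_psi * md.sigma_psi) / 2.0;
        double lr = half_cauchy_log(spsi_new, md.hc)
                  - half_cauchy_log(md.sigma_psi, md.hc)
                  + (double)(N + 1) * eps;          // Jacobian of the scaling
        std::vector<double> iota_old(md.iota);
        for (int s = 0; s < S; ++s) {
          double nw = md.iota[s] + dio;
          lr += -0.5 * (nw * nw - md.iota[s] * md.iota[s]) /
                (md.nsd * md.nsd);
        }
        double ld2;
        if (md.refresh_chol(spsi_new, md.sigma_tau, md.R, L2, ld2)) {
          for (int s = 0; s < S; ++s) md.iota[s] += dio;
          std::vector<double> pn(d);
          double dl = 0.0;
          std::vector<double> Mn(N * (size_t)S);
          for (int i = 0; i < N; ++i) {
            for (int c = 0; c < d; ++c) pn[c] = md.P[i * d + c];
            pn[0] *= c0;
            dl += mvn_logdens(&pn[0], L2, d) - md.mvn_i[i];
            for (int s = 0; s < S; ++s) {
              Mn[i * S + s] = md.mix_of(i, s, pn[0], md.A[i * S + s],
                                        md.C[i * S + s]);
              dl += Mn[i * S + s] - md.M[i * S + s];
            }
          }
          bool acc = mh_accept(lr + dl);
          if (acc) {
            md.sigma_psi = spsi_new;
            md.L = L2; md.logdetR = ld2;
            for (int i = 0; i < N; ++i) {
              md.P[i * d] *= c0;
              md.mvn_i[i] = mvn_logdens(&md.P[i * d], md.L, d);
              for (int s = 0; s < S; ++s) md.M[i * S + s] = Mn[i * S + s];
            }
          } else {
            md.iota = iota_old;
          }
          if (warm) ad_scale_psi.tune(acc, 0.44);
        }
      }

      // --- ridge move: shift beta_C against the offsets -------------------
      // keeps every attentive time intensity beta_C + beta*_j fixed, so the
      // attentive component is invariant; the C/IER RT component moves
      {
        double del = rw_step(ad_shift_bC_bs.scale());
        bool ok = true;
        for (int j = 0; j < J; ++j)
          if (md.bstar[j] - del < 0.0) { ok = false; break; }
        if (ok) {
          double bC_new = md.beta_C + del;
          double lr = -0.5 * (bC_new * bC_new - md.beta_C * md.beta_C) /
                      (md.nsd * md.nsd);
          for (int j = 0; j < J; ++j) {
            double bs_new = md.bstar[j] - del;
            lr += -0.5 * (bs_new * bs_new - md.bstar[j] * md.bstar[j]) /
                  (md.nsd * md.nsd);
          }
          double dl = 0.0;
          for (int i = 0; i < N; ++i)
            for (int s = 0; s < S; ++s) {
              gC2[i * S + s] = md.C_of(i, s, bC_new, md.sigma_C, md.kappa);
              gM2[i * S + s] = md.mix_of(i, s, md.P[i * d], md.A[i * S + s],
                                         gC2[i * S + s]);
              dl += gM2[i * S + s] - md.M[i * S + s];
            }
          bool acc = mh_accept(lr + dl);
          if (acc) {
            md.beta_C = bC_new;
            for (int j = 0; j < J; ++j) md.bstar[j] -= del;
            std::copy(gC2.begin(), gC2.end(), md.C.begin());
            std::copy(gM2.begin(), gM2.end(), md.M.begin());
            // per-item attentive contributions unchanged (beta_C + beta*)
          }
          if (warm) ad_shift_bC_bs.tune(acc, 0.44);
        }
      }

      // --- ridge move: shift all speeds against beta_C --------------------
      // attentive log-RT means depend on beta_C + beta* - tau: invariant
      {
        double del = rw_step(ad_shift_tau_bC.scale());
        double bC_new = md.beta_C + del;
        double lr = -0.5 * (bC_new * bC_new - md.beta_C * md.beta_C) /
                    (md.nsd * md.nsd);
        std::vector<double> pn(d);
        double dl = 0.0;
        for (int i = 0; i < N; ++i) {
          for (int c = 0; c < d; ++c) pn[c] = md.P[i * d + c];
          pn[1] += del;
          dl += mvn_logdens(&pn[0], md.L, d) - md.mvn_i[i];
          for (int s = 0; s < S; ++s) {
            gC2[i * S + s] = md.C_of(i, s, bC_new, md.sigma_C, md.kappa);
            gM2[i * S + s] = md.mix_of(i, s, md.P[i * d], md.A[i * S + s],
                                       gC2[i * S + s]);
            dl += gM2[i * S + s] - md.M[i * S + s];
          }
        }
        bool acc = mh_accept(lr + dl);
        if (acc) {
          md.beta_C = bC_new;
          for (int i = 0; i < N; ++i) {
            md.P[i * d + 1] += del;
            md.mvn_i[i] = mvn_logdens(&md.P[i * d], md.L, d);
          }
          std::copy(gC2.begin(), gC2.end(), md.C.begin());
          std::copy(gM2.begin(), gM2.end(), md.M.begin());
          // attentive per-item contributions invariant; tau cancels beta_C
        }
        if (warm) ad_shift_tau_bC.tune(acc, 0.44);
      }
    } // sweeps

    if (!warm) {
      int r = iter - n_warmup;
      int c = 0;
      draws(r, c++) = md.sigma_psi;
      draws(r, c++) = md.sigma_tau;
      draws(r, c++) = md.sigma_A;
      draws(r, c++) = md.sigma_C;
      draws(r, c++) = md.gamma;
      draws(r, c++) = md.beta_C;
      for (int s = 0; s < S; ++s) draws(r, c++) = md.iota[s];
      for (int k = 0; k <= K; ++k) draws(r, c++) = md.kappa[k];
      for (int pq = 0; pq < npair; ++pq)
        draws(r, c++) = md.R[pairs[pq].first * d + pairs[pq].second];
      for (int j = 0; j < J; ++j) draws(r, c++) = md.v[j];
      for (int j = 0; j < J; ++j) draws(r, c++) = md.bstar[j];
      for (int j = 0; j < J; ++j)
        for (int k = 0; k < K; ++k) draws(r, c++) = md.b[j * K + k];
      for (int i = 0; i < N; ++i) draws(r, c++) = md.P[i * d];
      for (int i = 0; i < N; ++i) draws(r, c++) = md.P[i * d + 1];
      for (int s = 0; s < S; ++s)
        for (int i = 0; i < N; ++i) draws(r, c++) = md.P[i * d + 2 + s];
      // posterior probability of the C/IER state per person-screen
      for (int i = 0; i < N; ++i)
        for (int s = 0; s < S; ++s) {
          double z = md.P[i * d] - md.iota[s];
          double lp0 = -log1pexp_(z);
          pdelta0(i, s) += std::exp(lp0 + md.C[i * S + s] - md.M[i * S + s]);
        }
    }
    if (iter % 50 == 0) Rcpp::checkUserInterrupt();
  }
  for (int i = 0; i < N; ++i)
    for (int s = 0; s < S; ++s) pdelta0(i, s) /= (double)n_keep;
  return List::create(_["draws"] = draws, _["pdelta0"] = pdelta0,
                      _["loglik"] = md.total_M());
}

// Total data log-likelihood of the item-level model (sum over person-screen
// mixtures, conditional on the person parameters; the multivariate normal
// population density is not included).
// [[Rcpp::export]]
double item_loglik_cpp(IntegerMatrix x, NumericMatrix t,
                       IntegerVector item_screen, int K, List pars,
                       List prior) {
  ItemModel md;
  md.init_data(x, t, item_screen, K);
  md.set_params(pars, prior);
  md.recompute_all();
  return md.total_M();
}

// ---------------------------------------------------------------------------
// Screen-level model
// ---------------------------------------------------------------------------

struct ScreenModel {
  int N, S, J, K, d;                 // d = 1 + S (tau, eta_1..S)
  std::vector<int> x;
  std::vector<int> scr;
  std::vector<std::vector<int> > items_of;
  std::vector<double> ltb;           // N*S log mean screen time
  std::vector<char> obs_tb;
  std::vector<double> cnt;           // N*S*(K+1)

  double sigma_tau, sigma_A, sigma_C, gamma, beta_C, piP, lambda;
  std::vector<double> kappa, v, b, bstar_s, pi;
  std::vector<double> P;             // N*d
  std::vector<double> R;
  double nsd, hc, lkj;
  std::vector<double> kalpha;

  std::vector<double> vdot, odot;    // per screen aggregates
  std::vector<double> ax, at, C;     // N*S
  std::vector<double> SA, SC, M;     // N (sums over screens, person mixture)
  std::vector<double> mvn_i;
  std::vector<double> L;
  double logdetR;

  void init_data(const IntegerMatrix& xm, const NumericMatrix& tb,
                 const IntegerVector& item_screen, int K_) {
    N = xm.nrow(); J = xm.ncol(); K = K_;
    S = tb.ncol();
    scr.assign(J, 0);
    for (int j = 0; j < J; ++j) scr[j] = item_screen[j];
    d = 1 + S;
    items_of.assign(S, std::vector<int>());
    for (int j = 0; j < J; ++j) items_of[scr[j]].push_back(j);
    x.assign(N * J, -1);
    cnt.assign(N * S * (K + 1), 0.0);
    ltb.assign(N * S, 0.0);
    obs_tb.assign(N * S, 0);
    for (int i = 0; i < N; ++i) {
      for (int j = 0; j < J; ++j)
        if (xm(i, j) != NA_INTEGER) {
          x[i * J + j] = xm(i, j);
          cnt[(i * S + scr[j]) * (K + 1) + xm(i, j)] += 1.0;
        }
      for (int s = 0; s < S; ++s)
        if (!NumericMatrix::is_na(tb(i, s))) {
          ltb[i * S + s] = std::log(tb(i, s));
          obs_tb[i * S + s] = 1;
        }
    }
  }

  void set_params(const List& init, const List& prior) {
    sigma_tau = as<double>(init["sigma_tau"]);
    sigma_A = as<double>(init["sigma_A"]);
    sigma_C = as<double>(init["sigma_C"]);
    gamma = as<double>(init["gamma"]);
    beta_C = as<double>(init["beta_C"]);
    piP = as<double>(init["pi_pop"]);
    lambda = as<double>(init["lambda"]);
    kappa = as<std::vector<double> >(init["kappa"]);
    v = as<std::vector<double> >(init["v"]);
    bstar_s = as<std::vector<double> >(init["beta_star_s"]);
    pi = as<std::vector<double> >(init["pi"]);
    NumericMatrix bm = init["b"];
    b.assign(J * K, 0.0);
    for (int j = 0; j < J; ++j)
      for (int k = 0; k < K; ++k) b[j * K + k] = bm(j, k);
    NumericMatrix pm = init["persons"];
    P.assign(N * d, 0.0);
    for (int i = 0; i < N; ++i)
      for (int c = 0; c < d; ++c) P[i * d + c] = pm(i, c);
    NumericMatrix rm = init["R"];
    R.assign(d * d, 0.0);
    for (int i = 0; i < d; ++i)
      for (int j2 = 0; j2 < d; ++j2) R[i * d + j2] = rm(i, j2);
    nsd = as<double>(prior["normal_sd"]);
    hc = as<double>(prior["half_cauchy_scale"]);
    lkj = as<double>(prior["lkj_shape"]);
    kalpha = as<std::vector<double> >(prior["kappa_alpha"]);
  }

  bool refresh_chol(double stau, const std::vector<double>& Rm,
                    std::vector<double>& Lout, double& ldetR) {
    std::vector<double> Sg(d * d);
    std::vector<double> sd(d, 1.0);
    sd[0] = stau;
    for (int i = 0; i < d; ++i)
      for (int j = 0; j < d; ++j) Sg[i * d + j] = sd[i] * sd[j] * Rm[i * d + j];
    if (!chol_small(Sg, d, Lout)) return false;
    double ld = 0.0;
    for (int i = 0; i < d; ++i) ld += 2.0 * std::log(Lout[i * d + i]);
    for (int i = 0; i < d; ++i) ld -= 2.0 * std::log(sd[i]);
    ldetR = ld;
    return true;
  }

  void refresh_aggregates() {
    vdot.assign(S, 1.0);
    odot.assign(S, 0.0);
    for (int s = 0; s < S; ++s) {
      double slv = 0.0, so = 0.0;
      int n = items_of[s].size();
      for (int m = 0; m < n; ++m) {
        int j = items_of[s][m];
        slv += std::log(v[j]);
        so += middle_step(&b[j * K], K);
      }
      vdot[s] = std::exp(slv / n);
      odot[s] = so / n;
    }
  }

  double ax_of(int i, int s, double eta) const {
    double out = 0.0;
    for (size_t m = 0; m < items_of[s].size(); ++m) {
      int j = items_of[s][m];
      int xi = x[i * J + j];
      if (xi >= 0) out += gpcm_logp(eta, v[j], &b[j * K], K, xi);
    }
    return out;
  }

  double at_of(int i, int s, double tau, double eta) const {
    if (!obs_tb[i * S + s]) return 0.0;
    double mu = (beta_C + bstar_s[s]) - tau
              - gamma * std::fabs(vdot[s] * eta - odot[s]);
    return lnorm_logdens(ltb[i * S + s], mu, sigma_A);
  }

  double C_of(int i, int s, double bC, double sC,
              const std::vector<double>& kap) const {
    double out = 0.0;
    const double* c = &cnt[(i * S + s) * (K + 1)];
    for (int k = 0; k <= K; ++k)
      if (c[k] > 0.0) out += c[k] * std::log(kap[k]);
    if (obs_tb[i * S + s]) out += lnorm_logdens(ltb[i * S + s], bC, sC);
    return out;
  }

  double mix_of(int i, double SAi, double SCi) const {
    return lse2(std::log(pi[i]) + SAi, std::log1p(-pi[i]) + SCi);
  }

  void recompute_all() {
    refresh_aggregates();
    refresh_chol(sigma_tau, R, L, logdetR);
    ax.assign(N * S, 0.0);
    at.assign(N * S, 0.0);
    C.assign(N * S, 0.0);
    SA.assign(N, 0.0);
    SC.assign(N, 0.0);
    M.assign(N, 0.0);
    mvn_i.assign(N, 0.0);
    for (int i = 0; i < N; ++i) {
      double tau = P[i * d];
      for (int s = 0; s < S; ++s) {
        double eta = P[i * d + 1 + s];
        ax[i * S + s] = ax_of(i, s, eta);
        at[i * S + s] = at_of(i, s, tau, eta);
        C[i * S + s] = C_of(i, s, beta_C, sigma_C, kappa);
        SA[i] += ax[i * S + s] + at[i * S + s];
        SC[i] += C[i * S + s];
      }
      M[i] = mix_of(i, SA[i], SC[i]);
      mvn_i[i] = mvn_logdens(&P[i * d], L, d);
    }
  }

  double total_M() const {
    double s = 0.0;
    for (int i = 0; i < N; ++i) s += M[i];
    return s;
  }
};

// Beta log density kernel for pi under (lambda*piP, lambda*(1-piP)),
// including the normalizing constant (needed for piP and lambda updates)
static inline double beta_logdens(double p, double a, double b) {
  return (a - 1.0) * std::log(p) + (b - 1.0) * std::log1p(-p)
       - R::lbeta(a, b);
}

// Full MCMC for the screen-level (aggregated timing) model.
// [[Rcpp::export]]
List mcmc_screen_cpp(IntegerMatrix x, NumericMatrix tbar,
                     IntegerVector item_screen, int K, List init, List prior,
                     int n_iter, int n_warmup, int thin) {
  ScreenModel md;
  md.init_data(x, tbar, item_screen, K);
  md.set_params(init, prior);
  md.recompute_all();
  const int N = md.N, S = md.S, J = md.J, d = md.d;
  const int npair = d * (d - 1) / 2;
  std::vector<std::pair<int, int> > pairs;
  for (int p = 0; p < d; ++p)
    for (int q = p + 1; q < d; ++q) pairs.push_back(std::make_pair(p, q));

  std::vector<Adapt> ad_person(N), ad_pi(N), ad_item(J), ad_bss(S),
      ad_rho(npair);
  Adapt ad_gamma, ad_betaC, ad_sigA, ad_sigC, ad_sigtau, ad_kap, ad_piP,
      ad_lam, ad_shift_bC_bs, ad_shift_tau_bC;

  int n_keep = n_iter - n_warmup;
  int P_npar = 7 + (K + 1) + npair + S + J + J * K + N * (1 + S) + N;
  NumericMatrix draws(n_keep, P_npar);
  NumericVector pcier(N);
  std::fill(pcier.begin(), pcier.end(), 0.0);

  std::vector<double> sax(S), sat(S);
  std::vector<double> gax(N * S), gat(N * S), gC(N * S), gSA(N), gSC(N),
      gM(N);
  std::vector<double> L2(d * d);

  for (int iter = 0; iter < n_iter; ++iter) {
    bool warm = iter < n_warmup;
    for (int sub = 0; sub < thin; ++sub) {
      // --- person parameters (tau, eta) -----------------------------------
      std::vector<double> csd(d, 1.0);
      csd[0] = md.sigma_tau;
      for (int i = 0; i < N; ++i) {
        double sc = ad_person[i].scale();
        std::vector<double> pn(d);
        for (int c = 0; c < d; ++c)
          pn[c] = md.P[i * d + c] + sc * csd[c] * norm_rand();
        double SAn = 0.0;
        for (int s = 0; s < S; ++s) {
          sax[s] = md.ax_of(i, s, pn[1 + s]);
          sat[s] = md.at_of(i, s, pn[0], pn[1 + s]);
          SAn += sax[s] + sat[s];
        }
        double Mn = md.mix_of(i, SAn, md.SC[i]);
        double lr = Mn - md.M[i] + mvn_logdens(&pn[0], md.L, d) - md.mvn_i[i];
        bool acc = mh_accept(lr);
        if (acc) {
          for (int c = 0; c < d; ++c) md.P[i * d + c] = pn[c];
          for (int s = 0; s < S; ++s) {
            md.ax[i * S + s] = sax[s];
            md.at[i * S + s] = sat[s];
          }
          md.SA[i] = SAn;
          md.M[i] = Mn;
          md.mvn_i[i] = mvn_logdens(&md.P[i * d], md.L, d);
        }
        if (warm) ad_person[i].tune(acc, 0.25);
      }

      // --- attentiveness probabilities pi_i -------------------------------
      {
        double aP = md.lambda * md.piP, bP = md.lambda * (1.0 - md.piP);
        for (int i = 0; i < N; ++i) {
          double sc = ad_pi[i].scale();
          double lo = std::log(md.pi[i]) - std::log1p(-md.pi[i])
                    + sc * norm_rand();
          double pn = 1.0 / (1.0 + std::exp(-lo));
          if (pn <= 0.0 || pn >= 1.0) { if (warm) ad_pi[i].tune(false, 0.44); continue; }
          double old = md.pi[i];
          double lr = (aP - 1.0) * (std::log(pn) - std::log(old))
                    + (bP - 1.0) * (std::log1p(-pn) - std::log1p(-old))
                    + std::log(pn) + std::log1p(-pn)      // logit Jacobian
                    - std::log(old) - std::log1p(-old);
          md.pi[i] = pn;
          double Mn = md.mix_of(i, md.SA[i], md.SC[i]);
          lr += Mn - md.M[i];
          bool acc = mh_accept(lr);
          if (acc) md.M[i] = Mn; else md.pi[i] = old;
          if (warm) ad_pi[i].tune(acc, 0.44);
        }
      }

      // --- population attentiveness proportion and concentration ----------
      for (int which = 0; which < 2; ++which) {
        Adapt& ad = which == 0 ? ad_piP : ad_lam;
        double sc = ad.scale();
        double piP_new = md.piP, lam_new = md.lambda, lr = 0.0;
        if (which == 0) {
          double lo = std::log(md.piP) - std::log1p(-md.piP) + sc * norm_rand();
          piP_new = 1.0 / (1.0 + std::exp(-lo));
          if (piP_new <= 0.0 || piP_new >= 1.0) continue;
          lr += std::log(piP_new) + std::log1p(-piP_new)
              - std::log(md.piP) - std::log1p(-md.piP);   // uniform prior
        } else {
          lam_new = std::exp(std::log(md.lambda) + sc * norm_rand());
          lr += half_cauchy_log(lam_new, md.hc)
              - half_cauchy_log(md.lambda, md.hc)
              + std::log(lam_new) - std::log(md.lambda);
        }
        double a_new = lam_new * piP_new, b_new = lam_new * (1.0 - piP_new);
        double a_old = md.lambda * md.piP, b_old = md.lambda * (1.0 - md.piP);
        for (int i = 0; i < N; ++i)
          lr += beta_logdens(md.pi[i], a_new, b_new)
              - beta_logdens(md.pi[i], a_old, b_old);
        bool acc = mh_accept(lr);
        if (acc) { md.piP = piP_new; md.lambda = lam_new; }
        if (warm) ad.tune(acc, 0.44);
      }

      // --- item parameters (v, b) -----------------------------------------
      for (int j = 0; j < J; ++j) {
        double sc = ad_item[j].scale();
        double v_old = md.v[j];
        std::vector<double> b_old(md.b.begin() + j * K,
                                  md.b.begin() + (j + 1) * K);
        double v_new = std::exp(std::log(v_old) + sc * norm_rand());
        std::vector<double> b_new(K);
        for (int k = 0; k < K; ++k) b_new[k] = b_old[k] + sc * norm_rand();
        int s = md.scr[j];
        double lr = half_cauchy_log(v_new, md.hc) - half_cauchy_log(v_old, md.hc)
                  + std::log(v_new) - std::log(v_old);
        for (int k = 0; k < K; ++k)
          lr += -0.5 * (b_new[k] * b_new[k] - b_old[k] * b_old[k]) /
                (md.nsd * md.nsd);
        md.v[j] = v_new;
        for (int k = 0; k < K; ++k) md.b[j * K + k] = b_new[k];
        double vdot_old = md.vdot[s], odot_old = md.odot[s];
        // refresh this screen's aggregates
        {
          double slv = 0.0, so = 0.0;
          int n = md.items_of[s].size();
          for (int m = 0; m < n; ++m) {
            int jj = md.items_of[s][m];
            slv += std::log(md.v[jj]);
            so += middle_step(&md.b[jj * K], K);
          }
          md.vdot[s] = std::exp(slv / n);
          md.odot[s] = so / n;
        }
        double dl = 0.0;
        for (int i = 0; i < N; ++i) {
          gax[i * S + s] = md.ax_of(i, s, md.P[i * d + 1 + s]);
          gat[i * S + s] = md.at_of(i, s, md.P[i * d], md.P[i * d + 1 + s]);
          gSA[i] = md.SA[i] - md.ax[i * S + s] - md.at[i * S + s]
                 + gax[i * S + s] + gat[i * S + s];
          gM[i] = md.mix_of(i, gSA[i], md.SC[i]);
          dl += gM[i] - md.M[i];
        }
        bool acc = mh_accept(lr + dl);
        if (acc) {
          for (int i = 0; i < N; ++i) {
            md.ax[i * S + s] = gax[i * S + s];
            md.at[i * S + s] = gat[i * S + s];
            md.SA[i] = gSA[i];
            md.M[i] = gM[i];
          }
        } else {
          md.v[j] = v_old;
          for (int k = 0; k < K; ++k) md.b[j * K + k] = b_old[k];
          md.vdot[s] = vdot_old;
          md.odot[s] = odot_old;
        }
        if (warm) ad_item[j].tune(acc, 0.25);
      }

      // --- screen time-intensity offsets ----------------------------------
      for (int s = 0; s < S; ++s) {
        double sc = ad_bss[s].scale();
        double old = md.bstar_s[s];
        double nw = std::fabs(old + sc * norm_rand());
        double lr = -0.5 * (nw * nw - old * old) / (md.nsd * md.nsd);
        md.bstar_s[s] = nw;
        double dl = 0.0;
        for (int i = 0; i < N; ++i) {
          gat[i * S + s] = md.at_of(i, s, md.P[i * d], md.P[i * d + 1 + s]);
          gSA[i] = md.SA[i] - md.at[i * S + s] + gat[i * S + s];
          gM[i] = md.mix_of(i, gSA[i], md.SC[i]);
          dl += gM[i] - md.M[i];
        }
        bool acc = mh_accept(lr + dl);
        if (acc) {
          for (int i = 0; i < N; ++i) {
            md.at[i * S + s] = gat[i * S + s];
            md.SA[i] = gSA[i];
            md.M[i] = gM[i];
          }
        } else md.bstar_s[s] = old;
        if (warm) ad_bss[s].tune(acc, 0.44);
      }

      // --- globals for the attentive timing component ----------------------
      for (int which = 0; which < 3; ++which) {
        Adapt& ad = which == 0 ? ad_gamma : (which == 1 ? ad_betaC : ad_sigA);
        double sc = ad.scale();
        double g_old = md.gamma, bC_old = md.beta_C, sA_old = md.sigma_A;
        double lr = 0.0;
        if (which == 0) {
          double nw = g_old + sc * norm_rand();
          lr += -0.5 * (nw * nw - g_old * g_old) / (md.nsd * md.nsd);
          md.gamma = nw;
        } else if (which == 1) {
          double nw = bC_old + sc * norm_rand();
          lr += -0.5 * (nw * nw - bC_old * bC_old) / (md.nsd * md.nsd);
          md.beta_C = nw;
        } else {
          double nw = std::exp(std::log(sA_old) + sc * norm_rand());
          lr += half_cauchy_log(nw, md.hc) - half_cauchy_log(sA_old, md.hc)
              + std::log(nw) - std::log(sA_old);
          md.sigma_A = nw;
        }
        double dl = 0.0;
        for (int i = 0; i < N; ++i) {
          gSA[i] = 0.0; gSC[i] = 0.0;
          for (int s = 0; s < S; ++s) {
            gat[i * S + s] = md.at_of(i, s, md.P[i * d], md.P[i * d + 1 + s]);
            gC[i * S + s] = which == 1
              ? md.C_of(i, s, md.beta_C, md.sigma_C, md.kappa)
              : md.C[i * S + s];
            gSA[i] += md.ax[i * S + s] + gat[i * S + s];
            gSC[i] += gC[i * S + s];
          }
          gM[i] = md.mix_of(i, gSA[i], gSC[i]);
          dl += gM[i] - md.M[i];
        }
        bool acc = mh_accept(lr + dl);
        if (acc) {
          std::copy(gat.begin(), gat.end(), md.at.begin());
          std::copy(gC.begin(), gC.end(), md.C.begin());
          std::copy(gSA.begin(), gSA.end(), md.SA.begin());
          std::copy(gSC.begin(), gSC.end(), md.SC.begin());
          std::copy(gM.begin(), gM.end(), md.M.begin());
        } else {
          md.gamma = g_old; md.beta_C = bC_old; md.sigma_A = sA_old;
        }
        if (warm) ad.tune(acc, 0.44);
      }

      // --- sigma_C and kappa ----------------------------------------------
      for (int which = 0; which < 2; ++which) {
        Adapt& ad = which == 0 ? ad_sigC : ad_kap;
        double sc = ad.scale();
        double sC_new = md.sigma_C;
        std::vector<double> kn(md.kappa);
        double lr = 0.0;
        if (which == 0) {
          sC_new = std::exp(std::log(md.sigma_C) + sc * norm_rand());
          lr += half_cauchy_log(sC_new, md.hc)
              - half_cauchy_log(md.sigma_C, md.hc)
              + std::log(sC_new) - std::log(md.sigma_C);
        } else {
          std::vector<double> y(K + 1, 0.0);
          double mx = 0.0;
          for (int k = 1; k <= K; ++k) {
            y[k] = std::log(md.kappa[k] / md.kappa[0]) + sc * norm_rand();
            if (y[k] > mx) mx = y[k];
          }
          double sum = 0.0;
          for (int k = 0; k <= K; ++k) sum += std::exp(y[k] - mx);
          for (int k = 0; k <= K; ++k) kn[k] = std::exp(y[k] - mx) / sum;
          for (int k = 0; k <= K; ++k)
            lr += md.kalpha[k] * (std::log(kn[k]) - std::log(md.kappa[k]));
        }
        double dl = 0.0;
        for (int i = 0; i < N; ++i) {
          gSC[i] = 0.0;
          for (int s = 0; s < S; ++s) {
            gC[i * S + s] = md.C_of(i, s, md.beta_C, sC_new, kn);
            gSC[i] += gC[i * S + s];
          }
          gM[i] = md.mix_of(i, md.SA[i], gSC[i]);
          dl += gM[i] - md.M[i];
        }
        bool acc = mh_accept(lr + dl);
        if (acc) {
          md.sigma_C = sC_new;
          md.kappa = kn;
          std::copy(gC.begin(), gC.end(), md.C.begin());
          std::copy(gSC.begin(), gSC.end(), md.SC.begin());
          std::copy(gM.begin(), gM.end(), md.M.begin());
        }
        if (warm) ad.tune(acc, which == 0 ? 0.44 : 0.25);
      }

      // --- sigma_tau -------------------------------------------------------
      {
        double sc = ad_sigtau.scale();
        double old = md.sigma_tau;
        double nw = std::exp(std::log(old) + sc * norm_rand());
        double lr = half_cauchy_log(nw, md.hc) - half_cauchy_log(old, md.hc)
                  + std::log(nw) - std::log(old);
        double ld2;
        if (md.refresh_chol(nw, md.R, L2, ld2)) {
          double dl = 0.0;
          for (int i = 0; i < N; ++i)
            dl += mvn_logdens(&md.P[i * d], L2, d) - md.mvn_i[i];
          bool acc = mh_accept(lr + dl);
          if (acc) {
            md.sigma_tau = nw;
            md.L = L2; md.logdetR = ld2;
            for (int i = 0; i < N; ++i)
              md.mvn_i[i] = mvn_logdens(&md.P[i * d], md.L, d);
          }
          if (warm) ad_sigtau.tune(acc, 0.44);
        }
      }

      // --- correlations ----------------------------------------------------
      for (int pq = 0; pq < npair; ++pq) {
        int p = pairs[pq].first, q = pairs[pq].second;
        double sc = ad_rho[pq].scale();
        double old = md.R[p * d + q];
        double nw = old + sc * norm_rand();
        bool acc = false;
        if (std::fabs(nw) < 1.0) {
          std::vector<double> Rn(md.R);
          Rn[p * d + q] = Rn[q * d + p] = nw;
          double ld2;
          if (md.refresh_chol(md.sigma_tau, Rn, L2, ld2)) {
            double lr = (md.lkj - 1.0) * (ld2 - md.logdetR);
            double dl = 0.0;
            for (int i = 0; i < N; ++i)
              dl += mvn_logdens(&md.P[i * d], L2, d) - md.mvn_i[i];
            acc = mh_accept(lr + dl);
            if (acc) {
              md.R = Rn; md.L = L2; md.logdetR = ld2;
              for (int i = 0; i < N; ++i)
                md.mvn_i[i] = mvn_logdens(&md.P[i * d], md.L, d);
            }
          }
        }
        if (warm) ad_rho[pq].tune(acc, 0.44);
      }

      // --- ridge move: shift beta_C against the screen offsets ------------
      {
        double del = rw_step(ad_shift_bC_bs.scale());
        bool ok = true;
        for (int s = 0; s < S; ++s)
          if (md.bstar_s[s] - del < 0.0) { ok = false; break; }
        if (ok) {
          double bC_new = md.beta_C + del;
          double lr = -0.5 * (bC_new * bC_new - md.beta_C * md.beta_C) /
                      (md.nsd * md.nsd);
          for (int s = 0; s < S; ++s) {
            double bs_new = md.bstar_s[s] - del;
            lr += -0.5 * (bs_new * bs_new - md.bstar_s[s] * md.bstar_s[s]) /
                  (md.nsd * md.nsd);
          }
          double dl = 0.0;
          for (int i = 0; i < N; ++i) {
            gSC[i] = 0.0;
            for (int s = 0; s < S; ++s) {
              gC[i * S + s] = md.C_of(i, s, bC_new, md.sigma_C, md.kappa);
              gSC[i] += gC[i * S + s];
            }
            gM[i] = md.mix_of(i, md.SA[i], gSC[i]);
            dl += gM[i] - md.M[i];
          }
          bool acc = mh_accept(lr + dl);
          if (acc) {
            md.beta_C = bC_new;
            for (int s = 0; s < S; ++s) md.bstar_s[s] -= del;
            std::copy(gC.begin(), gC.end(), md.C.begin());
            std::copy(gSC.begin(), gSC.end(), md.SC.begin());
            std::copy(gM.begin(), gM.end(), md.M.begin());
          }
          if (warm) ad_shift_bC_bs.tune(acc, 0.44);
        }
      }

      // --- ridge move: shift all speeds against beta_C --------------------
      {
        double del = rw_step(ad_shift_tau_bC.scale());
        double bC_new = md.beta_C + del;
        double lr = -0.5 * (bC_new * bC_new - md.beta_C * md.beta_C) /
                    (md.nsd * md.nsd);
        std::vector<double> pn(d);
        double dl = 0.0;
        for (int i = 0; i < N; ++i) {
          for (int c = 0; c < d; ++c) pn[c] = md.P[i * d + c];
          pn[0] += del;
          dl += mvn_logdens(&pn[0], md.L, d) - md.mvn_i[i];
          gSC[i] = 0.0;
          for (int s = 0; s < S; ++s) {
            gC[i * S + s] = md.C_of(i, s, bC_new, md.sigma_C, md.kappa);
            gSC[i] += gC[i * S + s];
          }
          gM[i] = md.mix_of(i, md.SA[i], gSC[i]);
          dl += gM[i] - md.M[i];
        }
        bool acc = mh_accept(lr + dl);
        if (acc) {
          md.beta_C = bC_new;
          for (int i = 0; i < N; ++i) {
            md.P[i * d] += del;
            md.mvn_i[i] = mvn_logdens(&md.P[i * d], md.L, d);
          }
          std::copy(gC.begin(), gC.end(), md.C.begin());
          std::copy(gSC.begin(), gSC.end(), md.SC.begin());
          std::copy(gM.begin(), gM.end(), md.M.begin());
        }
        if (warm) ad_shift_tau_bC.tune(acc, 0.44);
      }
    } // sweeps

    if (!warm) {
      int r = iter - n_warmup;
      int c = 0;
      draws(r, c++) = md.sigma_tau;
      draws(r, c++) = md.sigma_A;
      draws(r, c++) = md.sigma_C;
      draws(r, c++) = md.gamma;
      draws(r, c++) = md.beta_C;
      draws(r, c++) = md.piP;
      draws(r, c++) = md.lambda;
      for (int k = 0; k <= K; ++k) draws(r, c++) = md.kappa[k];
      for (int pq = 0; pq < npair; ++pq)
        draws(r, c++) = md.R[pairs[pq].first * d + pairs[pq].second];
      for (int s = 0; s < S; ++s) draws(r, c++) = md.bstar_s[s];
      for (int j = 0; j < J; ++j) draws(r, c++) = md.v[j];
      for (int j = 0; j < J; ++j)
        for (int k = 0; k < K; ++k) draws(r, c++) = md.b[j * K + k];
      for (int i = 0; i < N; ++i) draws(r, c++) = md.P[i * d];
      for (int s = 0; s < S; ++s)
        for (int i = 0; i < N; ++i) draws(r, c++) = md.P[i * d + 1 + s];
      for (int i = 0; i < N; ++i) draws(r, c++) = md.pi[i];
      for (int i = 0; i < N; ++i)
        pcier[i] += std::exp(std::log1p(-md.pi[i]) + md.SC[i] - md.M[i]);
    }
    if (iter % 50 == 0) Rcpp::checkUserInterrupt();
  }
  for (int i = 0; i < N; ++i) pcier[i] /= (double)n_keep;
  return List::create(_["draws"] = draws, _["pcier"] = pcier,
                      _["loglik"] = md.total_M());
}

// Total data log-likelihood of the screen-level model (sum of person-level
// mixtures, conditional on person parameters and pi).
// [[Rcpp::export]]
double screen_loglik_cpp(IntegerMatrix x, NumericMatrix tbar,
                         IntegerVector item_screen, int K, List pars,
                         List prior) {
  ScreenModel md;
  md.init_data(x, tbar, item_screen, K);
  md.set_params(pars, prior);
  md.recompute_all();
  return md.total_M();
}
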