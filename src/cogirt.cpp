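// Marginal-likelihood kernels for the latent cognitive-disability models.
//
// Observation-level log-likelihoods with analytic first/second derivatives
// w.r.t. the latent disability D, per-subject Newton mode finding, and
// Laplace / adaptive Gauss-Hermite approximations to the marginal
// likelihood over the subject random effects (1-D at baseline, 2-D
// baseline+slope for the longitudinal model). A fixed-node Gauss-Hermite
// marginal (response-table form) supports joint item-parameter estimation.
//
// Family codes used here (set up on the R side):
//   1 = Bernoulli / binomial with per-trial failure probability
//       p = c + (d - c) * logistic(a (D - b)), optional truncation at m
//   2 = truncated generalized Poisson (support 0..m), mean curve
//       p = d * (1 - logistic(a (D - b))), dispersion delta
//   3 = proportional-odds ordered categorical, thresholds th[0..K-2]

#include <Rcpp.h>
using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static double lfact_tab[64];
static bool lfact_ready = false;
static void init_lfact() {
  if (lfact_ready) return;
  for (int k = 0; k < 64; ++k) lfact_tab[k] = R::lgammafn(k + 1.0);
  lfact_ready = true;
}

// ---- binomial family ------------------------------------------------------
static inline void binom_eval(int y, int n, int m, double lch,
                              double a, double b, double cc, double u,
                              double D, double &ll, double &d1, double &d2,
                              bool want) {
  double q = sigmoid(a * (D - b));
  double p = cc + (u - cc) * q;
  const double eps = 1e-12;
  if (p < eps) p = eps;
  if (p > 1 - eps) p = 1 - eps;
  double pp = (u - cc) * a * q * (1 - q);
  double ppp = (u - cc) * a * a * q * (1 - q) * (1 - 2 * q);
  double lp = lch + y * std::log(p) + (n - y) * std::log(1 - p);
  double A = y / p - (n - y) / (1 - p);
  double Ap = -y / (p * p) - (n - y) / ((1 - p) * (1 - p));
  double corr1 = 0, corr2 = 0;
  if (m > 0 && m < n) { // truncated storage: renormalize over 0..m
    double lS = R::pbinom((double)m, (double)n, p, 1, 1);
    double lB = R::dbinom((double)m, (double)(n - 1), p, 1);
    double Sp = -n * std::exp(lB - lS);                  // (log S)'
    double SppS = Sp * (m / p - (n - 1.0 - m) / (1 - p)); // S''/S
    lp -= lS;
    corr1 = -Sp;
    corr2 = -(SppS - Sp * Sp);
  }
  ll = lp;
  if (want) {
    double g = A + corr1;
    d1 = g * pp;
    d2 = g * ppp + (Ap + corr2) * pp * pp;
  }
}

// ---- generalized Poisson --------------------------------------------------
static inline void gp_eval(int y, int kmax, double a, double b, double dmax,
                           double delta, double D,
                           double &ll, double &d1, double &d2, bool want) {
  double q = sigmoid(a * (D - b));
  double p = dmax * (1 - q);
  const double peps = 1e-10;
  if (p < peps) p = peps;
  double pp = -dmax * a * q * (1 - q);
  double ppp = -dmax * a * a * q * (1 - q) * (1 - 2 * q);
  double t[64], u1[64], u2[64];
  double tmax = -1e300;
  for (int k = 0; k <= kmax; ++k) {
    double lam = p + delta * k;
    if (k > 0 && lam <= 0) { t[k] = -1e300; u1[k] = 0; u2[k] = 0; continue; }
    if (k == 0) { t[0] = -p; u1[0] = -1.0; u2[0] = 0.0; }
    else {
      t[k] = std::log(p) + (k - 1) * std::log(lam) - p - delta * k - lfact_tab[k];
      u1[k] = 1.0 / p + (k - 1) / lam - 1.0;
      u2[k] = -1.0 / (p * p) - (k - 1) / (lam * lam);
    }
    if (t[k] > tmax) tmax = t[k];
  }
  double Z = 0, S1 = 0, S2 = 0;
  for (int k = 0; k <= kmax; ++k) {
    double e = std::exp(t[k] - tmax);
    Z += e;
    if (want) { S1 += e * u1[k]; S2 += e * (u2[k] + u1[k] * u1[k]); }
  }
  double lZ = tmax + std::log(Z);
  ll = t[y] - lZ;
  if (want) {
    double m1 = S1 / Z;
    double curv = S2 / Z - m1 * m1;   // d^2 log Z / dp^2
    double g = u1[y] - m1;
    d1 = g * pp;
    d2 = g * ppp + (u2[y] - curv) * pp * pp;
  }
}

// ---- ordered categorical --------------------------------------------------
static inline void ord_eval(int y, int K, const double *th, double a,
                            double D, double &ll, double &d1, double &d2,
                            bool want) {
  double gk = (y == 0) ? 1.0 : sigmoid(a * (D - th[y - 1]));
  double gk1 = (y == K - 1) ? 0.0 : sigmoid(a * (D - th[y]));
  double P = gk - gk1;
  if (P < 1e-300) P = 1e-300;
  ll = std::log(P);
  if (want) {
    double d1k = (y == 0) ? 0 : a * gk * (1 - gk);
    double d1k1 = (y == K - 1) ? 0 : a * gk1 * (1 - gk1);
    double d2k = (y == 0) ? 0 : a * a * gk * (1 - gk) * (1 - 2 * gk);
    double d2k1 = (y == K - 1) ? 0 : a * a * gk1 * (1 - gk1) * (1 - 2 * gk1);
    double g = (d1k - d1k1) / P;
    d1 = g;
    d2 = (d2k - d2k1) / P - g * g;
  }
}

struct ObsData {
  const int *fam, *y, *n, *m, *ncat;
  const double *a, *b, *c, *d, *delta, *lch, *t;
  const double *th; // column-major n_obs x thcols
  int thcols, nobs;
  // optional tabulated item log-likelihoods (item parameters fixed):
  // per item a column-major npts x 3K matrix [ll | d1 | d2] by outcome
  bool use_tab = false;
  std::vector<const double*> tabs;
  const int *obs_item = nullptr, *supK = nullptr;
  int npts = 0;
  double lo = 0, step = 1;
};

// cubic Hermite in (ll, d1); linear interpolation of the stored d2
static inline void tab_eval(const ObsData &od, int o, double D,
                            double &ll, double &d1, double &d2, bool want) {
  int j = od.obs_item[o];
  const double *M = od.tabs[j];
  int K = od.supK[j] + 1, npts = od.npts;
  double u = (D - od.lo) / od.step;
  if (u < 0) u = 0;
  if (u > npts - 1.000001) u = npts - 1.000001;
  int i = (int)u;
  double t = u - i, h = od.step;
  int y = od.y[o];
  const double *llc = M + (size_t)y * npts;
  const double *d1c = M + (size_t)(K + y) * npts;
  double t2 = t * t, t3 = t2 * t;
  ll = (2 * t3 - 3 * t2 + 1) * llc[i] + (t3 - 2 * t2 + t) * h * d1c[i] +
       (-2 * t3 + 3 * t2) * llc[i + 1] + (t3 - t2) * h * d1c[i + 1];
  if (want) {
    const double *d2c = M + (size_t)(2 * K + y) * npts;
    d1 = (6 * t2 - 6 * t) * llc[i] / h + (3 * t2 - 4 * t + 1) * d1c[i] +
         (-6 * t2 + 6 * t) * llc[i + 1] / h + (3 * t2 - 2 * t) * d1c[i + 1];
    d2 = (1 - t) * d2c[i] + t * d2c[i + 1];
  }
}

static inline void obs_eval(const ObsData &od, int o, double D,
                            double &ll, double &d1, double &d2, bool want) {
  if (od.use_tab) { tab_eval(od, o, D, ll, d1, d2, want); return; }
  switch (od.fam[o]) {
  case 1:
    binom_eval(od.y[o], od.n[o], od.m[o], od.lch[o], od.a[o], od.b[o],
               od.c[o], od.d[o], D, ll, d1, d2, want);
    break;
  case 2:
    gp_eval(od.y[o], od.m[o], od.a[o], od.b[o], od.d[o], od.delta[o], D,
            ll, d1, d2, want);
    break;
  default: {
    double thbuf[16];
    int K = od.ncat[o];
    for (int j = 0; j < K - 1; ++j) thbuf[j] = od.th[o + j * od.nobs];
    ord_eval(od.y[o], K, thbuf, od.a[o], D, ll, d1, d2, want);
  }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_obs_loglik(NumericVector D, IntegerVector y,
                             IntegerVector fam, NumericVector a,
                             NumericVector b, NumericVector c,
                             NumericVector d, NumericVector delta,
                             IntegerVector n, IntegerVector m,
                             NumericVector lch, NumericMatrix th,
                             IntegerVector ncat) {
  init_lfact();
  int N = D.size();
  ObsData od = {fam.begin(), y.begin(), n.begin(), m.begin(), ncat.begin(),
                a.begin(), b.begin(), c.begin(), d.begin(), delta.begin(),
                lch.begin(), nullptr, th.begin(), th.ncol(), N};
  NumericMatrix out(N, 3);
  for (int o = 0; o < N; ++o) {
    double ll = 0, d1 = 0, d2 = 0;
    obs_eval(od, o, D[o], ll, d1, d2, true);
    out(o, 0) = ll; out(o, 1) = d1; out(o, 2) = d2;
  }
  colnames(out) = CharacterVector::create("loglik", "d1", "d2");
  return out;
}

// ---- dropout --------------------------------------------------------------
static inline double cumhaz(int kind, double th3, double th4, double D0,
                            double ai, double t) {
  switch (kind) {
  case 0: return std::exp(th3) * t;                       // constant
  case 1: {                                               // disability D(t)
    double cc = th4 * ai;
    double h0 = std::exp(th3 + th4 * D0);
    if (std::fabs(cc * t) < 1e-8) return h0 * t * (1 + 0.5 * cc * t);
    return h0 * std::expm1(cc * t) / cc;
  }
  case 2: return std::exp(th3 + th4 * ai) * t;            // progression rate
  case 3: return std::exp(th3 + th4 * D0) * t;            // baseline D0
  }
  return 0.0;
}

// status: 0 none, 1 interval (t1, t2], 2 censored at t1
static inline double drop_ll(int status, double t1, double t2, int kind,
                             double th3, double th4, double D0, double ai) {
  if (status == 0) return 0.0;
  double H1 = cumhaz(kind, th3, th4, D0, ai, t1);
  if (status == 2) return -H1;
  double H2 = cumhaz(kind, th3, th4, D0, ai, t2);
  double diff = std::exp(-H1) - std::exp(-H2);
  if (diff < 1e-300) diff = 1e-300;
  return std::log(diff);
}

// ---- longitudinal joint likelihood ---------------------------------------
struct SubjCtx {
  const ObsData *od;
  int o0, o1;          // obs range
  double s;            // 1 - beta * x_grp
  double th1, th2;
  double Si11, Si12, Si22, ldetS; // prior precision & log det of Sigma
  int hkind;           // -1 none
  double th3, th4;
  int dstat; double dt1, dt2;
};

static double subj_droppart(const SubjCtx &cx, double e1, double e2) {
  if (cx.hkind < 0 || cx.dstat == 0) return 0.0;
  double D0 = cx.th1 + e1;
  double ai = cx.s * (cx.th2 + e2);
  return drop_ll(cx.dstat, cx.dt1, cx.dt2, cx.hkind, cx.th3, cx.th4, D0, ai);
}

// log joint g(eta) and optionally gradient/Hessian
static double subj_g(const SubjCtx &cx, double e1, double e2,
                     double *grad, double *hess) {
  const ObsData &od = *cx.od;
  bool want = grad != nullptr;
  double g = 0, g1 = 0, g2 = 0, h11 = 0, h12 = 0, h22 = 0;
  for (int o = cx.o0; o < cx.o1; ++o) {
    double D = cx.th1 + e1 + cx.s * (cx.th2 + e2) * od.t[o];
    double ll, d1 = 0, d2 = 0;
    obs_eval(od, o, D, ll, d1, d2, want);
    g += ll;
    if (want) {
      double w = cx.s * od.t[o];
      g1 += d1; g2 += d1 * w;
      h11 += d2; h12 += d2 * w; h22 += d2 * w * w;
    }
  }
  // bivariate normal prior
  double q = cx.Si11 * e1 * e1 + 2 * cx.Si12 * e1 * e2 + cx.Si22 * e2 * e2;
  g += -0.5 * q - M_LN_SQRT_2PI * 2 - 0.5 * cx.ldetS;
  if (want) {
    g1 += -(cx.Si11 * e1 + cx.Si12 * e2);
    g2 += -(cx.Si12 * e1 + cx.Si22 * e2);
    h11 -= cx.Si11; h12 -= cx.Si12; h22 -= cx.Si22;
  }
  // dropout factor; derivatives by central differences (scalar, cheap)
  if (cx.hkind >= 0 && cx.dstat != 0) {
    double f0 = subj_droppart(cx, e1, e2);
    g += f0;
    if (want) {
      const double h = 1e-5;
      double fp1 = subj_droppart(cx, e1 + h, e2);
      double fm1 = subj_droppart(cx, e1 - h, e2);
      double fp2 = subj_droppart(cx, e1, e2 + h);
      double fm2 = subj_droppart(cx, e1, e2 - h);
      double fpp = subj_droppart(cx, e1 + h, e2 + h);
      double fpm = subj_droppart(cx, e1 + h, e2 - h);
      double fmp = subj_droppart(cx, e1 - h, e2 + h);
      double fmm = subj_droppart(cx, e1 - h, e2 - h);
      g1 += (fp1 - fm1) / (2 * h);
      g2 += (fp2 - fm2) / (2 * h);
      h11 += (fp1 - 2 * f0 + fm1) / (h * h);
      h22 += (fp2 - 2 * f0 + fm2) / (h * h);
      h12 += (fpp - fpm - fmp + fmm) / (4 * h * h);
    }
  }
  if (want) {
    grad[0] = g1; grad[1] = g2;
    hess[0] = h11; hess[1] = h12; hess[2] = h22;
  }
  return g;
}

// Newton ascent of g(eta); returns mode, fills H = -hess (PD) and g at mode
static double subj_newton(const SubjCtx &cx, double &e1, double &e2,
                          double H[3]) {
  double grad[2], hess[3];
  double g = subj_g(cx, e1, e2, grad, hess);
  for (int it = 0; it < 60; ++it) {
    // warm starts are usually already converged
    if (std::fabs(grad[0]) < 3e-8 && std::fabs(grad[1]) < 3e-8) break;
    double A = -hess[0], B = -hess[1], C = -hess[2];
    // ensure PD
    double ridge = 0;
    for (int r = 0; r < 50 && (A + ridge <= 1e-8 ||
         (A + ridge) * (C + ridge) - B * B <= 1e-12); ++r)
      ridge = (ridge == 0) ? 1e-4 : ridge * 10;
    A += ridge; C += ridge;
    double det = A * C - B * B;
    double s1 = (C * grad[0] - B * grad[1]) / det;
    double s2 = (A * grad[1] - B * grad[0]) / det;
    double step = 1.0;
    double ng = 0, ngrad[2], nhess[3], ne1 = 0, ne2 = 0;
    bool ok = false;
    for (int half = 0; half < 30; ++half) {
      ne1 = e1 + step * s1; ne2 = e2 + step * s2;
      ng = subj_g(cx, ne1, ne2, ngrad, nhess);
      if (ng >= g - 1e-12) { ok = true; break; }
      step *= 0.5;
    }
    if (!ok) break;
    e1 = ne1; e2 = ne2; g = ng;
    grad[0] = ngrad[0]; grad[1] = ngrad[1];
    hess[0] = nhess[0]; hess[1] = nhess[1]; hess[2] = nhess[2];
    if (std::fabs(grad[0]) < 1e-9 && std::fabs(grad[1]) < 1e-9) break;
  }
  H[0] = -hess[0]; H[1] = -hess[1]; H[2] = -hess[2];
  // final PD safeguard for the Laplace determinant
  if (H[0] <= 1e-8) H[0] = 1e-8;
  double det = H[0] * H[2] - H[1] * H[1];
  if (det <= 1e-10) { H[2] += (1e-10 - det) / H[0] + 1e-8; }
  return g;
}

// Tabulate every item's outcome log-likelihoods and their first two
// derivatives on a latent grid (item parameters fixed): per item a
// column-major npts x 3(sup+1) matrix [ll | d1 | d2].
// [[Rcpp::export]]
List cpp_build_item_tables(IntegerVector famI, NumericVector aI,
                           NumericVector bI, NumericVector cI,
                           NumericVector dI, NumericVector deltaI,
                           IntegerVector nI, IntegerVector mI,
                           NumericMatrix thI, IntegerVector ncatI,
                           IntegerVector supI, double lo, double hi,
                           double step) {
  init_lfact();
  int J = famI.size();
  int npts = (int)std::round((hi - lo) / step) + 1;
  List out(J);
  double thbuf[16];
  for (int j = 0; j < J; ++j) {
    int K = supI[j] + 1;
    NumericMatrix M(npts, 3 * K);
    if (famI[j] == 3) {
      int Kc = ncatI[j];
      for (int v = 0; v < Kc - 1; ++v) thbuf[v] = thI(j, v);
    }
    for (int q = 0; q < npts; ++q) {
      double D = lo + q * step;
      for (int v = 0; v < K; ++v) {
        double ll, d1 = 0, d2 = 0;
        if (famI[j] == 1) {
          double lch = R::lchoose((double)nI[j], (double)v);
          binom_eval(v, nI[j], mI[j], lch, aI[j], bI[j], cI[j], dI[j], D,
                     ll, d1, d2, true);
        } else if (famI[j] == 2) {
          gp_eval(v, mI[j], aI[j], bI[j], dI[j], deltaI[j], D,
                  ll, d1, d2, true);
        } else {
          ord_eval(v, ncatI[j], thbuf, aI[j], D, ll, d1, d2, true);
        }
        M(q, v) = ll;
        M(q, K + v) = d1;
        M(q, 2 * K + v) = d2;
      }
    }
    out[j] = M;
  }
  out.attr("lo") = lo;
  out.attr("step") = step;
  out.attr("npts") = npts;
  return out;
}

// [[Rcpp::export]]
List cpp_long_marginal(IntegerVector off, IntegerVector y, IntegerVector fam,
                       NumericVector a, NumericVector b, NumericVector c,
                       NumericVector d, NumericVector delta, IntegerVector n,
                       IntegerVector m, NumericVector lch, NumericMatrix th,
                       IntegerVector ncat, NumericVector t_years,
                       NumericVector xgrp, double theta1, double theta2,
                       double om1, double om2, double rho, double beta,
                       int hazard_kind, double th3, double th4,
                       IntegerVector dstat, NumericVector dt1,
                       NumericVector dt2, int method, NumericVector ghx,
                       NumericVector ghw, NumericMatrix eta_ws,
                       Nullable<List> tables = R_NilValue,
                       Nullable<IntegerVector> obs_item = R_NilValue,
                       Nullable<IntegerVector> supI = R_NilValue) {
  init_lfact();
  int nsub = off.size() - 1;
  ObsData od = {fam.begin(), y.begin(), n.begin(), m.begin(), ncat.begin(),
                a.begin(), b.begin(), c.begin(), d.begin(), delta.begin(),
                lch.begin(), t_years.begin(), th.begin(), th.ncol(),
                (int)y.size()};
  IntegerVector obs_item_, supI_;
  if (tables.isNotNull()) {
    List tabs(tables);
    obs_item_ = IntegerVector(obs_item);
    supI_ = IntegerVector(supI);
    od.use_tab = true;
    od.tabs.resize(tabs.size());
    for (int j = 0; j < tabs.size(); ++j)
      od.tabs[j] = NumericMatrix(tabs[j]).begin();
    od.obs_item = obs_item_.begin();
    od.supK = supI_.begin();
    od.lo = as<double>(tabs.attr("lo"));
    od.step = as<double>(tabs.attr("step"));
    od.npts = as<int>(tabs.attr("npts"));
  }
  double v1 = om1 * om1, v2 = om2 * om2, cv = rho * om1 * om2;
  double detS = v1 * v2 - cv * cv;
  if (detS < 1e-12) detS = 1e-12;
  double Si11 = v2 / detS, Si22 = v1 / detS, Si12 = -cv / detS;
  double ldetS = std::log(detS);
  NumericVector lli(nsub);
  int Q = ghx.size();
  for (int i = 0; i < nsub; ++i) {
    SubjCtx cx;
    cx.od = &od; cx.o0 = off[i]; cx.o1 = off[i + 1];
    cx.s = 1.0 - beta * xgrp[i];
    cx.th1 = theta1; cx.th2 = theta2;
    cx.Si11 = Si11; cx.Si12 = Si12; cx.Si22 = Si22; cx.ldetS = ldetS;
    cx.hkind = hazard_kind; cx.th3 = th3; cx.th4 = th4;
    cx.dstat = dstat[i]; cx.dt1 = dt1[i]; cx.dt2 = dt2[i];
    double e1 = eta_ws(i, 0), e2 = eta_ws(i, 1);
    double H[3];
    double ghat = subj_newton(cx, e1, e2, H);
    eta_ws(i, 0) = e1; eta_ws(i, 1) = e2;
    double det = H[0] * H[2] - H[1] * H[1];
    if (method == 0) { // Laplace
      lli[i] = ghat + M_LN_SQRT_2PI * 2 - 0.5 * std::log(det);
    } else {           // adaptive Gauss-Hermite, tensor product
      // lower Cholesky of H^{-1}
      double Hi11 = H[2] / det, Hi12 = -H[1] / det, Hi22 = H[0] / det;
      double l11 = std::sqrt(Hi11);
      double l21 = Hi12 / l11;
      double l22 = std::sqrt(std::max(Hi22 - l21 * l21, 1e-12));
      double s2 = std::sqrt(2.0);
      double acc = 0;
      for (int j = 0; j < Q; ++j) {
        for (int k = 0; k < Q; ++k) {
          double z1 = ghx[j], z2 = ghx[k];
          double ee1 = e1 + s2 * l11 * z1;
          double ee2 = e2 + s2 * (l21 * z1 + l22 * z2);
          double gv = subj_g(cx, ee1, ee2, nullptr, nullptr);
          acc += ghw[j] * ghw[k] * std::exp(gv - ghat + z1 * z1 + z2 * z2);
        }
      }
      lli[i] = ghat + std::log(2.0 * l11 * l22 * acc);
    }
  }
  double total = 0;
  for (int i = 0; i < nsub; ++i) total += lli[i];
  return List::create(_["loglik"] = total, _["subject"] = lli);
}

// ---- baseline (1-D latent, standard normal prior) -------------------------
static double subj_g1(const ObsData &od, int o0, int o1, double D,
                      double &d1, double &d2, bool want) {
  double g = -0.5 * D * D - M_LN_SQRT_2PI;
  double g1 = -D, g2 = -1;
  for (int o = o0; o < o1; ++o) {
    double ll, a1 = 0, a2 = 0;
    obs_eval(od, o, D, ll, a1, a2, want);
    g += ll; g1 += a1; g2 += a2;
  }
  d1 = g1; d2 = g2;
  return g;
}

static double newton1(const ObsData &od, int o0, int o1, double &D,
                      double &curv) {
  double d1, d2;
  double g = subj_g1(od, o0, o1, D, d1, d2, true);
  for (int it = 0; it < 60; ++it) {
    if (std::fabs(d1) < 3e-8) break;
    double H = -d2;
    if (H < 1e-8) H = 1e-8;
    double step = d1 / H;
    if (step > 3) step = 3;
    if (step < -3) step = -3;
    double nd1, nd2, nD = D, ng = g;
    bool ok = false;
    double sc = 1.0;
    for (int half = 0; half < 30; ++half) {
      nD = D + sc * step;
      ng = subj_g1(od, o0, o1, nD, nd1, nd2, true);
      if (ng >= g - 1e-12) { ok = true; break; }
      sc *= 0.5;
    }
    if (!ok) break;
    D = nD; g = ng; d1 = nd1; d2 = nd2;
    if (std::fabs(d1) < 1e-10) break;
  }
  curv = -d2;
  if (curv < 1e-8) curv = 1e-8;
  return g;
}

// [[Rcpp::export]]
List cpp_baseline_marginal(IntegerVector off, IntegerVector y,
                           IntegerVector fam, NumericVector a,
                           NumericVector b, NumericVector c, NumericVector d,
                           NumericVector delta, IntegerVector n,
                           IntegerVector m, NumericVector lch,
                           NumericMatrix th, IntegerVector ncat, int method,
                           NumericVector ghx, NumericVector ghw,
                           NumericVector d_ws) {
  init_lfact();
  int nsub = off.size() - 1;
  ObsData od = {fam.begin(), y.begin(), n.begin(), m.begin(), ncat.begin(),
                a.begin(), b.begin(), c.begin(), d.begin(), delta.begin(),
                lch.begin(), nullptr, th.begin(), th.ncol(), (int)y.size()};
  NumericVector lli(nsub);
  int Q = ghx.size();
  for (int i = 0; i < nsub; ++i) {
    double D = d_ws[i], curv;
    double ghat = newton1(od, off[i], off[i + 1], D, curv);
    d_ws[i] = D;
    if (method == 0) {
      lli[i] = ghat + M_LN_SQRT_2PI - 0.5 * std::log(curv);
    } else {
      double sd = 1.0 / std::sqrt(curv);
      double acc = 0, dd1, dd2;
      for (int q = 0; q < Q; ++q) {
        double Dq = D + std::sqrt(2.0) * sd * ghx[q];
        double gv = subj_g1(od, off[i], off[i + 1], Dq, dd1, dd2, false);
        acc += ghw[q] * std::exp(gv - ghat + ghx[q] * ghx[q]);
      }
      lli[i] = ghat + std::log(std::sqrt(2.0) * sd * acc);
    }
  }
  double total = 0;
  for (int i = 0; i < nsub; ++i) total += lli[i];
  return List::create(_["loglik"] = total, _["subject"] = lli);
}

// [[Rcpp::export]]
NumericMatrix cpp_ebe(IntegerVector off, IntegerVector y, IntegerVector fam,
                      NumericVector a, NumericVector b, NumericVector c,
                      NumericVector d, NumericVector delta, IntegerVector n,
                      IntegerVector m, NumericVector lch, NumericMatrix th,
                      IntegerVector ncat) {
  init_lfact();
  int nsub = off.size() - 1;
  ObsData od = {fam.begin(), y.begin(), n.begin(), m.begin(), ncat.begin(),
                a.begin(), b.begin(), c.begin(), d.begin(), delta.begin(),
                lch.begin(), nullptr, th.begin(), th.ncol(), (int)y.size()};
  NumericMatrix out(nsub, 2);
  for (int i = 0; i < nsub; ++i) {
    double D = 0, curv;
    newton1(od, off[i], off[i + 1], D, curv);
    out(i, 0) = D;
    out(i, 1) = 1.0 / std::sqrt(curv);
  }
  colnames(out) = CharacterVector::create("d_hat", "d_sd");
  return out;
}

// ---- fixed-node Gauss-Hermite marginal (joint item estimation) ------------
// Item-indexed parameter arrays; responses reference items via item_idx.
// Nodes Dq / weights wq follow the N(0,1) prior. Returns the negative
// marginal log-likelihood and its exact gradient with respect to the
// natural item parameters (posterior-weight accumulation): slot order
// per item is (a, b, c, d) for binomial, (a, b, d, delta) for the
// generalized Poisson and (a, th1..th4) for ordered items.
// [[Rcpp::export]]
List cpp_mml_nll_grad(IntegerVector off, IntegerVector item_idx,
                      IntegerVector y, IntegerVector famI, NumericVector aI,
                      NumericVector bI, NumericVector cI, NumericVector dI,
                      NumericVector deltaI, IntegerVector nI,
                      IntegerVector mI, NumericMatrix thI,
                      IntegerVector ncatI, IntegerVector supI,
                      NumericVector Dq, NumericVector wq) {
  init_lfact();
  const int NSLOT = 5;
  int J = famI.size(), Q = Dq.size(), nsub = off.size() - 1;
  // tables: T[j][v*Q+q] log pmf; G[j][((s*K)+v)*Q+q] d log pmf / d param_s
  std::vector< std::vector<double> > T(J), G(J);
  for (int j = 0; j < J; ++j) {
    int K = supI[j] + 1;
    T[j].assign((size_t)K * Q, 0.0);
    G[j].assign((size_t)NSLOT * K * Q, 0.0);
    for (int q = 0; q < Q; ++q) {
      double D = Dq[q];
      if (famI[j] == 1) {
        int n = nI[j], mm = mI[j];
        double qv = sigmoid(aI[j] * (D - bI[j]));
        double p = cI[j] + (dI[j] - cI[j]) * qv;
        const double eps = 1e-12;
        if (p < eps) p = eps;
        if (p > 1 - eps) p = 1 - eps;
        double lS = 0, Sp = 0;
        if (mm > 0 && mm < n) {
          lS = R::pbinom((double)mm, (double)n, p, 1, 1);
          Sp = -n * std::exp(R::dbinom((double)mm, (double)(n - 1), p, 1) -
                             lS);
        }
        double qd = qv * (1 - qv);
        double dp_da = (dI[j] - cI[j]) * qd * (D - bI[j]);
        double dp_db = -(dI[j] - cI[j]) * aI[j] * qd;
        double dp_dc = 1 - qv;
        double dp_dd = qv;
        for (int v = 0; v < K; ++v) {
          T[j][(size_t)v * Q + q] =
            R::lchoose((double)n, (double)v) + v * std::log(p) +
            (n - v) * std::log(1 - p) - lS;
          double dldp = v / p - (n - v) / (1 - p) - Sp;
          G[j][((size_t)0 * K + v) * Q + q] = dldp * dp_da;
          G[j][((size_t)1 * K + v) * Q + q] = dldp * dp_db;
          G[j][((size_t)2 * K + v) * Q + q] = dldp * dp_dc;
          G[j][((size_t)3 * K + v) * Q + q] = dldp * dp_dd;
        }
      } else if (famI[j] == 2) {
        int kmax = mI[j];
        double qv = sigmoid(aI[j] * (D - bI[j]));
        double p = dI[j] * (1 - qv);
        if (p < 1e-10) p = 1e-10;
        double qd = qv * (1 - qv);
        double dp_da = -dI[j] * qd * (D - bI[j]);
        double dp_db = dI[j] * aI[j] * qd;
        double dp_dd = 1 - qv;
        double t[64], u1[64], v1[64], tmax = -1e300;
        for (int k = 0; k <= kmax; ++k) {
          double lam = p + deltaI[j] * k;
          if (k > 0 && lam <= 0) { t[k] = -1e300; u1[k] = 0; v1[k] = 0; }
          else if (k == 0) { t[0] = -p; u1[0] = -1.0; v1[0] = 0.0; }
          else {
            t[k] = std::log(p) + (k - 1) * std::log(lam) - p -
              deltaI[j] * k - lfact_tab[k];
            u1[k] = 1.0 / p + (k - 1) / lam - 1.0;
            v1[k] = (double)k * (k - 1) / lam - k;
          }
          if (t[k] > tmax) tmax = t[k];
        }
        double Z = 0, Su = 0, Sv = 0;
        for (int k = 0; k <= kmax; ++k) {
          double e = std::exp(t[k] - tmax);
          Z += e; Su += e * u1[k]; Sv += e * v1[k];
        }
        double lZ = tmax + std::log(Z), mu = Su / Z, mv = Sv / Z;
        for (int v = 0; v < K; ++v) {
          T[j][(size_t)v * Q + q] = t[v] - lZ;
          double dldp = u1[v] - mu;
          G[j][((size_t)0 * K + v) * Q + q] = dldp * dp_da;
          G[j][((size_t)1 * K + v) * Q + q] = dldp * dp_db;
          G[j][((size_t)2 * K + v) * Q + q] = dldp * dp_dd;
          G[j][((size_t)3 * K + v) * Q + q] = v1[v] - mv;
        }
      } else {
        int Kc = ncatI[j];
        double gam[16], dga[16], gth[16];
        gam[0] = 1; dga[0] = 0; gth[0] = 0;
        for (int v = 1; v < Kc; ++v) {
          double g = sigmoid(aI[j] * (D - thI(j, v - 1)));
          gam[v] = g;
          dga[v] = g * (1 - g) * (D - thI(j, v - 1)); // d gamma / d a
          gth[v] = -aI[j] * g * (1 - g);              // d gamma / d th_{v-1}
        }
        gam[Kc] = 0; dga[Kc] = 0; gth[Kc] = 0;
        for (int v = 0; v < Kc; ++v) {
          double P = gam[v] - gam[v + 1];
          if (P < 1e-300) P = 1e-300;
          T[j][(size_t)v * Q + q] = std::log(P);
          G[j][((size_t)0 * K + v) * Q + q] = (dga[v] - dga[v + 1]) / P;
          if (v >= 1)
            G[j][((size_t)v * K + v) * Q + q] += gth[v] / P;
          if (v + 1 <= Kc - 1)
            G[j][((size_t)(v + 1) * K + v) * Q + q] += -gth[v + 1] / P;
        }
      }
    }
  }
  std::vector<double> acc(Q), W(Q);
  NumericMatrix grad(J, NSLOT);
  double total = 0;
  for (int i = 0; i < nsub; ++i) {
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int o = off[i]; o < off[i + 1]; ++o) {
      const double *row = &T[item_idx[o]][(size_t)y[o] * Q];
      for (int q = 0; q < Q; ++q) acc[q] += row[q];
    }
    double amax = acc[0];
    for (int q = 1; q < Q; ++q) if (acc[q] > amax) amax = acc[q];
    double s = 0;
    for (int q = 0; q < Q; ++q) {
      W[q] = wq[q] * std::exp(acc[q] - amax);
      s += W[q];
    }
    total += amax + std::log(s);
    for (int q = 0; q < Q; ++q) W[q] /= s;
    for (int o = off[i]; o < off[i + 1]; ++o) {
      int j = item_idx[o];
      int K = supI[j] + 1;
      for (int sl = 0; sl < NSLOT; ++sl) {
        const double *row = &G[j][((size_t)sl * K + y[o]) * Q];
        double gsum = 0;
        for (int q = 0; q < Q; ++q) gsum += W[q] * row[q];
        grad(j, sl) -= gsum; // negative log-likelihood
      }
    }
  }
  return List::create(_["nll"] = -total, _["grad"] = grad);
}

// [[Rcpp::export]]
double cpp_mml_nll(IntegerVector off, IntegerVector item_idx, IntegerVector y,
                   IntegerVector famI, NumericVector aI, NumericVector bI,
                   NumericVector cI, NumericVector dI, NumericVector deltaI,
                   IntegerVector nI, IntegerVector mI, NumericMatrix thI,
                   IntegerVector ncatI, IntegerVector supI,
                   NumericVector Dq, NumericVector wq) {
  init_lfact();
  int J = famI.size(), Q = Dq.size(), nsub = off.size() - 1;
  // table T[item][value][node]
  std::vector< std::vector<double> > T(J);
  for (int j = 0; j < J; ++j) {
    int K = supI[j] + 1;
    T[j].resize((size_t)K * Q);
    for (int q = 0; q < Q; ++q) {
      double D = Dq[q];
      if (famI[j] == 1) {
        int n = nI[j], mm = mI[j];
        double qv = sigmoid(aI[j] * (D - bI[j]));
        double p = cI[j] + (dI[j] - cI[j]) * qv;
        const double eps = 1e-12;
        if (p < eps) p = eps;
        if (p > 1 - eps) p = 1 - eps;
        double lS = (mm > 0 && mm < n)
          ? R::pbinom((double)mm, (double)n, p, 1, 1) : 0.0;
        for (int v = 0; v < K; ++v)
          T[j][(size_t)v * Q + q] =
            R::lchoose((double)n, (double)v) + v * std::log(p) +
            (n - v) * std::log(1 - p) - lS;
      } else if (famI[j] == 2) {
        int kmax = mI[j];
        double qv = sigmoid(aI[j] * (D - bI[j]));
        double p = dI[j] * (1 - qv);
        if (p < 1e-10) p = 1e-10;
        double t[64], tmax = -1e300;
        for (int k = 0; k <= kmax; ++k) {
          double lam = p + deltaI[j] * k;
          if (k > 0 && lam <= 0) { t[k] = -1e300; continue; }
          t[k] = (k == 0) ? -p
            : std::log(p) + (k - 1) * std::log(lam) - p - deltaI[j] * k -
              lfact_tab[k];
          if (t[k] > tmax) tmax = t[k];
        }
        double Z = 0;
        for (int k = 0; k <= kmax; ++k) Z += std::exp(t[k] - tmax);
        double lZ = tmax + std::log(Z);
        for (int v = 0; v < K; ++v) T[j][(size_t)v * Q + q] = t[v] - lZ;
      } else {
        int Kc = ncatI[j];
        double prev = 1.0;
        for (int v = 0; v < Kc; ++v) {
          double nxt = (v == Kc - 1) ? 0.0
            : sigmoid(aI[j] * (D - thI(j, v)));
          double P = prev - nxt;
          if (P < 1e-300) P = 1e-300;
          T[j][(size_t)v * Q + q] = std::log(P);
          prev = nxt;
        }
      }
    }
  }
  std::vector<double> acc(Q);
  double total = 0;
  for (int i = 0; i < nsub; ++i) {
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int o = off[i]; o < off[i + 1]; ++o) {
      const double *row = &T[item_idx[o]][(size_t)y[o] * Q];
      for (int q = 0; q < Q; ++q) acc[q] += row[q];
    }
    double amax = acc[0];
    for (int q = 1; q < Q; ++q) if (acc[q] > amax) amax = acc[q];
    double s = 0;
    for (int q = 0; q < Q; ++q) s += wq[q] * std::exp(acc[q] - amax);
    total += amax + std::log(s);
  }
  return -total;
}
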