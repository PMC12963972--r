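// Core numerics: truncated Conway-Maxwell-Poisson, joint log posterior with
// analytic gradients on the unconstrained scale, and an adaptive HMC sampler.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct ZStats {
  double logZ;  // log normalizing constant of the truncated pmf
  double Ej;    // E[j] under the truncated pmf
  double Ej2;   // E[j^2]
  double Elgf;  // E[lgamma(j+1)]
};

// Truncated COM-Poisson normalization and moments for pmf
// propto exp(j*loglam - nu*lgamma(j+1)), j = 0..upper. The summand is
// unimodal in j with continuous argmax where nu*digamma(j+1) = loglam,
// i.e. j ~ exp(loglam/nu); checking the two adjacent integers gives the
// exact max term for the log-sum-exp without a separate scan.
static ZStats cmp_zstats(double loglam, double nu, int upper,
                         const std::vector<double>& lg) {
  double jstar = std::exp(loglam / nu) - 0.5;
  int j0 = int(std::floor(jstar));
  if (j0 < 0) j0 = 0;
  if (j0 > upper) j0 = upper;
  int j1 = j0 + 1 <= upper ? j0 + 1 : upper;
  double M = std::max(j0 * loglam - nu * lg[j0], j1 * loglam - nu * lg[j1]);
  double s0 = 0.0, s1 = 0.0, s2 = 0.0, s3 = 0.0;
  for (int j = 0; j <= upper; ++j) {
    double e = std::exp(j * loglam - nu * lg[j] - M);
    s0 += e;
    s1 += j * e;
    s2 += double(j) * j * e;
    s3 += lg[j] * e;
  }
  ZStats z;
  z.logZ = M + std::log(s0);
  z.Ej = s1 / s0;
  z.Ej2 = s2 / s0;
  z.Elgf = s3 / s0;
  return z;
}

static std::vector<double> lgamma_table(int n) {
  std::vector<double> lg(n + 1);
  for (int j = 0; j <= n; ++j) lg[j] = std::lgamma(double(j) + 1.0);
  return lg;
}

// Asymptotic mean-matching rate: lambda = (mu + (nu-1)/(2 nu))^nu
static double loglam_approx(double mu, double nu) {
  double a = (nu - 1.0) / (2.0 * nu);
  return nu * std::log(mu + a);
}

// Exact mean-constrained rate: solve E_trunc[j](lambda, nu) = mu by Newton
// on log(lambda); derivative d E[j] / d loglam = Var[j].
static double loglam_solve(double mu, double nu, int upper,
                           const std::vector<double>& lg) {
  double ll = loglam_approx(mu, nu);
  for (int it = 0; it < 100; ++it) {
    ZStats z = cmp_zstats(ll, nu, upper, lg);
    double f = z.Ej - mu;
    double v = z.Ej2 - z.Ej * z.Ej;
    if (v < 1e-12) break;
    double step = f / v;
    if (step > 5.0) step = 5.0;
    if (step < -5.0) step = -5.0;
    ll -= step;
    if (std::fabs(f) < 1e-10 * std::max(1.0, mu)) break;
  }
  return ll;
}

// [[Rcpp::export]]
NumericVector cmp_logpmf_cpp(IntegerVector y, NumericVector mu, double nu,
                             IntegerVector upper, std::string method) {
  int n = y.size();
  NumericVector out(n);
  int maxu = 0;
  for (int i = 0; i < n; ++i) if (upper[i] > maxu) maxu = upper[i];
  std::vector<double> lg = lgamma_table(maxu);
  bool solve = (method == "solve");
  for (int i = 0; i < n; ++i) {
    if (y[i] > upper[i]) stop("y exceeds the truncation bound");
    double ll = solve ? loglam_solve(mu[i], nu, upper[i], lg)
                      : loglam_approx(mu[i], nu);
    ZStats z = cmp_zstats(ll, nu, upper[i], lg);
    out[i] = y[i] * ll - nu * lg[y[i]] - z.logZ;
  }
  return out;
}

// [[Rcpp::export]]
double cmp_lambda_cpp(double mu, double nu, int upper, std::string method) {
  std::vector<double> lg = lgamma_table(upper);
  double ll = (method == "solve") ? loglam_solve(mu, nu, upper, lg)
                                  : loglam_approx(mu, nu);
  return std::exp(ll);
}

// ---------------------------------------------------------------------------
// Joint model: unconstrained parameter vector
//   u = [log theta_b (K), log theta_e, z (C-1, ALR coords of s_e),
//        v = log(nu - lb)]
// ---------------------------------------------------------------------------

struct Model {
  std::vector<double> y;
  double N;                    // observed burden
  std::vector<double> B;       // C x K background proportions, column-major
  int C, K;
  std::vector<int> upper;      // per-channel truncation bound
  std::vector<double> logp;    // log smoothed observed proportions
  std::vector<double> lg;      // lgamma table
  double ynorm;
  double ab, bb, ae, be;       // Gamma(shape, rate) for theta_b, theta_e
  double nu_mean, nu_sd, nu_lb, nu_lognorm;
  double rw, rt, rh;           // cosine reward weight, threshold, smoothness
  double dscale, dfloor;       // Dirichlet concentration scale and floor
};

static Model build_model(List dat) {
  Model m;
  NumericVector y = dat["y"];
  m.y.assign(y.begin(), y.end());
  m.N = as<double>(dat["N"]);
  NumericMatrix B = dat["B"];
  m.C = B.nrow();
  m.K = B.ncol();
  m.B.assign(B.begin(), B.end());
  IntegerVector up = dat["upper"];
  m.upper.assign(up.begin(), up.end());
  NumericVector p = dat["p"];
  m.logp.resize(m.C);
  for (int c = 0; c < m.C; ++c) m.logp[c] = std::log(p[c]);
  int maxu = 0;
  for (int c = 0; c < m.C; ++c) if (m.upper[c] > maxu) maxu = m.upper[c];
  m.lg = lgamma_table(maxu);
  double yn = 0.0;
  for (int c = 0; c < m.C; ++c) yn += m.y[c] * m.y[c];
  m.ynorm = std::sqrt(yn);
  m.ab = as<double>(dat["ab"]); m.bb = as<double>(dat["bb"]);
  m.ae = as<double>(dat["ae"]); m.be = as<double>(dat["be"]);
  m.nu_mean = as<double>(dat["nu_mean"]);
  m.nu_sd = as<double>(dat["nu_sd"]);
  m.nu_lb = as<double>(dat["nu_lb"]);
  m.nu_lognorm = R::pnorm(m.nu_lb, m.nu_mean, m.nu_sd, 0, 1); // log P(nu>lb)
  m.rw = as<double>(dat["rw"]);
  m.rt = as<double>(dat["rt"]);
  m.rh = as<double>(dat["rh"]);
  m.dscale = as<double>(dat["dscale"]);
  m.dfloor = as<double>(dat["dfloor"]);
  return m;
}

// Log posterior density and gradient in the unconstrained space.
// Returns -Inf (grad untouched) on numerical failure.
static double logpost_grad(const Model& m, const std::vector<double>& u,
                           std::vector<double>& grad) {
  const int K = m.K, C = m.C;
  const int dim = K + C + 1;
  std::fill(grad.begin(), grad.end(), 0.0);

  std::vector<double> tb(K);
  for (int k = 0; k < K; ++k) tb[k] = std::exp(u[k]);
  double te = std::exp(u[K]);
  double v = u[K + C];
  double nu = m.nu_lb + std::exp(v);
  if (!std::isfinite(te) || !std::isfinite(nu)) return -INFINITY;

  // softmax with implicit last coordinate 0
  std::vector<double> s(C);
  double zmax = 0.0;
  for (int j = 0; j < C - 1; ++j) if (u[K + 1 + j] > zmax) zmax = u[K + 1 + j];
  double zs = std::exp(-zmax); // last coord
  for (int j = 0; j < C - 1; ++j) {
    s[j] = std::exp(u[K + 1 + j] - zmax);
    zs += s[j];
  }
  s[C - 1] = std::exp(-zmax) / zs;
  for (int j = 0; j < C - 1; ++j) s[j] /= zs;

  // reconstruction r = N * (B theta_b + theta_e s)
  std::vector<double> r(C);
  double S = 0.0;
  for (int c = 0; c < C; ++c) {
    double acc = te * s[c];
    for (int k = 0; k < K; ++k) acc += tb[k] * m.B[c + k * C];
    r[c] = m.N * acc;
    S += r[c];
  }
  if (S <= 0.0) return -INFINITY;

  double lp = 0.0;
  // --- priors (with log-Jacobians of the transforms) ---
  for (int k = 0; k < K; ++k) {
    lp += m.ab * std::log(m.bb) - std::lgamma(m.ab)
        + (m.ab - 1.0) * u[k] - m.bb * tb[k] + u[k];
    grad[k] += m.ab - m.bb * tb[k];
  }
  lp += m.ae * std::log(m.be) - std::lgamma(m.ae)
      + (m.ae - 1.0) * u[K] - m.be * te + u[K];
  grad[K] += m.ae - m.be * te;

  lp += R::dnorm(nu, m.nu_mean, m.nu_sd, 1) - m.nu_lognorm + v;
  grad[K + C] += -(nu - m.nu_mean) / (m.nu_sd * m.nu_sd) * std::exp(v) + 1.0;

  // flat Dirichlet(1,...,1) on s_e plus ALR Jacobian sum(log s)
  lp += std::lgamma(double(C));
  for (int c = 0; c < C; ++c) lp += std::log(s[c]);
  for (int j = 0; j < C - 1; ++j) grad[K + 1 + j] += 1.0 - C * s[j];

  std::vector<double> gR(C, 0.0); // d lp / d r_c from the likelihood terms
  double dnu = 0.0;

  // --- COM-Poisson count likelihood ---
  double a = (nu - 1.0) / (2.0 * nu);
  for (int c = 0; c < C; ++c) {
    double base = r[c] + a;
    if (base <= 0.0) return -INFINITY;
    double ll = nu * std::log(base);
    ZStats z = cmp_zstats(ll, nu, m.upper[c], m.lg);
    int yc = int(m.y[c]);
    lp += yc * ll - nu * m.lg[yc] - z.logZ;
    double dll = yc - z.Ej; // d lp / d loglam
    gR[c] += dll * nu / base;
    dnu += dll * (std::log(base) + 1.0 / (2.0 * nu * base))
         + (z.Elgf - m.lg[yc]);
  }

  // --- Dirichlet spectrum likelihood ---
  {
    double asum = 0.0;
    std::vector<double> alpha(C);
    std::vector<bool> floored(C);
    for (int c = 0; c < C; ++c) {
      alpha[c] = m.dscale * r[c] / S;
      floored[c] = alpha[c] < m.dfloor;
      if (floored[c]) alpha[c] = m.dfloor;
      asum += alpha[c];
    }
    lp += std::lgamma(asum);
    double psum = R::digamma(asum);
    double tdot = 0.0;
    std::vector<double> t(C, 0.0);
    for (int c = 0; c < C; ++c) {
      lp += -std::lgamma(alpha[c]) + (alpha[c] - 1.0) * m.logp[c];
      if (!floored[c])
        t[c] = m.dscale * (psum - R::digamma(alpha[c]) + m.logp[c]);
      tdot += t[c] * (r[c] / S);
    }
    for (int c = 0; c < C; ++c) gR[c] += (t[c] - tdot) / S;
  }

  // --- cosine reward ---
  {
    double rn = 0.0, cd = 0.0;
    for (int c = 0; c < C; ++c) { rn += r[c] * r[c]; cd += m.y[c] * r[c]; }
    rn = std::sqrt(rn);
    double cs = cd / (m.ynorm * rn);
    double sig = 1.0 / (1.0 + std::exp(-(cs - m.rt) / m.rh));
    lp += m.rw * sig;
    double dcos = m.rw * sig * (1.0 - sig) / m.rh;
    for (int c = 0; c < C; ++c)
      gR[c] += dcos * (m.y[c] / (m.ynorm * rn) - cs * r[c] / (rn * rn));
  }

  if (!std::isfinite(lp)) return -INFINITY;

  // --- chain rule back to the unconstrained coordinates ---
  for (int k = 0; k < K; ++k) {
    double acc = 0.0;
    for (int c = 0; c < C; ++c) acc += gR[c] * m.B[c + k * C];
    grad[k] += tb[k] * m.N * acc;
  }
  {
    double acc = 0.0;
    for (int c = 0; c < C; ++c) acc += gR[c] * s[c];
    grad[K] += te * m.N * acc;
  }
  {
    double dot = 0.0;
    std::vector<double> dLds(C);
    for (int c = 0; c < C; ++c) {
      dLds[c] = m.N * te * gR[c];
      dot += s[c] * dLds[c];
    }
    for (int j = 0; j < C - 1; ++j)
      grad[K + 1 + j] += s[j] * (dLds[j] - dot);
  }
  grad[K + C] += dnu * std::exp(v);

  for (int i = 0; i < dim; ++i)
    if (!std::isfinite(grad[i])) return -INFINITY;
  return lp;
}

// [[Rcpp::export]]
List logpost_u_cpp(NumericVector u, List dat) {
  Model m = build_model(dat);
  int dim = m.K + m.C + 1;
  if (u.size() != dim) stop("parameter vector has wrong length");
  std::vector<double> uu(u.begin(), u.end()), g(dim, 0.0);
  double lp = logpost_grad(m, uu, g);
  return List::create(_["value"] = lp, _["grad"] = NumericVector(g.begin(), g.end()));
}

// ---------------------------------------------------------------------------
// Adaptive HMC: dual-averaging step size, one-window diagonal mass
// adaptation, jittered leapfrog trajectory lengths. Uses R's RNG so chains
// are reproducible under set.seed().
// ---------------------------------------------------------------------------

static double kinetic(const std::vector<double>& p,
                      const std::vector<double>& invM) {
  double k = 0.0;
  for (size_t i = 0; i < p.size(); ++i) k += p[i] * p[i] * invM[i];
  return 0.5 * k;
}

// [[Rcpp::export]]
List hmc_run_cpp(NumericVector u0, int warmup, int sampling, List dat,
                 int max_leapfrog, double target_accept) {
  Model m = build_model(dat);
  const int dim = m.K + m.C + 1;
  if (u0.size() != dim) stop("initial vector has wrong length");

  std::vector<double> u(u0.begin(), u0.end()), g(dim, 0.0);
  double lp = logpost_grad(m, u, g);
  if (!std::isfinite(lp)) stop("initial point has non-finite log posterior");

  std::vector<double> invM(dim, 1.0);

  // find a reasonable initial step size (single-step acceptance near 0.5)
  double eps = 0.1;
  {
    for (int tries = 0; tries < 50; ++tries) {
      std::vector<double> p(dim), u1 = u, g1 = g;
      for (int i = 0; i < dim; ++i) p[i] = norm_rand();
      double H0 = -lp + kinetic(p, invM);
      std::vector<double> p1 = p;
      for (int i = 0; i < dim; ++i) p1[i] += 0.5 * eps * g1[i];
      for (int i = 0; i < dim; ++i) u1[i] += eps * invM[i] * p1[i];
      double lp1 = logpost_grad(m, u1, g1);
      double H1 = INFINITY;
      if (std::isfinite(lp1)) {
        for (int i = 0; i < dim; ++i) p1[i] += 0.5 * eps * g1[i];
        H1 = -lp1 + kinetic(p1, invM);
      }
      double la = H0 - H1;
      if (std::isfinite(la) && la > std::log(0.5)) {
        if (la < std::log(0.95)) break;
        eps *= 2.0;
      } else {
        eps *= 0.5;
      }
      if (eps < 1e-8 || eps > 1e3) break;
    }
  }

  // dual averaging state
  double mu_da = std::log(10.0 * eps), logeps = std::log(eps),
         logeps_bar = logeps, Hbar = 0.0;
  const double da_gamma = 0.05, da_t0 = 10.0, da_kappa = 0.75;
  int da_m = 0;

  // mass-adaptation window (Welford)
  int w1 = warmup / 4, w2 = (3 * warmup) / 4;
  bool adapt_mass = warmup >= 200;
  std::vector<double> wm(dim, 0.0), ws(dim, 0.0);
  long wn = 0;

  NumericMatrix draws(sampling, dim);
  NumericVector lps(sampling);
  int divergences = 0, n_accept = 0;

  std::vector<double> p(dim), up(dim), gp(dim);
  for (int iter = 0; iter < warmup + sampling; ++iter) {
    bool in_warmup = iter < warmup;
    double step = in_warmup ? std::exp(logeps) : std::exp(logeps_bar);
    int L = 1 + int(unif_rand() * max_leapfrog);
    if (L > max_leapfrog) L = max_leapfrog;

    for (int i = 0; i < dim; ++i) p[i] = norm_rand() / std::sqrt(invM[i]);
    double H0 = -lp + kinetic(p, invM);

    up = u; gp = g;
    double lpp = lp;
    std::vector<double> pp = p;
    bool bad = false;
    for (int l = 0; l < L; ++l) {
      for (int i = 0; i < dim; ++i) pp[i] += 0.5 * step * gp[i];
      for (int i = 0; i < dim; ++i) up[i] += step * invM[i] * pp[i];
      lpp = logpost_grad(m, up, gp);
      if (!std::isfinite(lpp)) { bad = true; break; }
      for (int i = 0; i < dim; ++i) pp[i] += 0.5 * step * gp[i];
    }
    double alpha;
    if (bad) {
      alpha = 0.0;
      if (!in_warmup) ++divergences;
    } else {
      double H1 = -lpp + kinetic(pp, invM);
      double dH = H0 - H1;
      if (!std::isfinite(dH) || dH < -1000.0) {
        alpha = 0.0;
        if (!in_warmup) ++divergences;
      } else {
        alpha = dH > 0.0 ? 1.0 : std::exp(dH);
      }
    }
    if (alpha > 0.0 && unif_rand() < alpha) {
      u = up; g = gp; lp = lpp;
      if (!in_warmup) ++n_accept;
    }

    if (in_warmup) {
      ++da_m;
      Hbar = (1.0 - 1.0 / (da_m + da_t0)) * Hbar
           + (target_accept - alpha) / (da_m + da_t0);
      logeps = mu_da - std::sqrt(double(da_m)) / da_gamma * Hbar;
      double w = std::pow(double(da_m), -da_kappa);
      logeps_bar = w * logeps + (1.0 - w) * logeps_bar;

      if (adapt_mass && iter >= w1 && iter < w2) {
        ++wn;
        for (int i = 0; i < dim; ++i) {
          double d = u[i] - wm[i];
          wm[i] += d / wn;
          ws[i] += d * (u[i] - wm[i]);
        }
      }
      if (adapt_mass && iter == w2 - 1 && wn > 10) {
        for (int i = 0; i < dim; ++i) {
          double var = ws[i] / (wn - 1);
          invM[i] = var * wn / (wn + 5.0) + 1e-3 * 5.0 / (wn + 5.0);
          if (invM[i] < 1e-8) invM[i] = 1e-8;
        }
        // restart step-size adaptation around the current step
        double cur = std::exp(logeps);
        mu_da = std::log(10.0 * cur);
        Hbar = 0.0;
        da_m = 0;
        logeps = std::log(cur);
        logeps_bar = logeps;
      }
    } else {
      int s = iter - warmup;
      for (int i = 0; i < dim; ++i) draws(s, i) = u[i];
      lps[s] = lp;
    }
  }

  return List::create(
    _["draws"] = draws, _["lp"] = lps,
    _["accept_rate"] = sampling > 0 ? double(n_accept) / sampling : NA_REAL,
    _["divergences"] = divergences,
    _["stepsize"] = std::exp(logeps_bar));
}
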