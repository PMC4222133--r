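// Numerical core: conditional-Gaussian moment propagation, likelihood,
// Euler-Maruyama simulation.  A specialised scalar path handles J = 1
// (the common case and the hot loop of the optimizer); general J uses
// Armadillo.  All random draws go through R's RNG so set.seed() governs
// every stochastic routine.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG_FLOOR = 1e-300;  // floor for log-density / log-hazard args
static const double PSD_TOL   = 1e-10;   // clip-and-count tolerance for gamma

// ---------------------------------------------------------------------------
// Parameter container.  Components as functions of age t (covariate-adjusted
// intercepts are supplied per individual from the R side):
//   a(t)  = a0 + a1 t                       (J x J feedback)
//   f1(t) = f1int + f1s t                   (allostatic target)
//   f0(t) = f0int + f0s t                   (physiological norm)
//   B B'  constant;  Q(t) = Q0 max(1 + q1 t, 0);  mu0(t) = exp(c0 + th t + lmu)
// ---------------------------------------------------------------------------
struct Par {
  int J;
  arma::mat a0, a1;
  arma::vec f1s, f0s;
  arma::mat BBt;
  arma::mat Q0;
  double q1, c0, theta;
  arma::vec m0;
  arma::mat gamma0;
};

static Par par_from_list(const List& p) {
  Par P;
  P.J = as<int>(p["J"]);
  P.a0 = as<arma::mat>(p["a0"]);
  P.a1 = as<arma::mat>(p["a1"]);
  P.f1s = as<arma::vec>(p["f1_1"]);
  P.f0s = as<arma::vec>(p["f0_1"]);
  P.BBt = as<arma::mat>(p["BBt"]);
  P.Q0 = as<arma::mat>(p["Q0"]);
  P.q1 = as<double>(p["q1"]);
  P.c0 = as<double>(p["c0"]);
  P.theta = as<double>(p["theta"]);
  P.m0 = as<arma::vec>(p["m0"]);
  P.gamma0 = as<arma::mat>(p["gamma0"]);
  return P;
}

// ------------------------------ scalar (J = 1) -----------------------------

struct SPar {
  double a0, a1, f1s, f0s, bb, Q0, q1, c0, theta, m0, g0;
};

static SPar spar_from(const Par& P) {
  SPar s;
  s.a0 = P.a0(0, 0); s.a1 = P.a1(0, 0);
  s.f1s = P.f1s(0);  s.f0s = P.f0s(0);
  s.bb = P.BBt(0, 0);
  s.Q0 = P.Q0(0, 0); s.q1 = P.q1;
  s.c0 = P.c0; s.theta = P.theta;
  s.m0 = P.m0(0); s.g0 = P.gamma0(0, 0);
  return s;
}

// dm/dt = a(m - f1) - 2 g Q (m - f0)
// dg/dt = 2 a g + B^2 - 2 g^2 Q
// dH/dt = mu0 + Q ((m - f0)^2 + g)
static inline void sderiv(const SPar& p, double f1i, double f0i, double lmu,
                          double t, double m, double g,
                          double& dm, double& dg, double& dH) {
  double qf = 1.0 + p.q1 * t; if (qf < 0.0) qf = 0.0;
  double Qt = p.Q0 * qf;
  double at = p.a0 + p.a1 * t;
  double d1 = m - (f1i + p.f1s * t);
  double d0 = m - (f0i + p.f0s * t);
  dm = at * d1 - 2.0 * g * Qt * d0;
  dg = 2.0 * at * g + p.bb - 2.0 * g * g * Qt;
  dH = std::exp(p.c0 + p.theta * t + lmu) + Qt * (d0 * d0 + g);
}

static inline double smu(const SPar& p, double f1i, double f0i, double lmu,
                         double t, double m, double g) {
  double qf = 1.0 + p.q1 * t; if (qf < 0.0) qf = 0.0;
  double Qt = p.Q0 * qf;
  double d0 = m - (f0i + p.f0s * t);
  return std::exp(p.c0 + p.theta * t + lmu) + Qt * (d0 * d0 + g);
}

// classical RK4 over [t0, t1]; updates m, g, H in place; returns clip count
static int sprop(const SPar& p, double f1i, double f0i, double lmu,
                 double t0, double t1, double& m, double& g, double& H,
                 double hmax) {
  int nclip = 0;
  double len = t1 - t0;
  if (len <= 0.0) return 0;
  int n = (int)std::ceil(len / hmax);
  if (n < 1) n = 1;
  double h = len / n;
  double t = t0;
  for (int i = 0; i < n; ++i) {
    double k1m, k1g, k1H, k2m, k2g, k2H, k3m, k3g, k3H, k4m, k4g, k4H;
    sderiv(p, f1i, f0i, lmu, t, m, g, k1m, k1g, k1H);
    sderiv(p, f1i, f0i, lmu, t + 0.5 * h, m + 0.5 * h * k1m, g + 0.5 * h * k1g,
           k2m, k2g, k2H);
    sderiv(p, f1i, f0i, lmu, t + 0.5 * h, m + 0.5 * h * k2m, g + 0.5 * h * k2g,
           k3m, k3g, k3H);
    sderiv(p, f1i, f0i, lmu, t + h, m + h * k3m, g + h * k3g, k4m, k4g, k4H);
    m += h / 6.0 * (k1m + 2.0 * k2m + 2.0 * k3m + k4m);
    g += h / 6.0 * (k1g + 2.0 * k2g + 2.0 * k3g + k4g);
    H += h / 6.0 * (k1H + 2.0 * k2H + 2.0 * k3H + k4H);
    if (g < 0.0) { if (g < -PSD_TOL) ++nclip; g = 0.0; }
    t = t0 + (i + 1) * h;
    if (!std::isfinite(m) || !std::isfinite(g))
      stop("moment propagation diverged at age %.3f", t);
  }
  return nclip;
}

// ------------------------------ general J ----------------------------------

struct MState { arma::vec m; arma::mat g; double H; };

static inline void mderiv(const Par& P, const arma::vec& f1i,
                          const arma::vec& f0i, double lmu, double t,
                          const arma::vec& m, const arma::mat& g,
                          arma::vec& dm, arma::mat& dg, double& dH) {
  double qf = 1.0 + P.q1 * t; if (qf < 0.0) qf = 0.0;
  arma::mat Qt = P.Q0 * qf;
  arma::mat at = P.a0 + P.a1 * t;
  arma::vec d1 = m - (f1i + P.f1s * t);
  arma::vec d0 = m - (f0i + P.f0s * t);
  dm = at * d1 - 2.0 * g * (Qt * d0);
  dg = at * g + g * at.t() + P.BBt - 2.0 * g * Qt * g;
  dH = std::exp(P.c0 + P.theta * t + lmu) +
       arma::as_scalar(d0.t() * Qt * d0) + arma::trace(Qt * g);
}

static inline double mmu(const Par& P, const arma::vec& f0i, double lmu,
                         double t, const arma::vec& m, const arma::mat& g) {
  double qf = 1.0 + P.q1 * t; if (qf < 0.0) qf = 0.0;
  arma::mat Qt = P.Q0 * qf;
  arma::vec d0 = m - (f0i + P.f0s * t);
  return std::exp(P.c0 + P.theta * t + lmu) +
         arma::as_scalar(d0.t() * Qt * d0) + arma::trace(Qt * g);
}

static int psd_clip(arma::mat& g) {
  g = 0.5 * (g + g.t());
  arma::vec ev; arma::mat V;
  if (g.min() >= 0.0 && g.is_diagmat()) return 0;
  arma::eig_sym(ev, V, g);
  if (ev.min() >= 0.0) return 0;
  int bad = (ev.min() < -PSD_TOL) ? 1 : 0;
  ev.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  g = V * arma::diagmat(ev) * V.t();
  return bad;
}

static int mprop(const Par& P, const arma::vec& f1i, const arma::vec& f0i,
                 double lmu, double t0, double t1, MState& s, double hmax) {
  int nclip = 0;
  double len = t1 - t0;
  if (len <= 0.0) return 0;
  int n = (int)std::ceil(len / hmax);
  if (n < 1) n = 1;
  double h = len / n;
  double t = t0;
  arma::vec k1m, k2m, k3m, k4m;
  arma::mat k1g, k2g, k3g, k4g;
  double k1H, k2H, k3H, k4H;
  for (int i = 0; i < n; ++i) {
    mderiv(P, f1i, f0i, lmu, t, s.m, s.g, k1m, k1g, k1H);
    mderiv(P, f1i, f0i, lmu, t + 0.5 * h, s.m + 0.5 * h * k1m,
           s.g + 0.5 * h * k1g, k2m, k2g, k2H);
    mderiv(P, f1i, f0i, lmu, t + 0.5 * h, s.m + 0.5 * h * k2m,
           s.g + 0.5 * h * k2g, k3m, k3g, k3H);
    mderiv(P, f1i, f0i, lmu, t + h, s.m + h * k3m, s.g + h * k3g,
           k4m, k4g, k4H);
    s.m += h / 6.0 * (k1m + 2.0 * k2m + 2.0 * k3m + k4m);
    s.g += h / 6.0 * (k1g + 2.0 * k2g + 2.0 * k3g + k4g);
    s.H += h / 6.0 * (k1H + 2.0 * k2H + 2.0 * k3H + k4H);
    nclip += psd_clip(s.g);
    t = t0 + (i + 1) * h;
    if (!s.m.is_finite() || !s.g.is_finite())
      stop("moment propagation diverged at age %.3f", t);
  }
  return nclip;
}

// ---------------------------------------------------------------------------
// Propagate the moment state over one interval.  Exported for prediction and
// diagnostics; the likelihood uses the same kernels internally.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_propagate_interval(List par, arma::vec f1i, arma::vec f0i, double lmu,
                            double t_from, double t_to, arma::vec m,
                            arma::mat g, double H, double hmax) {
  Par P = par_from_list(par);
  if (P.J == 1) {
    double ms = m(0), gs = g(0, 0), Hs = H;
    SPar sp = spar_from(P);
    int nc = sprop(sp, f1i(0), f0i(0), lmu, t_from, t_to, ms, gs, Hs, hmax);
    double mu = smu(sp, f1i(0), f0i(0), lmu, t_to, ms, gs);
    return List::create(_["m"] = NumericVector::create(ms),
                        _["gamma"] = NumericMatrix(1, 1, &gs),
                        _["H"] = Hs, _["mu"] = mu, _["nclip"] = nc);
  }
  MState s; s.m = m; s.g = g; s.H = H;
  int nc = mprop(P, f1i, f0i, lmu, t_from, t_to, s, hmax);
  double mu = mmu(P, f0i, lmu, t_to, s.m, s.g);
  return List::create(_["m"] = s.m, _["gamma"] = s.g, _["H"] = s.H,
                      _["mu"] = mu, _["nclip"] = nc);
}

// ---------------------------------------------------------------------------
// Per-individual log-likelihood contributions (continuous-time model).
//
// Exact-observation mode (sigma_me = 0): first observation initialises the
// state (m <- y, gamma <- 0) and is not scored; each later observation is
// scored with the one-step-ahead Gaussian predictive density, then resets the
// state.  With sigma_me > 0 a linear-Gaussian filter update replaces the hard
// reset and the predictive covariance gains sigma_me^2 I.
// Survival factor: exp(-H(t0 -> tau)) with the hazard averaged over the
// conditional law; event adds log(mu_bar(tau-)).
// Individuals with no observations contribute the survival part only,
// propagated from the initial law.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_indiv_logliks(List par, arma::mat F1I, arma::mat F0I,
                                arma::vec LMU, arma::vec obs_age,
                                arma::mat obs_y, arma::ivec obs_ptr,
                                arma::vec t0, arma::vec tau, arma::ivec delta,
                                double hmax, double sigma_me) {
  Par P = par_from_list(par);
  const int N = t0.n_elem;
  NumericVector out(N);
  int nclip = 0;
  const double r2 = sigma_me * sigma_me;

  if (P.J == 1) {
    SPar sp = spar_from(P);
    for (int i = 0; i < N; ++i) {
      double f1i = F1I(0, i), f0i = F0I(0, i), lmu = LMU(i);
      double m = sp.m0, g = sp.g0, H = 0.0, t = t0(i);
      double ll = 0.0;
      bool seen = false;
      for (int j = obs_ptr(i); j < obs_ptr(i + 1); ++j) {
        double ta = obs_age(j), y = obs_y(0, j);
        if (ta < t - 1e-9)
          stop("individual %d: observation ages not increasing", i + 1);
        nclip += sprop(sp, f1i, f0i, lmu, t, ta, m, g, H, hmax);
        t = ta;
        if (seen) {
          double s = g + r2;
          if (s <= 0.0)
            stop("individual %d: degenerate predictive density at age %.3f "
                 "(duplicated observation age?)", i + 1, ta);
          double z = y - m;
          ll += -0.5 * std::log(2.0 * M_PI * s) - 0.5 * z * z / s;
        }
        if (r2 > 0.0) {
          double K = (g + r2 > 0.0) ? g / (g + r2) : 0.0;
          m = m + K * (y - m);
          g = (1.0 - K) * g;
          seen = true;
        } else {
          m = y; g = 0.0; seen = true;
        }
      }
      if (tau(i) < t - 1e-9)
        stop("individual %d: observation after terminal age", i + 1);
      nclip += sprop(sp, f1i, f0i, lmu, t, tau(i), m, g, H, hmax);
      double mu_end = smu(sp, f1i, f0i, lmu, tau(i), m, g);
      ll += -H;
      if (delta(i) == 1)
        ll += std::log(std::max(mu_end, LOG_FLOOR));
      out[i] = ll;
    }
  } else {
    const int J = P.J;
    arma::mat Ieye = arma::eye(J, J);
    for (int i = 0; i < N; ++i) {
      arma::vec f1i = F1I.col(i), f0i = F0I.col(i);
      double lmu = LMU(i);
      MState s; s.m = P.m0; s.g = P.gamma0; s.H = 0.0;
      double t = t0(i), ll = 0.0;
      bool seen = false;
      for (int j = obs_ptr(i); j < obs_ptr(i + 1); ++j) {
        double ta = obs_age(j);
        arma::vec y = obs_y.col(j);
        if (ta < t - 1e-9)
          stop("individual %d: observation ages not increasing", i + 1);
        nclip += mprop(P, f1i, f0i, lmu, t, ta, s, hmax);
        t = ta;
        arma::mat S = s.g + r2 * Ieye;
        if (seen) {
          arma::mat L;
          if (!arma::chol(L, S, "lower"))
            stop("individual %d: degenerate predictive density at age %.3f",
                 i + 1, ta);
          arma::vec z = arma::solve(arma::trimatl(L), y - s.m);
          ll += -0.5 * J * std::log(2.0 * M_PI) -
                arma::sum(arma::log(L.diag())) - 0.5 * arma::dot(z, z);
        }
        if (r2 > 0.0) {
          arma::mat K = s.g * arma::inv_sympd(S);
          s.m = s.m + K * (y - s.m);
          s.g = (Ieye - K) * s.g;
          psd_clip(s.g);
        } else {
          s.m = y; s.g.zeros();
        }
        seen = true;
      }
      if (tau(i) < t - 1e-9)
        stop("individual %d: observation after terminal age", i + 1);
      nclip += mprop(P, f1i, f0i, lmu, t, tau(i), s, hmax);
      double mu_end = mmu(P, f0i, lmu, tau(i), s.m, s.g);
      ll += -s.H;
      if (delta(i) == 1)
        ll += std::log(std::max(mu_end, LOG_FLOOR));
      out[i] = ll;
    }
  }
  out.attr("nclip") = nclip;
  return out;
}

// ---------------------------------------------------------------------------
// Marginal survival S(t) = exp(-int mu_bar) from the initial law, no resets.
// `ages` must be sorted increasing and >= t0.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_marginal_survival(List par, arma::vec f1i, arma::vec f0i,
                                    double lmu, double t0, arma::vec ages,
                                    double hmax) {
  Par P = par_from_list(par);
  NumericVector out(ages.n_elem);
  if (P.J == 1) {
    SPar sp = spar_from(P);
    double m = sp.m0, g = sp.g0, H = 0.0, t = t0;
    for (arma::uword k = 0; k < ages.n_elem; ++k) {
      sprop(sp, f1i(0), f0i(0), lmu, t, ages(k), m, g, H, hmax);
      t = ages(k);
      out[k] = std::exp(-H);
    }
  } else {
    MState s; s.m = P.m0; s.g = P.gamma0; s.H = 0.0;
    double t = t0;
    for (arma::uword k = 0; k < ages.n_elem; ++k) {
      mprop(P, f1i, f0i, lmu, t, ages(k), s, hmax);
      t = ages(k);
      out[k] = std::exp(-s.H);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Discrete-time likelihood.  Data must sit on the step grid: every gap
// between consecutive observations equals `step` (within tol).  Transition
// factors N(y_{j+1}; y_j + a(t_j)(y_j - f1(t_j)) D, BB' D); per-step survival
// factors exp(-mu(t_j, y_j) D) with the last observed value held fixed after
// the final examination; event factor 1 - exp(-mu D) at the event step.
// Steps before the first observation use the initial mean m0.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_discrete_logliks(List par, arma::mat F1I, arma::mat F0I,
                                   arma::vec LMU, arma::vec obs_age,
                                   arma::mat obs_y, arma::ivec obs_ptr,
                                   arma::vec t0, arma::vec tau,
                                   arma::ivec delta, double step, double tol) {
  Par P = par_from_list(par);
  const int N = t0.n_elem, J = P.J;
  NumericVector out(N);
  arma::mat L;
  if (!arma::chol(L, P.BBt * step, "lower"))
    stop("BB' * step is not positive-definite: transition density degenerate");
  double ldetL = arma::sum(arma::log(L.diag()));

  for (int i = 0; i < N; ++i) {
    arma::vec f1i = F1I.col(i), f0i = F0I.col(i);
    double lmu = LMU(i), ll = 0.0;
    int lo = obs_ptr(i), hi = obs_ptr(i + 1);
    arma::vec ycur = P.m0;
    double t = t0(i);
    // survival steps before first observation (if entry precedes it)
    double first_age = (hi > lo) ? obs_age(lo) : tau(i);
    while (t < first_age - tol) {
      double D = std::min(step, first_age - t);
      ll += -mmu(P, f0i, lmu, t, ycur, arma::zeros(J, J)) * D;
      t += D;
    }
    for (int j = lo; j < hi; ++j) {
      arma::vec y = obs_y.col(j);
      if (j > lo) {
        double gap = obs_age(j) - obs_age(j - 1);
        if (std::fabs(gap - step) > tol)
          stop("individual %d: observation gap %.6f does not equal the step "
               "%.6f; bin the data first", i + 1, gap, step);
        double tj = obs_age(j - 1);
        arma::mat at = P.a0 + P.a1 * tj;
        arma::vec mean = ycur + at * (ycur - (f1i + P.f1s * tj)) * step;
        arma::vec z = arma::solve(arma::trimatl(L), y - mean);
        ll += -0.5 * J * std::log(2.0 * M_PI) - ldetL - 0.5 * arma::dot(z, z);
        // survival factor for the step just traversed
        ll += -mmu(P, f0i, lmu, tj, ycur, arma::zeros(J, J)) * step;
      }
      ycur = y;
      t = obs_age(j);
    }
    // hold last value until tau
    bool event_done = false;
    while (t < tau(i) - tol) {
      double D = std::min(step, tau(i) - t);
      double mu = mmu(P, f0i, lmu, t, ycur, arma::zeros(J, J));
      if (delta(i) == 1 && t + D >= tau(i) - tol) {
        ll += std::log(std::max(1.0 - std::exp(-mu * D), LOG_FLOOR));
        event_done = true;
      } else {
        ll += -mu * D;
      }
      t += D;
    }
    if (delta(i) == 1 && !event_done) {
      // event at (or within tol of) the last examination age
      double mu = mmu(P, f0i, lmu, t, ycur, arma::zeros(J, J));
      ll += std::log(std::max(1.0 - std::exp(-mu * step), LOG_FLOOR));
    }
    out[i] = ll;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Euler-Maruyama path simulation with hazard-driven events.
// Event at step k with probability 1 - exp(-mu(t_k, y_k) dt); event age
// reported at the step midpoint.  Uses R's RNG.
// ---------------------------------------------------------------------------
static inline double haz(const Par& P, const arma::vec& f0i, double lmu,
                         double t, const arma::vec& y) {
  double qf = 1.0 + P.q1 * t; if (qf < 0.0) qf = 0.0;
  arma::vec d0 = y - (f0i + P.f0s * t);
  return std::exp(P.c0 + P.theta * t + lmu) +
         arma::as_scalar(d0.t() * (P.Q0 * qf) * d0);
}

// [[Rcpp::export]]
List cpp_simulate_path(List par, arma::vec f1i, arma::vec f0i, double lmu,
                       double t0, arma::vec y0, double dt, double horizon,
                       bool keep_path) {
  Par P = par_from_list(par);
  const int J = P.J;
  int nstep = (int)std::ceil((horizon - t0) / dt - 1e-12);
  arma::mat B;
  bool noise = arma::norm(P.BBt, "fro") > 0.0;
  if (noise && !arma::chol(B, P.BBt, "lower"))
    stop("BB' not positive semi-definite");
  arma::mat path;
  arma::vec times;
  if (keep_path) { path.set_size(J, nstep + 1); times.set_size(nstep + 1); }
  arma::vec y = y0;
  double t = t0;
  if (keep_path) { path.col(0) = y; times(0) = t; }
  bool event = false;
  double age_end = horizon;
  int kept = 1;
  for (int k = 0; k < nstep; ++k) {
    double h = std::min(dt, horizon - t);
    double mu = haz(P, f0i, lmu, t, y);
    if (R::runif(0.0, 1.0) < 1.0 - std::exp(-mu * h)) {
      event = true;
      age_end = t + 0.5 * h;
      break;
    }
    arma::mat at = P.a0 + P.a1 * t;
    arma::vec drift = at * (y - (f1i + P.f1s * t));
    y += drift * h;
    if (noise) {
      arma::vec z(J);
      for (int j = 0; j < J; ++j) z(j) = R::norm_rand();
      y += std::sqrt(h) * (B * z);
    }
    if (!y.is_finite())
      stop("simulated trajectory diverged at age %.3f", t + h);
    t += h;
    if (keep_path) { path.col(kept) = y; times(kept) = t; ++kept; }
  }
  List out = List::create(_["event"] = event, _["age_end"] = age_end);
  if (keep_path) {
    out["time"] = times.head(kept);
    out["y"] = path.head_cols(kept);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Cohort simulation: per-individual regime index (1-based into `pars`),
// covariate-adjusted intercepts, examination schedule in CSR layout.
// y0 drawn from the regime's initial law.  Returns kept observations (ages
// <= tau, after missingness thinning, with optional measurement noise) and
// the survival table columns.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_simulate_cohort(List pars, arma::ivec cls, arma::mat F1I,
                         arma::mat F0I, arma::vec LMU, arma::vec t0,
                         arma::vec exam_age, arma::ivec exam_ptr,
                         arma::vec cens_age, double dt, double sigma_me,
                         double miss_prob) {
  const int K = pars.size();
  std::vector<Par> P(K);
  std::vector<arma::mat> Bl(K);
  std::vector<arma::mat> L0(K);
  for (int k = 0; k < K; ++k) {
    P[k] = par_from_list(pars[k]);
    if (!arma::chol(Bl[k], P[k].BBt, "lower")) {
      if (arma::norm(P[k].BBt, "fro") == 0.0) Bl[k].zeros(P[k].J, P[k].J);
      else stop("BB' not positive semi-definite in regime %d", k + 1);
    }
    if (!arma::chol(L0[k], P[k].gamma0, "lower")) {
      if (arma::norm(P[k].gamma0, "fro") == 0.0) L0[k].zeros(P[k].J, P[k].J);
      else stop("gamma0 not positive semi-definite in regime %d", k + 1);
    }
  }
  const int N = t0.n_elem, J = P[0].J;
  std::vector<double> o_age, o_y;
  std::vector<int> o_ptr(N + 1, 0);
  arma::vec tau(N);
  arma::ivec delta(N);

  for (int i = 0; i < N; ++i) {
    int k = cls(i) - 1;
    arma::vec f1i = F1I.col(i), f0i = F0I.col(i);
    double lmu = LMU(i);
    arma::vec z(J);
    for (int j = 0; j < J; ++j) z(j) = R::norm_rand();
    arma::vec y = P[k].m0 + L0[k] * z;
    double t = t0(i), horizon = cens_age(i);
    bool event = false;
    double age_end = horizon;
    int ei = exam_ptr(i), ehi = exam_ptr(i + 1);
    // take exam at entry if scheduled at t0
    auto take_exam = [&](double at_age, const arma::vec& yy) {
      if (miss_prob > 0.0 && R::runif(0.0, 1.0) < miss_prob) return;
      o_age.push_back(at_age);
      for (int j = 0; j < J; ++j)
        o_y.push_back(yy(j) + (sigma_me > 0.0 ? R::norm_rand() * sigma_me : 0.0));
    };
    while (ei < ehi && exam_age(ei) <= t + 1e-12) {
      take_exam(exam_age(ei), y);
      ++ei;
    }
    while (t < horizon - 1e-12) {
      double h = std::min(dt, horizon - t);
      double mu = haz(P[k], f0i, lmu, t, y);
      if (R::runif(0.0, 1.0) < 1.0 - std::exp(-mu * h)) {
        event = true;
        age_end = t + 0.5 * h;
        break;
      }
      arma::mat at = P[k].a0 + P[k].a1 * t;
      y += at * (y - (f1i + P[k].f1s * t)) * h;
      for (int j = 0; j < J; ++j) z(j) = R::norm_rand();
      y += std::sqrt(h) * (Bl[k] * z);
      if (!y.is_finite())
        stop("individual %d: trajectory diverged at age %.3f", i + 1, t + h);
      t += h;
      while (ei < ehi && exam_age(ei) <= t + 1e-12) {
        if (exam_age(ei) <= age_end) take_exam(exam_age(ei), y);
        ++ei;
      }
    }
    tau(i) = event ? age_end : horizon;
    delta(i) = event ? 1 : 0;
    // drop any exam recorded past tau (event mid-step can precede grid point)
    while (!o_age.empty() && (int)o_age.size() > o_ptr[i] &&
           o_age.back() > tau(i) + 1e-12) {
      o_age.pop_back();
      for (int j = 0; j < J; ++j) o_y.pop_back();
    }
    o_ptr[i + 1] = (int)o_age.size();
  }
  arma::mat Y(J, o_age.size());
  for (size_t c = 0; c < o_age.size(); ++c)
    for (int j = 0; j < J; ++j) Y(j, c) = o_y[c * J + j];
  return List::create(_["obs_age"] = o_age, _["obs_y"] = Y,
                      _["obs_ptr"] = o_ptr, _["tau"] = tau,
                      _["delta"] = delta);
}

// ---------------------------------------------------------------------------
// Monte-Carlo marginal survival: fraction of simulated paths (y0 from the
// initial law) surviving past each requested age.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_mc_survival(List par, arma::vec f1i, arma::vec f0i,
                              double lmu, double t0, double dt,
                              arma::vec ages, int npaths) {
  Par P = par_from_list(par);
  const int J = P.J;
  arma::mat B, L0;
  if (!arma::chol(B, P.BBt, "lower")) {
    if (arma::norm(P.BBt, "fro") == 0.0) B.zeros(J, J);
    else stop("BB' not positive semi-definite");
  }
  if (!arma::chol(L0, P.gamma0, "lower")) {
    if (arma::norm(P.gamma0, "fro") == 0.0) L0.zeros(J, J);
    else stop("gamma0 not positive semi-definite");
  }
  double horizon = ages.max();
  arma::vec alive(ages.n_elem, arma::fill::zeros);
  arma::vec z(J);
  for (int s = 0; s < npaths; ++s) {
    for (int j = 0; j < J; ++j) z(j) = R::norm_rand();
    arma::vec y = P.m0 + L0 * z;
    double t = t0;
    bool event = false;
    double age_end = horizon;
    while (t < horizon - 1e-12) {
      double h = std::min(dt, horizon - t);
      double mu = haz(P, f0i, lmu, t, y);
      if (R::runif(0.0, 1.0) < 1.0 - std::exp(-mu * h)) {
        event = true;
        age_end = t + 0.5 * h;
        break;
      }
      arma::mat at = P.a0 + P.a1 * t;
      y += at * (y - (f1i + P.f1s * t)) * h;
      for (int j = 0; j < J; ++j) z(j) = R::norm_rand();
      y += std::sqrt(h) * (B * z);
      t += h;
    }
    for (arma::uword k = 0; k < ages.n_elem; ++k)
      if (!event || age_end > ages(k)) alive(k) += 1.0;
  }
  return wrap(alive / (double)npaths);
}
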