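#include <Rcpp.h>
using namespace Rcpp;

// Linear noise approximation kernels for the two-stage gene expression model
//   dM = (c*tau(t) - dM*M) dt + sqrt(c*tau(t) + dM*M) dW1
//   dP = (alpha*M - dP*P) dt + sqrt(alpha*M + dP*P) dW2
// with tau(t) a single off->on changepoint at time s (t >= s is on-phase).
// The mean has a closed form per phase (linear constant-coefficient system);
// the covariance is integrated by fixed-substep RK4 against that mean.

// (1 - exp(-a*dt))/a, stable for small and negative a; limit dt at a = 0.
static inline double gfun(double a, double dt) {
  if (std::fabs(a) < 1e-300) return dt;
  return -expm1(-a * dt) / a;
}

// Precomputed closed-form mean step over a fixed dt within one phase.
// mM' = mM*EM + ctau*gM ; mP' = mP*EP + alpha*(mM*h2 + ctau*I2)
struct MeanStep {
  double EM, EP, gM, h2, I2;
  MeanStep(double dM, double dP, double dt) {
    EM = std::exp(-dM * dt);
    EP = std::exp(-dP * dt);
    gM = gfun(dM, dt);
    double gP = gfun(dP, dt);
    h2 = EM * gfun(dP - dM, dt);
    // I2 = int_0^dt exp(-dP*(dt-u)) * g(dM, u) du; small-rate limits used
    // below the 1e-8 threshold to avoid catastrophic cancellation.
    if (std::fabs(dM) * dt > 1e-8) {
      I2 = (gP - h2) / dM;
    } else if (std::fabs(dP) * dt > 1e-8) {
      I2 = (dt - gP) / dP;
    } else {
      I2 = 0.5 * dt * dt;
    }
  }
  inline void apply(double &mM, double &mP, double ctau, double alpha) const {
    double mM1 = mM * EM + ctau * gM;
    double mP1 = mP * EP + alpha * (mM * h2 + ctau * I2);
    mM = mM1; mP = mP1;
  }
};

struct Kin {
  double tau_off, tau_on, s, alpha, dM, dP, c, kappa, sig2;
};

// Covariance ODE right-hand side given diffusion evaluated at mean (mMt, mPt).
static inline void cov_rhs(double s11, double s12, double s22,
                           double ctau, double mMt, double mPt,
                           const Kin &k,
                           double &f11, double &f12, double &f22) {
  double D1 = ctau + k.dM * mMt;
  double D2 = k.alpha * mMt + k.dP * mPt;
  f11 = -2.0 * k.dM * s11 + D1;
  f12 = k.alpha * s11 - (k.dM + k.dP) * s12;
  f22 = 2.0 * k.alpha * s12 - 2.0 * k.dP * s22 + D2;
}

// Propagate mean + covariance over one constant-phase segment of length len,
// with nsub RK4 substeps.  lin_mM/lin_mP is the linearization mean path used
// for the diffusion term (equal to the filtered mean unless a separate
// deterministic path is carried by the caller).
static void segment_step(double &mM, double &mP,
                         double &lin_mM, double &lin_mP, bool separate_lin,
                         double &s11, double &s12, double &s22,
                         double ctau, const Kin &k, double len, int nsub) {
  if (len <= 0.0) return;
  // keep h inside the RK4 stability region for the fastest relaxation rate
  // (|h * 2*delta| <= 0.5): long segments get extra substeps automatically
  double rmax = 2.0 * std::max(k.dM, k.dP);
  int nmin = (int)std::ceil(len * rmax / 0.5);
  if (nmin > nsub) nsub = nmin;
  double h = len / nsub;
  MeanStep half(k.dM, k.dP, 0.5 * h);
  for (int i = 0; i < nsub; i++) {
    // linearization mean at start / midpoint / end of the substep
    double m0M = lin_mM, m0P = lin_mP;
    double mhM = m0M, mhP = m0P;
    half.apply(mhM, mhP, ctau, k.alpha);
    double m1M = mhM, m1P = mhP;
    half.apply(m1M, m1P, ctau, k.alpha);

    double a11, a12, a22, b11, b12, b22, c11, c12, c22, d11, d12, d22;
    cov_rhs(s11, s12, s22, ctau, m0M, m0P, k, a11, a12, a22);
    cov_rhs(s11 + 0.5 * h * a11, s12 + 0.5 * h * a12, s22 + 0.5 * h * a22,
            ctau, mhM, mhP, k, b11, b12, b22);
    cov_rhs(s11 + 0.5 * h * b11, s12 + 0.5 * h * b12, s22 + 0.5 * h * b22,
            ctau, mhM, mhP, k, c11, c12, c22);
    cov_rhs(s11 + h * c11, s12 + h * c12, s22 + h * c22,
            ctau, m1M, m1P, k, d11, d12, d22);
    s11 += h / 6.0 * (a11 + 2.0 * b11 + 2.0 * c11 + d11);
    s12 += h / 6.0 * (a12 + 2.0 * b12 + 2.0 * c12 + d12);
    s22 += h / 6.0 * (a22 + 2.0 * b22 + 2.0 * c22 + d22);

    lin_mM = m1M; lin_mP = m1P;
    if (!separate_lin) {
      // filtered mean follows the same closed-form flow
      mM = m1M; mP = m1P;
    }
  }
  if (separate_lin) {
    MeanStep full(k.dM, k.dP, len);
    full.apply(mM, mP, ctau, k.alpha);
  }
}

// Propagate over (t0, t1], splitting at the changepoint s if it is interior.
static void interval_step(double t0, double t1,
                          double &mM, double &mP,
                          double &lin_mM, double &lin_mP, bool separate_lin,
                          double &s11, double &s12, double &s22,
                          const Kin &k, int nsub) {
  double ct_off = k.c * k.tau_off, ct_on = k.c * k.tau_on;
  if (t0 < k.s && k.s < t1) {
    segment_step(mM, mP, lin_mM, lin_mP, separate_lin, s11, s12, s22,
                 ct_off, k, k.s - t0, nsub);
    segment_step(mM, mP, lin_mM, lin_mP, separate_lin, s11, s12, s22,
                 ct_on, k, t1 - k.s, nsub);
  } else {
    double ctau = (t0 >= k.s) ? ct_on : ct_off;
    segment_step(mM, mP, lin_mM, lin_mP, separate_lin, s11, s12, s22,
                 ctau, k, t1 - t0, nsub);
  }
}

// Clip tiny negative eigenvalues of the 2x2 covariance; returns false when
// the matrix is indefinite beyond tolerance (caller raises).
static bool psd_project(double &s11, double &s12, double &s22) {
  double tr = s11 + s22;
  double tol = 1e-10 * std::max(tr, 1.0);
  double disc = std::sqrt(std::max(0.25 * (s11 - s22) * (s11 - s22) + s12 * s12, 0.0));
  double lmin = 0.5 * tr - disc;
  if (lmin >= 0.0) return true;
  if (lmin < -tol) return false;
  double lmax = 0.5 * tr + disc;
  // eigenvector for lmax
  double vx, vy;
  if (std::fabs(s12) > 1e-300) {
    vx = lmax - s22; vy = s12;
  } else {
    vx = (s11 >= s22) ? 1.0 : 0.0; vy = 1.0 - vx;
  }
  double nrm = std::sqrt(vx * vx + vy * vy);
  if (nrm == 0.0) { s11 = s12 = s22 = 0.0; return true; }
  vx /= nrm; vy /= nrm;
  s11 = lmax * vx * vx; s12 = lmax * vx * vy; s22 = lmax * vy * vy;
  return true;
}

static Kin make_kin(double tau_off, double tau_on, double s, double alpha,
                    double delta_M, double delta_P, double copy_number,
                    double kappa, double sigma_eps2) {
  Kin k;
  k.tau_off = tau_off; k.tau_on = tau_on; k.s = s; k.alpha = alpha;
  k.dM = delta_M; k.dP = delta_P; k.c = copy_number;
  k.kappa = kappa; k.sig2 = sigma_eps2;
  return k;
}

// [[Rcpp::export]]
List lna_propagate_cpp(double t0, NumericVector mean, NumericVector cov,
                       double t1,
                       double tau_off, double tau_on, double s, double alpha,
                       double delta_M, double delta_P, double copy_number,
                       int nsub) {
  Kin k = make_kin(tau_off, tau_on, s, alpha, delta_M, delta_P, copy_number,
                   1.0, 0.0);
  double mM = mean[0], mP = mean[1];
  double lin_mM = mM, lin_mP = mP;
  double s11 = cov[0], s12 = cov[1], s22 = cov[2];
  interval_step(t0, t1, mM, mP, lin_mM, lin_mP, false, s11, s12, s22, k, nsub);
  if (!psd_project(s11, s12, s22))
    stop("covariance lost positive semi-definiteness during propagation");
  return List::create(_["mean"] = NumericVector::create(mM, mP),
                      _["cov"] = NumericVector::create(s11, s12, s22));
}

static double filter_loglik(const NumericVector &times,
                            const NumericVector &signals,
                            const Kin &k, int nsub, bool deterministic_lin,
                            NumericVector *increments,
                            NumericVector *final_mean,
                            NumericVector *final_cov) {
  int n = times.size();
  double mM = 0.0, mP = 0.0, s11 = 0.0, s12 = 0.0, s22 = 0.0;
  double lin_mM = 0.0, lin_mP = 0.0;
  double t = 0.0, ll = 0.0;
  const double LOG2PI = 1.8378770664093454836;
  for (int i = 0; i < n; i++) {
    interval_step(t, times[i], mM, mP, lin_mM, lin_mP, deterministic_lin,
                  s11, s12, s22, k, nsub);
    t = times[i];
    double S = k.kappa * k.kappa * s22 + k.sig2;
    if (!(S > 0.0) || !R_finite(S)) return R_NegInf;
    double r = signals[i] - k.kappa * mP;
    double inc = -0.5 * (LOG2PI + std::log(S)) - 0.5 * r * r / S;
    ll += inc;
    if (increments) (*increments)[i] = inc;
    double K1 = k.kappa * s12 / S, K2 = k.kappa * s22 / S;
    mM += K1 * r; mP += K2 * r;
    double n11 = s11 - K1 * k.kappa * s12;
    double n12 = s12 - K1 * k.kappa * s22;
    double n22 = s22 - K2 * k.kappa * s22;
    s11 = n11; s12 = n12; s22 = n22;
    if (!psd_project(s11, s12, s22)) return R_NegInf;
    if (!deterministic_lin) { lin_mM = mM; lin_mP = mP; }
  }
  if (final_mean) { (*final_mean)[0] = mM; (*final_mean)[1] = mP; }
  if (final_cov) { (*final_cov)[0] = s11; (*final_cov)[1] = s12; (*final_cov)[2] = s22; }
  if (!R_finite(ll)) return R_NegInf;
  return ll;
}

// [[Rcpp::export]]
double lna_loglik_cpp(NumericVector times, NumericVector signals,
                      double tau_off, double tau_on, double s, double alpha,
                      double delta_M, double delta_P, double copy_number,
                      double kappa, double sigma_eps2,
                      int nsub, bool deterministic_lin) {
  Kin k = make_kin(tau_off, tau_on, s, alpha, delta_M, delta_P, copy_number,
                   kappa, sigma_eps2);
  return filter_loglik(times, signals, k, nsub, deterministic_lin,
                       nullptr, nullptr, nullptr);
}

// [[Rcpp::export]]
List lna_filter_cpp(NumericVector times, NumericVector signals,
                    double tau_off, double tau_on, double s, double alpha,
                    double delta_M, double delta_P, double copy_number,
                    double kappa, double sigma_eps2,
                    int nsub, bool deterministic_lin) {
  Kin k = make_kin(tau_off, tau_on, s, alpha, delta_M, delta_P, copy_number,
                   kappa, sigma_eps2);
  NumericVector inc(times.size()), fm(2), fc(3);
  double ll = filter_loglik(times, signals, k, nsub, deterministic_lin,
                            &inc, &fm, &fc);
  return List::create(_["loglik"] = ll, _["increments"] = inc,
                      _["mean"] = fm, _["cov"] = fc);
}
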