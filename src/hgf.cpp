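#include <Rcpp.h>
using namespace Rcpp;

// Two parallel binary hierarchical Gaussian filter branches (color, shape).
//
// Per-branch update, trial k (hat = prediction before seeing u):
//   sigma2hat = sigma2 + exp(kappa*mu3 + omega)    (2-level: exp(omega))
//   mu1hat    = logistic(mu2), argument clamped to +/- `clamp`
//   pi1hat    = 1 / (mu1hat * (1 - mu1hat))        (>= 4)
//   delta1    = u - mu1hat
//   pi2       = 1/sigma2hat + 1/pi1hat
//   mu2      <- mu2 + w * delta1 / pi2             (w = 1, or 2*rel for
//                                                   precision-feedback branches)
//   sigma2   <- 1/pi2
// 3-level volatility branch (kappa coupling, constant step theta on level 3):
//   w2     = exp(kappa*mu3 + omega) / sigma2hat
//   delta2 = (sigma2 + dmu2^2) / sigma2hat - 1
//   pi3    = 1/(sigma3 + theta) + kappa^2/2 * w2 * (w2 + (2*w2 - 1)*delta2)
//   mu3   <- mu3 + kappa/(2*pi3) * w2 * delta2
//
// Relevance weights are prediction-time quantities:
//   rel_color(k) = pi1hat_color(k) / (pi1hat_color(k) + pi1hat_shape(k)).

struct BranchState {
  double mu2, sigma2, mu3, sigma3;
};

struct BranchOut {
  double mu1hat, pi1hat, sigma2hat, vstep;
};

static const double SIGMA2_FLOOR = 1e-12;
static const double PI3_FLOOR = 1e-6;

static inline double logistic_clamped(double x, double clamp) {
  if (x > clamp) x = clamp;
  if (x < -clamp) x = -clamp;
  return 1.0 / (1.0 + std::exp(-x));
}

static inline bool branch_predict(const BranchState &s, int n_levels,
                                  double kappa, double omega, double theta,
                                  double clamp, BranchOut &out) {
  double vstep = (n_levels == 3) ? std::exp(kappa * s.mu3 + omega)
                                 : std::exp(omega);
  if (!std::isfinite(vstep)) return false;
  out.vstep = vstep;
  out.sigma2hat = s.sigma2 + vstep;
  if (!(out.sigma2hat > 0.0)) return false;
  out.mu1hat = logistic_clamped(s.mu2, clamp);
  out.pi1hat = 1.0 / (out.mu1hat * (1.0 - out.mu1hat));
  return std::isfinite(out.pi1hat);
}

// Returns false on numerical failure; flags record floor activations.
static inline bool branch_update(BranchState &s, const BranchOut &p, double u,
                                 double w, int n_levels, double kappa,
                                 double theta, bool &floored) {
  double delta1 = u - p.mu1hat;
  double pi2 = 1.0 / p.sigma2hat + 1.0 / p.pi1hat;
  if (!std::isfinite(pi2) || pi2 <= 0.0) return false;
  double mu2_old = s.mu2;
  s.mu2 = s.mu2 + w * delta1 / pi2;
  s.sigma2 = 1.0 / pi2;
  if (s.sigma2 < SIGMA2_FLOOR) { s.sigma2 = SIGMA2_FLOOR; floored = true; }
  if (n_levels == 3) {
    double w2 = p.vstep / p.sigma2hat;
    double dmu2 = s.mu2 - mu2_old;
    double delta2 = (s.sigma2 + dmu2 * dmu2) / p.sigma2hat - 1.0;
    double pi3hat = 1.0 / (s.sigma3 + theta);
    double pi3 = pi3hat +
      0.5 * kappa * kappa * w2 * (w2 + (2.0 * w2 - 1.0) * delta2);
    if (!std::isfinite(pi3)) return false;
    if (pi3 < PI3_FLOOR) { pi3 = PI3_FLOOR; floored = true; }
    s.mu3 = s.mu3 + 0.5 * kappa * (1.0 / pi3) * w2 * delta2;
    s.sigma3 = 1.0 / pi3;
  }
  return std::isfinite(s.mu2);
}

// Core pass over the trial sequence. Writes trajectories into the supplied
// vectors (length n). Returns the 1-based index of the first failing trial,
// or 0 on success.
static int filter_pass(const IntegerVector &u_color,
                       const IntegerVector &u_shape, double omega,
                       double sigma2_0, double mu2_0, int n_levels,
                       bool precfb, double kappa, double mu3_0,
                       double sigma3_0, double theta, double clamp,
                       NumericVector &mu1hat_c, NumericVector &pi1hat_c,
                       NumericVector &delta1_c, NumericVector &mu1hat_s,
                       NumericVector &pi1hat_s, NumericVector &delta1_s,
                       NumericVector &rel_color, NumericVector &rel_shape,
                       NumericVector &mu2_c, NumericVector &mu2_s,
                       bool &floored) {
  int n = u_color.size();
  BranchState sc = {mu2_0, sigma2_0, mu3_0, sigma3_0};
  BranchState ss = {mu2_0, sigma2_0, mu3_0, sigma3_0};
  floored = false;
  for (int k = 0; k < n; ++k) {
    BranchOut pc, ps;
    if (!branch_predict(sc, n_levels, kappa, omega, theta, clamp, pc))
      return k + 1;
    if (!branch_predict(ss, n_levels, kappa, omega, theta, clamp, ps))
      return k + 1;
    double rc = pc.pi1hat / (pc.pi1hat + ps.pi1hat);
    double rs = 1.0 - rc;
    mu1hat_c[k] = pc.mu1hat; pi1hat_c[k] = pc.pi1hat;
    mu1hat_s[k] = ps.mu1hat; pi1hat_s[k] = ps.pi1hat;
    delta1_c[k] = u_color[k] - pc.mu1hat;
    delta1_s[k] = u_shape[k] - ps.mu1hat;
    rel_color[k] = rc; rel_shape[k] = rs;
    double wc = precfb ? 2.0 * rc : 1.0;
    double ws = precfb ? 2.0 * rs : 1.0;
    if (!branch_update(sc, pc, (double)u_color[k], wc, n_levels, kappa, theta,
                       floored))
      return k + 1;
    if (!branch_update(ss, ps, (double)u_shape[k], ws, n_levels, kappa, theta,
                       floored))
      return k + 1;
    mu2_c[k] = sc.mu2; mu2_s[k] = ss.mu2;
  }
  return 0;
}

// [[Rcpp::export]]
List hgf_filter_cpp(IntegerVector u_color, IntegerVector u_shape, double omega,
                    double sigma2_0, double mu2_0, int n_levels, bool precfb,
                    double kappa, double mu3_0, double sigma3_0, double theta,
                    double clamp) {
  int n = u_color.size();
  NumericVector mu1hat_c(n), pi1hat_c(n), delta1_c(n), mu1hat_s(n),
      pi1hat_s(n), delta1_s(n), rel_color(n), rel_shape(n), mu2_c(n), mu2_s(n);
  bool floored = false;
  int bad = filter_pass(u_color, u_shape, omega, sigma2_0, mu2_0, n_levels,
                        precfb, kappa, mu3_0, sigma3_0, theta, clamp, mu1hat_c,
                        pi1hat_c, delta1_c, mu1hat_s, pi1hat_s, delta1_s,
                        rel_color, rel_shape, mu2_c, mu2_s, floored);
  return List::create(
      _["ok"] = (bad == 0), _["bad_trial"] = bad, _["floored"] = floored,
      _["mu1hat_color"] = mu1hat_c, _["pi1hat_color"] = pi1hat_c,
      _["delta1_color"] = delta1_c, _["mu1hat_shape"] = mu1hat_s,
      _["pi1hat_shape"] = pi1hat_s, _["delta1_shape"] = delta1_s,
      _["rel_color"] = rel_color, _["rel_shape"] = rel_shape,
      _["mu2_color"] = mu2_c, _["mu2_shape"] = mu2_s);
}

// Negative log-likelihood of observed log RTs under one learning x response
// model combination. beta = (b0, b1, b2, b3, b4, b5, b6); zeta is the
// Gaussian noise *variance* on the log-RT scale. Invalid trials contribute
// nothing to the likelihood but are filtered through the learner (the
// stimulus stream is observed regardless of the response).
// Returns +Inf on numerically invalid trajectories or zeta <= 0.
// [[Rcpp::export]]
double rt_neg_loglik_cpp(IntegerVector u_color, IntegerVector u_shape,
                         double omega, double sigma2_0, double mu2_0,
                         int n_levels, bool precfb, double kappa, double mu3_0,
                         double sigma3_0, double theta, double clamp,
                         NumericVector beta, double zeta, bool relpe,
                         bool irrelbias, NumericVector m_colorful,
                         NumericVector m_grey, NumericVector m_square,
                         NumericVector m_triangle, NumericVector outcome_code,
                         NumericVector logrt, LogicalVector valid) {
  int n = u_color.size();
  if (!(zeta > 0.0) || !std::isfinite(zeta)) return R_PosInf;
  NumericVector mu1hat_c(n), pi1hat_c(n), delta1_c(n), mu1hat_s(n),
      pi1hat_s(n), delta1_s(n), rel_color(n), rel_shape(n), mu2_c(n), mu2_s(n);
  bool floored = false;
  int bad = filter_pass(u_color, u_shape, omega, sigma2_0, mu2_0, n_levels,
                        precfb, kappa, mu3_0, sigma3_0, theta, clamp, mu1hat_c,
                        pi1hat_c, delta1_c, mu1hat_s, pi1hat_s, delta1_s,
                        rel_color, rel_shape, mu2_c, mu2_s, floored);
  if (bad != 0) return R_PosInf;
  double nll = 0.0;
  double half_log = 0.5 * std::log(2.0 * M_PI * zeta);
  for (int k = 0; k < n; ++k) {
    if (!valid[k]) continue;
    double adc = std::fabs(delta1_c[k]);
    double ads = std::fabs(delta1_s[k]);
    double pe = relpe ? (rel_color[k] * adc + rel_shape[k] * ads) / 2.0
                      : (adc + ads) / 2.0;
    double bias_c = beta[2] * m_colorful[k] + beta[3] * m_grey[k];
    double bias_s = beta[4] * m_square[k] + beta[5] * m_triangle[k];
    if (irrelbias) {
      // irrelevance of a feature = relevance of the opposing feature
      bias_c *= rel_shape[k];
      bias_s *= rel_color[k];
    }
    double pred = beta[0] + beta[1] * pe - bias_c - bias_s +
                  beta[6] * outcome_code[k];
    double r = logrt[k] - pred;
    nll += half_log + r * r / (2.0 * zeta);
  }
  if (!std::isfinite(nll)) return R_PosInf;
  return nll;
}
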