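// Compiled kernels for the hierarchical HMM: the inner four-state
// forward/backward pass runs once per candidate block inside the segmentation
// dynamic program, so both live here. State order: prev=0, curr=1, next=2,
// noise=3.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double LOG2PI = std::log(2.0 * M_PI);

static inline double gauss_pdf(double x, double mu, double sigma) {
  double z = (x - mu) / sigma;
  return std::exp(-0.5 * z * z) / (sigma * std::sqrt(2.0 * M_PI));
}

// Emission densities for one sample across the four states. Disabled states
// (mu = NA) get zero density; callers also zero their transition mass.
static inline void emis_row(double y, const double* mu, double sigma,
                            double noise_lo, double noise_hi, double* e) {
  for (int s = 0; s < 3; ++s)
    e[s] = ISNAN(mu[s]) ? 0.0 : gauss_pdf(y, mu[s], sigma);
  e[3] = (y >= noise_lo && y <= noise_hi && noise_hi > noise_lo)
             ? 1.0 / (noise_hi - noise_lo)
             : 0.0;
}

struct InnerParams {
  double trans[4][4];
  double init[4];
  double sigma;
  double noise_lo, noise_hi;
};

// Zero out transition/initial mass into disabled states and renormalize.
static void adjust_params(const InnerParams& in, const double* mu,
                          InnerParams& out) {
  out = in;
  bool off[4] = {ISNAN(mu[0]), false, ISNAN(mu[2]), false};
  for (int s = 0; s < 4; ++s)
    if (off[s]) {
      out.init[s] = 0.0;
      for (int r = 0; r < 4; ++r) out.trans[r][s] = 0.0;
    }
  double si = 0.0;
  for (int s = 0; s < 4; ++s) si += out.init[s];
  if (si > 0)
    for (int s = 0; s < 4; ++s) out.init[s] /= si;
  for (int r = 0; r < 4; ++r) {
    double sr = 0.0;
    for (int s = 0; s < 4; ++s) sr += out.trans[r][s];
    if (sr > 0)
      for (int s = 0; s < 4; ++s) out.trans[r][s] /= sr;
  }
}

// Scaled forward pass; returns log marginal likelihood (-Inf if the sequence
// has zero probability under the model).
static double forward_loglik(const double* y, int n, const double* mu,
                             const InnerParams& p) {
  double alpha[4], e[4];
  double ll = 0.0;
  emis_row(y[0], mu, p.sigma, p.noise_lo, p.noise_hi, e);
  double c = 0.0;
  for (int s = 0; s < 4; ++s) {
    alpha[s] = p.init[s] * e[s];
    c += alpha[s];
  }
  if (c <= 0.0) return R_NegInf;
  for (int s = 0; s < 4; ++s) alpha[s] /= c;
  ll += std::log(c);
  for (int t = 1; t < n; ++t) {
    emis_row(y[t], mu, p.sigma, p.noise_lo, p.noise_hi, e);
    double next[4];
    c = 0.0;
    for (int s = 0; s < 4; ++s) {
      double a = 0.0;
      for (int r = 0; r < 4; ++r) a += alpha[r] * p.trans[r][s];
      next[s] = a * e[s];
      c += next[s];
    }
    if (c <= 0.0) return R_NegInf;
    for (int s = 0; s < 4; ++s) alpha[s] = next[s] / c;
    ll += std::log(c);
  }
  return ll;
}

static InnerParams unpack_params(NumericMatrix trans, NumericVector init,
                                 double sigma, double noise_lo,
                                 double noise_hi) {
  InnerParams p;
  for (int r = 0; r < 4; ++r)
    for (int s = 0; s < 4; ++s) p.trans[r][s] = trans(r, s);
  for (int s = 0; s < 4; ++s) p.init[s] = init[s];
  p.sigma = sigma;
  p.noise_lo = noise_lo;
  p.noise_hi = noise_hi;
  return p;
}

// [[Rcpp::export(name = ".inner_forward_cpp")]]
double inner_forward_cpp(NumericVector y, NumericVector mu,
                         NumericMatrix trans, NumericVector init, double sigma,
                         double noise_lo, double noise_hi) {
  InnerParams p0 = unpack_params(trans, init, sigma, noise_lo, noise_hi);
  InnerParams p;
  double mu3[3] = {mu[0], mu[1], mu[2]};
  adjust_params(p0, mu3, p);
  return forward_loglik(REAL(y), y.size(), mu3, p);
}

// [[Rcpp::export(name = ".inner_posteriors_cpp")]]
NumericMatrix inner_posteriors_cpp(NumericVector y, NumericVector mu,
                                   NumericMatrix trans, NumericVector init,
                                   double sigma, double noise_lo,
                                   double noise_hi) {
  int n = y.size();
  InnerParams p0 = unpack_params(trans, init, sigma, noise_lo, noise_hi);
  InnerParams p;
  double mu3[3] = {mu[0], mu[1], mu[2]};
  adjust_params(p0, mu3, p);

  std::vector<double> a(n * 4), b(n * 4), cs(n);
  double e[4];
  emis_row(y[0], mu3, p.sigma, p.noise_lo, p.noise_hi, e);
  double c = 0.0;
  for (int s = 0; s < 4; ++s) {
    a[s] = p.init[s] * e[s];
    c += a[s];
  }
  if (c <= 0.0) stop("zero-probability sample in inner HMM");
  for (int s = 0; s < 4; ++s) a[s] /= c;
  cs[0] = c;
  for (int t = 1; t < n; ++t) {
    emis_row(y[t], mu3, p.sigma, p.noise_lo, p.noise_hi, e);
    c = 0.0;
    for (int s = 0; s < 4; ++s) {
      double v = 0.0;
      for (int r = 0; r < 4; ++r) v += a[(t - 1) * 4 + r] * p.trans[r][s];
      a[t * 4 + s] = v * e[s];
      c += a[t * 4 + s];
    }
    if (c <= 0.0) stop("zero-probability sample in inner HMM");
    for (int s = 0; s < 4; ++s) a[t * 4 + s] /= c;
    cs[t] = c;
  }
  for (int s = 0; s < 4; ++s) b[(n - 1) * 4 + s] = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    emis_row(y[t + 1], mu3, p.sigma, p.noise_lo, p.noise_hi, e);
    for (int r = 0; r < 4; ++r) {
      double v = 0.0;
      for (int s = 0; s < 4; ++s)
        v += p.trans[r][s] * e[s] * b[(t + 1) * 4 + s];
      b[t * 4 + r] = v / cs[t + 1];
    }
  }
  NumericMatrix post(n, 4);
  for (int t = 0; t < n; ++t) {
    double z = 0.0;
    for (int s = 0; s < 4; ++s) z += a[t * 4 + s] * b[t * 4 + s];
    for (int s = 0; s < 4; ++s) post(t, s) = a[t * 4 + s] * b[t * 4 + s] / z;
  }
  return post;
}

// OLS line fit; log-likelihood of residuals under N(0, residual_sigma), with
// the slope gate making near-flat stretches inadmissible as transitions.
// [[Rcpp::export(name = ".transition_loglik_cpp")]]
double transition_loglik_cpp(NumericVector y, double min_abs_slope,
                             double residual_sigma) {
  int n = y.size();
  if (n < 2) return R_NegInf;
  double sx = 0, sy = 0, sxx = 0, sxy = 0;
  for (int i = 0; i < n; ++i) {
    sx += i;
    sy += y[i];
    sxx += (double)i * i;
    sxy += i * y[i];
  }
  double den = n * sxx - sx * sx;
  double slope = (n * sxy - sx * sy) / den;
  double icpt = (sy - slope * sx) / n;
  if (std::fabs(slope) < min_abs_slope) return R_NegInf;
  double ll = 0.0;
  double ls = std::log(residual_sigma);
  for (int i = 0; i < n; ++i) {
    double r = y[i] - (icpt + slope * i);
    ll += -0.5 * LOG2PI - ls - 0.5 * r * r / (residual_sigma * residual_sigma);
  }
  return ll;
}

static double trimmed_mean(const double* y, int from, int to, double frac) {
  int n = to - from;
  std::vector<double> v(y + from, y + to);
  std::sort(v.begin(), v.end());
  int drop = (int)std::floor(frac * n);
  if (2 * drop >= n) drop = 0;
  double s = 0.0;
  for (int i = drop; i < n - drop; ++i) s += v[i];
  return s / (n - 2 * drop);
}

// Segmentation dynamic program over a candidate-changepoint lattice.
// cand: 0-based sample indices, strictly increasing, starting at 0 and ending
// at n. Returns the maximum-objective alternating B/T segmentation (starting
// and ending with B) where base blocks are scored by the inner-HMM marginal,
// transition blocks by the gated linear model, and block arrangement by the
// outer-HMM per-sample transition probabilities.
// [[Rcpp::export(name = ".segment_dp_cpp")]]
List segment_dp_cpp(NumericVector y, IntegerVector cand, int min_base_len,
                    int max_base_len, int max_trans_len, double min_abs_slope,
                    double residual_sigma, NumericMatrix trans,
                    NumericVector init, double sigma_inner, double noise_lo,
                    double noise_hi, NumericMatrix log_T_outer,
                    double log_pi_B, double trim_frac) {
  int M = cand.size();
  const double* yp = REAL(y);
  InnerParams base = unpack_params(trans, init, sigma_inner, noise_lo, noise_hi);

  // trimmed mean of the nearest elementary candidate segment of base length
  // to the left of cand[i] / right of cand[i] (NA when none exists):
  // stands in for the neighbouring k-mer baseline before any reference is
  // known.
  std::vector<double> prevMean(M, NA_REAL), nextMean(M, NA_REAL);
  for (int i = 1; i < M; ++i) {
    if (cand[i] - cand[i - 1] >= min_base_len)
      prevMean[i] = trimmed_mean(yp, cand[i - 1], cand[i], trim_frac);
    else
      prevMean[i] = prevMean[i - 1];
  }
  for (int i = M - 2; i >= 0; --i) {
    if (cand[i + 1] - cand[i] >= min_base_len)
      nextMean[i] = trimmed_mean(yp, cand[i], cand[i + 1], trim_frac);
    else
      nextMean[i] = nextMean[i + 1];
  }

  const double NEG = R_NegInf;
  std::vector<double> dpB(M, NEG), dpT(M, NEG);
  std::vector<int> fromB(M, -1), fromT(M, -1);
  double lBB = log_T_outer(0, 0), lBT = log_T_outer(0, 1);
  double lTB = log_T_outer(1, 0), lTT = log_T_outer(1, 1);

  InnerParams adj;
  for (int j = 1; j < M; ++j) {
    // base block ending at cand[j]; blocks longer than max_base_len are only
    // considered between adjacent candidates (degenerate flat signals)
    for (int i = 0; i < j; ++i) {
      int len = cand[j] - cand[i];
      if (len < min_base_len) continue;
      if (len > max_base_len && i != j - 1) continue;
      double head = (i == 0) ? log_pi_B
                             : (dpT[i] == NEG ? NEG : dpT[i] + lTB);
      if (head == NEG) continue;
      double mu3[3] = {prevMean[i], trimmed_mean(yp, cand[i], cand[j], trim_frac),
                       nextMean[j]};
      adjust_params(base, mu3, adj);
      double em = forward_loglik(yp + cand[i], len, mu3, adj);
      if (em == NEG) continue;
      double sc = head + em + (len - 1) * lBB;
      if (sc > dpB[j] + 1e-12) {
        dpB[j] = sc;
        fromB[j] = i;
      }
    }
    // transition block ending at cand[j]
    for (int i = std::max(1, j - 1); i >= 1; --i) {
      int len = cand[j] - cand[i];
      if (len > max_trans_len) break;
      if (len < 2) continue;
      if (dpB[i] == NEG) continue;
      NumericVector seg(yp + cand[i], yp + cand[j]);
      double em = transition_loglik_cpp(seg, min_abs_slope, residual_sigma);
      if (em == R_NegInf) continue;
      double sc = dpB[i] + lBT + em + (len - 1) * lTT;
      if (sc > dpT[j] + 1e-12) {
        dpT[j] = sc;
        fromT[j] = i;
      }
    }
  }

  if (dpB[M - 1] == NEG)
    return List::create(Named("ok") = false);

  std::vector<int> bnd;
  std::vector<char> lab;
  int j = M - 1;
  char cur = 'B';
  bnd.push_back(cand[j]);
  while (j > 0) {
    int i = (cur == 'B') ? fromB[j] : fromT[j];
    lab.push_back(cur);
    bnd.push_back(cand[i]);
    cur = (cur == 'B') ? 'T' : 'B';
    j = i;
  }
  std::reverse(bnd.begin(), bnd.end());
  std::reverse(lab.begin(), lab.end());
  int nb = lab.size();
  IntegerVector starts(nb), ends(nb);
  CharacterVector labels(nb);
  NumericVector muPrev(nb), muNext(nb);
  for (int b = 0; b < nb; ++b) {
    starts[b] = bnd[b];
    ends[b] = bnd[b + 1];
    labels[b] = std::string(1, lab[b]);
    // neighbour means used when this block was scored (for posterior reuse)
    int ci = std::find(cand.begin(), cand.end(), bnd[b]) - cand.begin();
    int cj = std::find(cand.begin(), cand.end(), bnd[b + 1]) - cand.begin();
    muPrev[b] = prevMean[ci];
    muNext[b] = nextMean[cj];
  }
  return List::create(Named("ok") = true, Named("start") = starts,
                      Named("end") = ends, Named("label") = labels,
                      Named("mu_prev") = muPrev, Named("mu_next") = muNext,
                      Named("loglik") = dpB[M - 1]);
}
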