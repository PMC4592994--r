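#include <Rcpp.h>
using namespace Rcpp;

// Exact Polya-Gamma sampling via Devroye's alternating-series rejection for
// PG(1, c); PG(b, c) with integer b is the b-fold convolution (PG is
// infinitely divisible in its shape). The target is the Jacobi-type density:
// PG(1, c) = J*(1, c/2) / 4.

static const double TRUNC = 0.64; // crossover point of the two series forms

static double a_coef(int n, double x) {
  double nh = n + 0.5;
  if (x > TRUNC)
    return M_PI * nh * std::exp(-nh * nh * M_PI * M_PI * x / 2.0);
  else
    return M_PI * nh * std::pow(2.0 / (M_PI * x), 1.5) *
           std::exp(-2.0 * nh * nh / x);
}

// P(IG(mu = 1/z, lambda = 1) <= t), z >= 0 (z = 0 is the Levy limit);
// the exp(2z) factor is evaluated on the log scale to survive large z.
static double pigauss(double t, double z) {
  double s = 1.0 / std::sqrt(t);
  double t1 = R::pnorm(s * (t * z - 1.0), 0.0, 1.0, 1, 0);
  double t2 = std::exp(2.0 * z + R::pnorm(-s * (t * z + 1.0), 0.0, 1.0, 1, 1));
  return t1 + t2;
}

// Inverse-Gaussian(1/z, 1) restricted to (0, t)
static double rtigauss(double z, double t) {
  double x;
  if (z < 1.0 / t) {
    // mean beyond the truncation point: scaled-chi-square proposal
    for (;;) {
      double e1, e2;
      do {
        e1 = exp_rand();
        e2 = exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      if (unif_rand() <= std::exp(-0.5 * z * z * x)) return x;
    }
  } else {
    // Michael-Schucany-Haas, retry until inside (0, t)
    double mu = 1.0 / z;
    for (;;) {
      double y = norm_rand();
      y *= y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy -
          0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
      if (x <= t) return x;
    }
  }
}

// One exact PG(1, c) draw. Symmetric in c.
double rpg1(double c) {
  double z = std::fabs(c) * 0.5;
  double fz = M_PI * M_PI / 8.0 + z * z / 2.0;
  double p = (M_PI / (2.0 * fz)) * std::exp(-fz * TRUNC);
  double q = 2.0 * std::exp(-z) * pigauss(TRUNC, z);
  for (;;) {
    double x;
    if (unif_rand() < p / (p + q))
      x = TRUNC + exp_rand() / fz; // truncated-exponential branch
    else
      x = rtigauss(z, TRUNC);      // truncated inverse-Gaussian branch
    // squeeze via the alternating partial sums
    double s = a_coef(0, x);
    double y = unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return 0.25 * x;
      } else {
        s += a_coef(n, x);
        if (y > s) break; // reject, restart proposal
      }
    }
  }
}

// PG(b, c) for integer b >= 1
double rpg_int(int b, double c) {
  double s = 0.0;
  for (int k = 0; k < b; ++k) s += rpg1(c);
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_rpg(int n, int b, NumericVector c) {
  if (b < 1) stop("Polya-Gamma shape must be a positive integer");
  NumericVector out(n);
  int nc = c.size();
  for (int i = 0; i < n; ++i) {
    double ci = c[i % nc];
    if (!R_finite(ci)) stop("Polya-Gamma tilt must be finite");
    out[i] = rpg_int(b, ci);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Truncated standard normal on (a, b), tail-safe.  Strategy:
//  * untruncated or one virtually-unbounded side near the mode: naive retry;
//  * one-sided tails: Robert's shifted-exponential rejection;
//  * two-sided: normal retry when the interval holds enough mass, otherwise a
//    tilted-uniform rejection (exact, efficient for narrow deep-tail slabs) or
//    the one-sided tail sampler with an upper rejection for wide tail slabs.

static double tail_exp_rej(double a) { // sample N(0,1) | x > a, a > 0
  double lambda = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double x = a + exp_rand() / lambda;
    double d = x - lambda;
    if (unif_rand() <= std::exp(-0.5 * d * d)) return x;
  }
}

static double std_tnorm(double a, double b) {
  bool la = !R_finite(a), ub = !R_finite(b);
  if (la && ub) return norm_rand();
  if (ub) { // (a, Inf)
    if (a <= 0.45) {
      for (;;) { double x = norm_rand(); if (x > a) return x; }
    }
    return tail_exp_rej(a);
  }
  if (la) return -std_tnorm(-b, R_PosInf); // (-Inf, b) by symmetry
  // two-sided
  if (a >= b) stop("invalid truncation interval");
  if (b < 0.0) return -std_tnorm(-b, -a);
  if (a < 0.0) { // interval straddles the mode
    if (b - a > 2.0) { // wide: plain normal rejection accepts quickly
      for (;;) { double x = norm_rand(); if (x > a && x < b) return x; }
    }
    for (;;) { // narrow: uniform rejection, bound exp(-x^2/2) at the mode
      double x = a + (b - a) * unif_rand();
      if (unif_rand() <= std::exp(-0.5 * x * x)) return x;
    }
  }
  if (a < 0.45 && b - a > 1.5) { // near-mode, wide enough for normal retry
    for (;;) { double x = norm_rand(); if (x > a && x < b) return x; }
  }
  // both bounds in the upper tail
  if ((b - a) * a > 0.8) { // wide tail slab: one-sided sampler + upper cut
    for (;;) { double x = tail_exp_rej(a); if (x < b) return x; }
  }
  for (;;) { // narrow tail slab: tilted-uniform rejection
    double x = a + (b - a) * unif_rand();
    if (unif_rand() <= std::exp(0.5 * (a * a - x * x))) return x;
  }
}

double rtnorm1(double mean, double sd, double lower, double upper) {
  double a = (lower - mean) / sd, b = (upper - mean) / sd;
  return mean + sd * std_tnorm(a, b);
}

// [[Rcpp::export]]
NumericVector cpp_rtnorm(int n, NumericVector mean, NumericVector sd,
                         NumericVector lower, NumericVector upper) {
  NumericVector out(n);
  int nm = mean.size(), ns = sd.size(), nl = lower.size(), nu = upper.size();
  for (int i = 0; i < n; ++i) {
    double m = mean[i % nm], s = sd[i % ns];
    double lo = lower[i % nl], up = upper[i % nu];
    if (!(s > 0) || !R_finite(s)) stop("sd must be positive and finite");
    if (!(lo < up)) stop("lower bound must be strictly below upper bound");
    out[i] = rtnorm1(m, s, lo, up);
  }
  return out;
}
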