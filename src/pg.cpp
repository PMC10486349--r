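// Exact Polya-Gamma PG(1, z) sampling by Devroye's alternating-series
// method, used for the conjugate data augmentation of the multinomial
// logit likelihood. Draws use R's RNG so results are reproducible under
// set.seed().
#include <Rcpp.h>
using namespace Rcpp;

static const double TRUNC = 0.64;   // series truncation point

// n-th coefficient of the alternating series for the J*(1, .) density
static double a_coef(int n, double x) {
  double k = n + 0.5;
  if (x > TRUNC)
    return M_PI * k * std::exp(-k * k * M_PI * M_PI * x / 2.0);
  else
    return std::pow(2.0 / (M_PI * x), 1.5) * M_PI * k *
           std::exp(-2.0 * k * k / x);
}

// Inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, TRUNC]
static double rtigauss(double z) {
  double x = TRUNC + 1.0;
  double mu = 1.0 / z;
  if (mu > TRUNC) {
    // sample truncated inverse-chi-square and accept with the exp tilt
    double alpha = 0.0;
    while (unif_rand() > alpha) {
      double e1, e2;
      do {
        e1 = exp_rand();
        e2 = exp_rand();
      } while (e1 * e1 > 2.0 * e2 / TRUNC);
      x = TRUNC / ((1.0 + TRUNC * e1) * (1.0 + TRUNC * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    while (x > TRUNC) {
      double y = norm_rand();
      y = y * y;
      double muy = mu * y;
      // Michael-Schucany-Haas transform for IG(mu, 1)
      x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(muy * (4.0 + muy));
      if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

// P(exponential right tail) / total mass of the proposal mixture
static double mass_texpon(double z) {
  double K = M_PI * M_PI / 8.0 + z * z / 2.0;
  double b = std::sqrt(1.0 / TRUNC) * (TRUNC * z - 1.0);
  double a = -std::sqrt(1.0 / TRUNC) * (TRUNC * z + 1.0);
  double x0 = std::log(K) + K * TRUNC;
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// one draw from PG(1, z)
static double rpg1(double zin) {
  double z = std::fabs(zin) * 0.5;
  double K = M_PI * M_PI / 8.0 + z * z / 2.0;
  double p_exp = mass_texpon(z);
  while (true) {
    double x;
    if (unif_rand() < p_exp)
      x = TRUNC + exp_rand() / K;
    else
      x = rtigauss(z);
    // squeeze accept/reject on the alternating series
    double s = a_coef(0, x);
    double y = unif_rand() * s;
    int n = 0;
    while (true) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return x / 4.0;
      } else {
        s += a_coef(n, x);
        if (y > s) break;  // reject, retry
      }
    }
  }
}

//' Draw Polya-Gamma PG(1, z) variates
//'
//' One exact draw per element of `z`, via Devroye's alternating-series
//' rejection sampler. `PG(1, 0)` has mean 1/4; in general the mean is
//' `tanh(z/2) / (2 z)`.
//'
//' @param z Numeric vector of tilting parameters.
//' @return Numeric vector of PG(1, z) draws.
//' @export
// [[Rcpp::export]]
NumericVector rpolyagamma(NumericVector z) {
  R_xlen_t n = z.size();
  NumericVector out(n);
  GetRNGstate();
  for (R_xlen_t i = 0; i < n; ++i) out[i] = rpg1(z[i]);
  PutRNGstate();
  return out;
}
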