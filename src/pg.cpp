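#include <Rcpp.h>
using namespace Rcpp;

// Exact Polya-Gamma PG(1, z) sampling by the alternating-series
// accept-reject method of Devroye (2009) / Polson, Scott & Windle (2013).
// Uses R's RNG so draws follow set.seed().

static const double TRUNC = 0.64; // series crossover point

// piecewise coefficients a_n(x) of the Jacobi-theta density
static double a_coef(int n, double x) {
  double nph = n + 0.5;
  if (x > TRUNC)
    return M_PI * nph * std::exp(-nph * nph * M_PI * M_PI * x / 2.0);
  return M_PI * nph * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * nph * nph / x);
}

// inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, TRUNC);
// z >= 0, z = 0 means mu = Inf
static double rtigauss(double z) {
  double t = TRUNC, X;
  double mu = (z > 0.0) ? 1.0 / z : R_PosInf;
  if (mu > t) {
    // rejection from scaled inverse-chi-square proposal
    for (;;) {
      double E1 = R::exp_rand(), E2 = R::exp_rand();
      while (E1 * E1 > 2.0 * E2 / t) {
        E1 = R::exp_rand();
        E2 = R::exp_rand();
      }
      X = t / ((1.0 + t * E1) * (1.0 + t * E1));
      if (R::unif_rand() <= std::exp(-0.5 * z * z * X)) return X;
    }
  }
  // mu <= t: draw IG(mu, 1) until it lands in (0, t)
  for (;;) {
    double Y = R::norm_rand();
    Y = Y * Y;
    double muY = mu * Y;
    X = mu + 0.5 * mu * muY - 0.5 * mu * std::sqrt(4.0 * muY + muY * muY);
    if (R::unif_rand() > mu / (mu + X)) X = mu * mu / X;
    if (X < t) return X;
  }
}

static double rpg1(double zin) {
  double z = std::fabs(zin) * 0.5;
  double t = TRUNC;
  double K = M_PI * M_PI / 8.0 + z * z / 2.0;
  // mixing weights of the exponential tail vs truncated-IG head
  double p = (M_PI / (2.0 * K)) * std::exp(-K * t);
  // IG(1/z, 1) cdf at t, on log scale where it can underflow
  double sqt = std::sqrt(t);
  double term1 = R::pnorm((z * t - 1.0) / sqt, 0.0, 1.0, 1, 0);
  double term2 =
      std::exp(2.0 * z + R::pnorm(-(z * t + 1.0) / sqt, 0.0, 1.0, 1, 1));
  double q = 2.0 * std::exp(-z) * (term1 + term2);
  double ratio = p / (p + q);

  for (;;) {
    double X;
    if (R::unif_rand() < ratio)
      X = t + R::exp_rand() / K;
    else
      X = rtigauss(z);
    // alternating-series accept-reject on the Jacobi density
    double S = a_coef(0, X);
    double Y = R::unif_rand() * S;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        S -= a_coef(n, X);
        if (Y <= S) return X / 4.0;
      } else {
        S += a_coef(n, X);
        if (Y > S) break; // reject, redraw X
      }
    }
  }
}

//' @noRd
// [[Rcpp::export(rpg_cpp)]]
NumericVector rpg_cpp(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i]);
  return out;
}
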