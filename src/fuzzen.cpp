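#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fuzzy entropy of one series.
//
// Embeds the series in windows of length m and m+1 (N - m windows each),
// takes Chebyshev distances between all window pairs, maps each distance to
// a membership exp(-(d / r_eff)^n_exp), averages memberships excluding
// self-comparisons, and returns ln(phi_m) - ln(phi_{m+1}). With r
// interpreted relative (the default), r_eff = r * population SD of the
// series; the tolerance divides the distance inside the power, which is
// what makes the relative mode exactly amplitude-invariant.
static double phi_w(const std::vector<double>& x, int nseg, int w,
                    double r_eff, double n_exp) {
  long double acc = 0.0;
  for (int i = 0; i < nseg; ++i) {
    for (int j = i + 1; j < nseg; ++j) {
      double d = 0.0;
      for (int k = 0; k < w; ++k) {
        double diff = std::fabs(x[i + k] - x[j + k]);
        if (diff > d) d = diff;
      }
      acc += std::exp(-std::pow(d / r_eff, n_exp));
    }
  }
  // mean over ordered pairs (j != i) equals mean over unordered pairs
  return (double)(2.0L * acc / ((long double)nseg * (nseg - 1)));
}

static double fuzzen_one(const std::vector<double>& x, int m, double r,
                         double n_exp, bool relative) {
  int n = (int)x.size();
  if (n < m + 2) Rcpp::stop("fuzzy entropy needs length >= m + 2 (got %d, m = %d)", n, m);
  double mean = 0.0;
  for (double v : x) mean += v;
  mean /= n;
  double ss = 0.0;
  for (double v : x) ss += (v - mean) * (v - mean);
  double sd = std::sqrt(ss / n);
  if (sd == 0.0) return 0.0;  // constant series: all distances 0, limit is 0
  double r_eff = relative ? r * sd : r;
  int nseg = n - m;  // window counts matched across m and m+1
  double pm  = phi_w(x, nseg, m,     r_eff, n_exp);
  double pm1 = phi_w(x, nseg, m + 1, r_eff, n_exp);
  return std::log(pm) - std::log(pm1);
}

// [[Rcpp::export]]
double fuzzen_cpp(NumericVector x, int m, double r, double n_exp, bool relative) {
  std::vector<double> v(x.begin(), x.end());
  return fuzzen_one(v, m, r, n_exp, relative);
}

// Column-wise fuzzy entropy (columns are independent series).
// [[Rcpp::export]]
NumericVector fuzzen_cols_cpp(NumericMatrix X, int m, double r, double n_exp,
                              bool relative) {
  int nc = X.ncol(), nr = X.nrow();
  NumericVector out(nc);
  std::vector<double> v(nr);
  for (int c = 0; c < nc; ++c) {
    for (int i = 0; i < nr; ++i) v[i] = X(i, c);
    out[c] = fuzzen_one(v, m, r, n_exp, relative);
  }
  return out;
}
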