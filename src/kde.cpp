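#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Evaluate a Gaussian-kernel density estimate built on log-scale points.
// logp: training log-abundances; b: bandwidth (log units); q: query
// log-abundances. Returns the log of the KDE density on the LOG scale
// (no Jacobian; the caller subtracts the query log-abundance to convert
// to a density per abundance unit) and the KDE-smoothed cdf.
// The log-pdf is computed by a max-shifted log-sum-exp so it stays
// finite even for queries many bandwidths outside the training range.
// [[Rcpp::export]]
List kde_eval_cpp(NumericVector logp, double b, NumericVector q) {
  const int n = logp.size();
  const int m = q.size();
  NumericVector log_pdf(m), cdf(m);
  const double log_norm = -std::log((double)n) - std::log(b) -
                          0.5 * std::log(2.0 * M_PI);
  for (int i = 0; i < m; ++i) {
    double qi = q[i];
    double mx = -INFINITY;
    for (int j = 0; j < n; ++j) {
      double t = (qi - logp[j]) / b;
      double u = -0.5 * t * t;
      if (u > mx) mx = u;
    }
    double s = 0.0, cs = 0.0;
    for (int j = 0; j < n; ++j) {
      double t = (qi - logp[j]) / b;
      s += std::exp(-0.5 * t * t - mx);
      cs += R::pnorm(t, 0.0, 1.0, 1, 0);
    }
    log_pdf[i] = mx + std::log(s) + log_norm;
    cdf[i] = cs / n;
  }
  return List::create(_["log_pdf"] = log_pdf, _["cdf"] = cdf);
}
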