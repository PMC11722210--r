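#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Mass-action right-hand side for one cell.
// reac, net: (n_reactions x n_species) stoichiometry matrices stored
// column-major as in R; rates: resolved rate constants per reaction.
static inline void mass_action_deriv(const double* x,
                                     const double* reac,
                                     const double* net,
                                     const double* rates,
                                     int nr, int ns,
                                     double* dx) {
  for (int i = 0; i < ns; ++i) dx[i] = 0.0;
  for (int j = 0; j < nr; ++j) {
    double flux = rates[j];
    if (flux == 0.0) continue;
    for (int i = 0; i < ns; ++i) {
      double s = reac[j + (std::size_t)i * nr];
      if (s > 0.0) {
        if (s == 1.0) flux *= x[i];
        else if (s == 2.0) flux *= x[i] * x[i];
        else flux *= std::pow(x[i], s);
      }
    }
    if (flux == 0.0) continue;
    for (int i = 0; i < ns; ++i) {
      double nij = net[j + (std::size_t)i * nr];
      if (nij != 0.0) dx[i] += nij * flux;
    }
  }
}

// Dormand-Prince 5(4) coefficients.
static const double c2 = 1.0 / 5.0, c3 = 3.0 / 10.0, c4 = 4.0 / 5.0,
                    c5 = 8.0 / 9.0;
static const double a21 = 1.0 / 5.0;
static const double a31 = 3.0 / 40.0, a32 = 9.0 / 40.0;
static const double a41 = 44.0 / 45.0, a42 = -56.0 / 15.0, a43 = 32.0 / 9.0;
static const double a51 = 19372.0 / 6561.0, a52 = -25360.0 / 2187.0,
                    a53 = 64448.0 / 6561.0, a54 = -212.0 / 729.0;
static const double a61 = 9017.0 / 3168.0, a62 = -355.0 / 33.0,
                    a63 = 46732.0 / 5247.0, a64 = 49.0 / 176.0,
                    a65 = -5103.0 / 18656.0;
static const double b1 = 35.0 / 384.0, b3 = 500.0 / 1113.0,
                    b4 = 125.0 / 192.0, b5 = -2187.0 / 6784.0,
                    b6 = 11.0 / 84.0;
// 4th-order embedded weights.
static const double e1 = 5179.0 / 57600.0, e3 = 7571.0 / 16695.0,
                    e4 = 393.0 / 640.0, e5 = -92097.0 / 339200.0,
                    e6 = 187.0 / 2100.0, e7 = 1.0 / 40.0;

// Integrate a batch of cells under identical mass-action dynamics from
// time 0 to tend with an adaptive Dormand-Prince 5(4) scheme.
// Returns the evolved state matrix plus a per-cell status code:
// 0 = ok, 1 = max step count exceeded, 2 = step size underflow.
// [[Rcpp::export]]
List dopri_evolve_cpp(NumericMatrix x0, double tend,
                      NumericMatrix reac, NumericMatrix net,
                      NumericVector rates,
                      double rtol, double atol, int max_steps) {
  const int ncell = x0.nrow();
  const int ns = x0.ncol();
  const int nr = reac.nrow();

  NumericMatrix out(ncell, ns);
  IntegerVector status(ncell);

  if (tend == 0.0) {
    for (int c = 0; c < ncell; ++c)
      for (int i = 0; i < ns; ++i) out(c, i) = x0(c, i);
    return List::create(_["states"] = out, _["status"] = status);
  }

  const double* rp = &reac[0];
  const double* np = &net[0];
  const double* kp = &rates[0];

  std::vector<double> y(ns), ynew(ns), ytmp(ns), err(ns);
  std::vector<double> k1(ns), k2(ns), k3(ns), k4(ns), k5(ns), k6(ns), k7(ns);

  const double hmin_floor = tend * 1e-14;

  for (int c = 0; c < ncell; ++c) {
    for (int i = 0; i < ns; ++i) y[i] = x0(c, i);
    double t = 0.0;
    double h = tend * 1e-3;
    int steps = 0;
    int code = 0;
    bool have_k1 = false;

    while (t < tend) {
      if (++steps > max_steps) { code = 1; break; }
      if (h < hmin_floor) { code = 2; break; }
      if (t + h > tend) h = tend - t;

      if (!have_k1) {
        mass_action_deriv(y.data(), rp, np, kp, nr, ns, k1.data());
        have_k1 = true;
      }
      for (int i = 0; i < ns; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
      mass_action_deriv(ytmp.data(), rp, np, kp, nr, ns, k2.data());
      for (int i = 0; i < ns; ++i)
        ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
      mass_action_deriv(ytmp.data(), rp, np, kp, nr, ns, k3.data());
      for (int i = 0; i < ns; ++i)
        ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
      mass_action_deriv(ytmp.data(), rp, np, kp, nr, ns, k4.data());
      for (int i = 0; i < ns; ++i)
        ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                              a54 * k4[i]);
      mass_action_deriv(ytmp.data(), rp, np, kp, nr, ns, k5.data());
      for (int i = 0; i < ns; ++i)
        ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                              a64 * k4[i] + a65 * k5[i]);
      mass_action_deriv(ytmp.data(), rp, np, kp, nr, ns, k6.data());
      for (int i = 0; i < ns; ++i)
        ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                              b5 * k5[i] + b6 * k6[i]);
      mass_action_deriv(ynew.data(), rp, np, kp, nr, ns, k7.data());

      double errnorm = 0.0;
      for (int i = 0; i < ns; ++i) {
        double e5th = y[i] + h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                                  e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
        double sc = atol + rtol * std::max(std::fabs(y[i]),
                                           std::fabs(ynew[i]));
        double d = (ynew[i] - e5th) / sc;
        errnorm += d * d;
      }
      errnorm = std::sqrt(errnorm / ns);

      if (errnorm <= 1.0) {
        t += h;
        y.swap(ynew);
        k1.swap(k7);  // FSAL
        double fac = (errnorm == 0.0)
                         ? 5.0
                         : std::min(5.0, std::max(0.2, 0.9 * std::pow(errnorm, -0.2)));
        h *= fac;
      } else {
        double fac = std::max(0.2, 0.9 * std::pow(errnorm, -0.2));
        h *= fac;
        have_k1 = true;  // k1 still valid at (t, y)
      }
    }

    status[c] = code;
    for (int i = 0; i < ns; ++i) out(c, i) = y[i];
    if (code != 0) break;  // caller reports the offending cell
  }

  return List::create(_["states"] = out, _["status"] = status);
}
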