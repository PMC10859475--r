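#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Analytic central-compartment concentration for a zero-order infusion into a
// one- or two-compartment disposition model with first-order elimination.
//
// Two-compartment hybrid constants: alpha, beta are the roots of
//   s^2 - (k10 + k12 + k21) s + k10 k21 = 0,
// bolus unit response C(t) = (D/V1) [A e^{-alpha t} + B e^{-beta t}] with
//   A = (alpha - k21)/(alpha - beta), B = (k21 - beta)/(alpha - beta).
// The infusion solution is the convolution with a rate-R0 pulse of length dur.
// ---------------------------------------------------------------------------

static inline double conc_single(double t, double start, double amt, double dur,
                                 double CL, double V1, double Q, double V2,
                                 int ncmt, bool *bad) {
  double el = t - start;
  if (el <= 0.0) return 0.0;
  double R0 = amt / dur;
  double k10 = CL / V1;
  if (ncmt == 1) {
    if (el <= dur)
      return R0 / CL * (1.0 - std::exp(-k10 * el));
    return R0 / CL * (1.0 - std::exp(-k10 * dur)) * std::exp(-k10 * (el - dur));
  }
  double k12 = Q / V1, k21 = Q / V2;
  double s = k10 + k12 + k21;
  double disc = s * s - 4.0 * k10 * k21;
  if (disc < 0.0) disc = 0.0;
  double root = std::sqrt(disc);
  double alpha = 0.5 * (s + root);
  double beta  = 0.5 * (s - root);
  if ((alpha - beta) <= 1e-10 * alpha) {  // physiologically precluded here
    if (bad) *bad = true;
    return NA_REAL;
  }
  double A = (alpha - k21) / (alpha - beta);
  double B = (k21 - beta) / (alpha - beta);
  if (el <= dur)
    return (R0 / V1) * (A * (1.0 - std::exp(-alpha * el)) / alpha +
                        B * (1.0 - std::exp(-beta  * el)) / beta);
  double tp = el - dur;
  return (R0 / V1) * (A * (1.0 - std::exp(-alpha * dur)) * std::exp(-alpha * tp) / alpha +
                      B * (1.0 - std::exp(-beta  * dur)) * std::exp(-beta  * tp) / beta);
}

// [[Rcpp::export]]
NumericVector cpp_conc(NumericVector t, NumericVector dose_start,
                       NumericVector dose_amt, NumericVector dose_dur,
                       double CL, double V1, double Q, double V2, int ncmt) {
  int nt = t.size(), nd = dose_start.size();
  NumericVector out(nt);
  bool bad = false;
  for (int i = 0; i < nt; ++i) {
    double c = 0.0;
    for (int d = 0; d < nd; ++d)
      c += conc_single(t[i], dose_start[d], dose_amt[d], dose_dur[d],
                       CL, V1, Q, V2, ncmt, &bad);
    out[i] = c;
  }
  if (bad)
    stop("degenerate two-compartment roots (alpha ~ beta within 1e-10 relative)");
  return out;
}

// ---------------------------------------------------------------------------
// FOCE-type (Laplace-at-the-conditional-mode, with interaction) objective.
//
// Per subject, the conditional -2 log-likelihood is
//   g(eta) = sum_j [ ln(2 pi var_j) + (y_j - f_j)^2 / var_j ]
//          + eta' Omega^{-1} eta + ln det(2 pi Omega),
// with var_j = sig2_add + sig2_prop * f_j^2 evaluated at the individual
// prediction (the "interaction"). The marginal contribution is approximated
// by Laplace at the mode eta-hat:
//   OFV_i = g(eta-hat) - k ln(2 pi) + ln det G,
//   G = J' W J + Omega^{-1}  (Gauss-Newton curvature, W = 1/var).
// The inner mode search is a damped Newton with the same G.
// ---------------------------------------------------------------------------

static void predict_subject(const double *ot, int nobs,
                            const double *ds, const double *da, const double *dd,
                            int ndose, const double *P, int ncmt,
                            double *f, bool *bad) {
  for (int j = 0; j < nobs; ++j) {
    double c = 0.0;
    for (int d = 0; d < ndose; ++d)
      c += conc_single(ot[j], ds[d], da[d], dd[d], P[0], P[1], P[2], P[3],
                       ncmt, bad);
    f[j] = c;
  }
}

// solve A x = b for small k, A overwritten; returns log|det A| or NA if singular
static double solve_small(int k, std::vector<double> &A, std::vector<double> &b,
                          bool *ok) {
  double logdet = 0.0;
  for (int c = 0; c < k; ++c) {
    int piv = c;
    for (int r = c + 1; r < k; ++r)
      if (std::fabs(A[r * k + c]) > std::fabs(A[piv * k + c])) piv = r;
    if (std::fabs(A[piv * k + c]) < 1e-300) { *ok = false; return NA_REAL; }
    if (piv != c) {
      for (int cc = 0; cc < k; ++cc) std::swap(A[c * k + cc], A[piv * k + cc]);
      std::swap(b[c], b[piv]);
    }
    logdet += std::log(std::fabs(A[c * k + c]));
    for (int r = c + 1; r < k; ++r) {
      double m = A[r * k + c] / A[c * k + c];
      for (int cc = c; cc < k; ++cc) A[r * k + cc] -= m * A[c * k + cc];
      b[r] -= m * b[c];
    }
  }
  for (int c = k - 1; c >= 0; --c) {
    double s = b[c];
    for (int cc = c + 1; cc < k; ++cc) s -= A[c * k + cc] * b[cc];
    b[c] = s / A[c * k + c];
  }
  *ok = true;
  return logdet;
}

static const double LN2PI = 1.8378770664093453;
static const double F_FLOOR = 1e-10;  // prediction floor under proportional error

// [[Rcpp::export]]
List cpp_foce(IntegerVector obs_ptr, NumericVector obs_time, NumericVector obs_dv,
              IntegerVector dose_ptr, NumericVector dose_start,
              NumericVector dose_amt, NumericVector dose_dur,
              NumericVector theta_pop, NumericVector theta_cov,
              IntegerVector eff_param, IntegerVector eff_form, NumericMatrix eff_x,
              IntegerVector eta_param, NumericVector omega2,
              double sig2_add, double sig2_prop,
              int ncmt, double inner_tol, int max_inner, bool want_eta) {
  int n_subj = obs_ptr.size() - 1;
  int n_eff = eff_param.size();
  int k = eta_param.size();

  NumericVector ofv_i(n_subj);
  NumericMatrix eta_out(k, want_eta ? n_subj : 0);
  bool all_ok = true;
  double total = 0.0;

  std::vector<double> f, f0, J;
  std::vector<double> eta(k), eta_try(k), grad(k), A(k * k), rhs(k);

  for (int i = 0; i < n_subj; ++i) {
    int o0 = obs_ptr[i], o1 = obs_ptr[i + 1], nobs = o1 - o0;
    int d0 = dose_ptr[i], d1 = dose_ptr[i + 1], ndose = d1 - d0;
    const double *ot = &obs_time[0] + o0;
    const double *dv = &obs_dv[0] + o0;
    const double *ds = ndose ? &dose_start[0] + d0 : NULL;
    const double *da = ndose ? &dose_amt[0] + d0 : NULL;
    const double *dd = ndose ? &dose_dur[0] + d0 : NULL;

    // typical parameters: (theta_pop + sum linear) * prod multiplicative
    double base[4], add[4] = {0, 0, 0, 0}, mult[4] = {1, 1, 1, 1};
    for (int p = 0; p < 4; ++p) base[p] = theta_pop[p];
    for (int e = 0; e < n_eff; ++e) {
      int p = eff_param[e];
      double x = eff_x(i, e), th = theta_cov[e];
      switch (eff_form[e]) {
        case 0: add[p]  += th * x;            break;  // linear
        case 1: mult[p] *= std::exp(th * x);  break;  // exponential
        case 2: mult[p] *= std::pow(x, th);   break;  // power (x > 0)
        case 3: mult[p] *= std::pow(th, x);   break;  // categorical (th > 0)
      }
    }
    double typ[4];
    bool bad_typ = false;
    int npar_used = (ncmt == 1) ? 2 : 4;
    for (int p = 0; p < 4; ++p) {
      typ[p] = (base[p] + add[p]) * mult[p];
      if (p < npar_used && (!std::isfinite(typ[p]) || typ[p] <= 0.0))
        bad_typ = true;
    }
    if (bad_typ) { all_ok = false; ofv_i[i] = NA_REAL; continue; }

    if (nobs == 0) { ofv_i[i] = 0.0; continue; }

    f.resize(nobs); f0.resize(nobs); J.resize((size_t)nobs * std::max(k, 1));

    bool bad = false;
    // g at a given eta; fills fbuf
    auto g_of = [&](const double *et, double *fbuf) -> double {
      double P[4];
      for (int p = 0; p < 4; ++p) P[p] = typ[p];
      for (int m = 0; m < k; ++m) P[eta_param[m]] *= std::exp(et[m]);
      predict_subject(ot, nobs, ds, da, dd, ndose, P, ncmt, fbuf, &bad);
      double g = 0.0;
      for (int j = 0; j < nobs; ++j) {
        double fj = fbuf[j];
        if (!std::isfinite(fj)) { bad = true; return NA_REAL; }
        double fv = (sig2_prop > 0.0 && fj < F_FLOOR) ? F_FLOOR : fj;
        double var = sig2_add + sig2_prop * fv * fv;
        if (var <= 0.0) { bad = true; return NA_REAL; }
        double r = dv[j] - fj;
        g += std::log(2.0 * M_PI * var) + r * r / var;
      }
      for (int m = 0; m < k; ++m)
        g += et[m] * et[m] / omega2[m] + std::log(2.0 * M_PI * omega2[m]);
      return g;
    };

    for (int m = 0; m < k; ++m) eta[m] = 0.0;
    double g = g_of(eta.data(), f0.data());
    if (bad || !std::isfinite(g)) { all_ok = false; ofv_i[i] = NA_REAL; continue; }

    double logdetG = 0.0;
    bool have_G = false;

    if (k > 0) {
      const double h = 1e-5;
      for (int it = 0; it < max_inner; ++it) {
        // finite-difference Jacobian df/deta at current eta
        for (int m = 0; m < k; ++m) {
          for (int mm = 0; mm < k; ++mm) eta_try[mm] = eta[mm];
          eta_try[m] += h;
          g_of(eta_try.data(), f.data());
          if (bad) break;
          for (int j = 0; j < nobs; ++j)
            J[(size_t)j * k + m] = (f[j] - f0[j]) / h;
        }
        if (bad) break;

        // gradient and Gauss-Newton curvature of g
        for (int m = 0; m < k; ++m) grad[m] = 2.0 * eta[m] / omega2[m];
        for (int m = 0; m < k; ++m)
          for (int l = 0; l < k; ++l)
            A[m * k + l] = (m == l) ? 2.0 / omega2[m] : 0.0;
        for (int j = 0; j < nobs; ++j) {
          double fj = f0[j];
          double fv = (sig2_prop > 0.0 && fj < F_FLOOR) ? F_FLOOR : fj;
          double var = sig2_add + sig2_prop * fv * fv;
          double r = dv[j] - fj;
          double dvar_df = 2.0 * sig2_prop * fv;
          for (int m = 0; m < k; ++m) {
            double Jm = J[(size_t)j * k + m];
            double dvar = dvar_df * Jm;
            grad[m] += dvar / var - 2.0 * r * Jm / var - r * r * dvar / (var * var);
            for (int l = 0; l < k; ++l)
              A[m * k + l] += 2.0 * J[(size_t)j * k + m] * J[(size_t)j * k + l] / var;
          }
        }
        for (int m = 0; m < k; ++m) rhs[m] = -grad[m];
        std::vector<double> Awork(A);
        bool ok = false;
        double ld = solve_small(k, Awork, rhs, &ok);
        if (!ok) { bad = true; break; }
        logdetG = ld - k * std::log(2.0);  // det(G) = det(A/2)
        have_G = true;

        // damped Newton step
        double step = 1.0, g_new = g;
        bool improved = false;
        for (int ls = 0; ls < 12; ++ls) {
          for (int m = 0; m < k; ++m) {
            double v = eta[m] + step * rhs[m];
            if (v > 8.0) v = 8.0;
            if (v < -8.0) v = -8.0;
            eta_try[m] = v;
          }
          g_new = g_of(eta_try.data(), f.data());
          if (!bad && std::isfinite(g_new) && g_new <= g) { improved = true; break; }
          bad = false;
          step *= 0.5;
        }
        if (!improved) break;  // at (numerical) mode
        double dec = g - g_new;
        for (int m = 0; m < k; ++m) eta[m] = eta_try[m];
        std::copy(f.begin(), f.end(), f0.begin());
        g = g_new;
        if (dec < inner_tol) break;
      }
      if (bad) { all_ok = false; ofv_i[i] = NA_REAL; continue; }

      // curvature at the mode (recompute if the last loop exited before forming G)
      {
        const double h = 1e-5;
        for (int m = 0; m < k; ++m) {
          for (int mm = 0; mm < k; ++mm) eta_try[mm] = eta[mm];
          eta_try[m] += h;
          g_of(eta_try.data(), f.data());
          if (bad) break;
          for (int j = 0; j < nobs; ++j)
            J[(size_t)j * k + m] = (f[j] - f0[j]) / h;
        }
        if (bad) { all_ok = false; ofv_i[i] = NA_REAL; continue; }
        for (int m = 0; m < k; ++m)
          for (int l = 0; l < k; ++l)
            A[m * k + l] = (m == l) ? 1.0 / omega2[m] : 0.0;
        for (int j = 0; j < nobs; ++j) {
          double fj = f0[j];
          double fv = (sig2_prop > 0.0 && fj < F_FLOOR) ? F_FLOOR : fj;
          double var = sig2_add + sig2_prop * fv * fv;
          for (int m = 0; m < k; ++m)
            for (int l = 0; l < k; ++l)
              A[m * k + l] += J[(size_t)j * k + m] * J[(size_t)j * k + l] / var;
        }
        std::vector<double> rhs0(k, 0.0), Awork(A);
        bool ok = false;
        logdetG = solve_small(k, Awork, rhs0, &ok);
        if (!ok) { all_ok = false; ofv_i[i] = NA_REAL; continue; }
        have_G = true;
      }
      ofv_i[i] = g - k * LN2PI + logdetG;
    } else {
      ofv_i[i] = g;  // no random effects: plain -2 log-likelihood
    }
    (void)have_G;
    if (want_eta)
      for (int m = 0; m < k; ++m) eta_out(m, i) = eta[m];
    total += ofv_i[i];
  }

  return List::create(_["ofv"] = all_ok ? total : NA_REAL,
                      _["ofv_i"] = ofv_i,
                      _["eta"] = eta_out,
                      _["ok"] = all_ok);
}
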