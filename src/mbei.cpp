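#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Model-based expression index fit: for one probeset, y_ij ~ theta_i * phi_j
// (i = array, j = probe), sum_j phi_j^2 = J over retained probes.
// Alternating least squares with iterative outlier exclusion (at most
// max_rounds cells removed, one per refit round), then whole probes/arrays
// with more than half their cells masked are dropped.

namespace {

double median_of(std::vector<double> v) {
  if (v.empty()) return NA_REAL;
  size_t m = v.size() / 2;
  std::nth_element(v.begin(), v.begin() + m, v.end());
  double hi = v[m];
  if (v.size() % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + m);
    return (lo + hi) / 2.0;
  }
  return hi;
}

struct FitResult {
  std::vector<double> theta, se, phi;
  std::vector<int> mask;   // J x I, column-major in i: mask[j + J*i], 1 = excluded
  bool unreliable;
};

// Alternating least squares on retained cells. y is J x I (probe x array),
// stored column-major: y[j + J*i].
void als_fit(const std::vector<double>& y, const std::vector<int>& mask,
             int J, int I, std::vector<double>& theta, std::vector<double>& phi,
             int max_iter = 100) {
  std::vector<bool> probe_active(J, false), array_active(I, false);
  for (int i = 0; i < I; ++i)
    for (int j = 0; j < J; ++j)
      if (!mask[j + J * i]) { probe_active[j] = true; array_active[i] = true; }

  int Jr = 0;
  for (int j = 0; j < J; ++j) if (probe_active[j]) ++Jr;

  // init: phi = 1 on active probes, theta = per-array mean of retained cells
  for (int j = 0; j < J; ++j) phi[j] = probe_active[j] ? 1.0 : NA_REAL;
  for (int i = 0; i < I; ++i) {
    double s = 0; int n = 0;
    for (int j = 0; j < J; ++j)
      if (!mask[j + J * i]) { s += y[j + J * i]; ++n; }
    theta[i] = (n > 0) ? s / n : NA_REAL;
  }
  if (Jr == 0) return;

  for (int it = 0; it < max_iter; ++it) {
    double delta = 0.0;
    for (int i = 0; i < I; ++i) {
      if (!array_active[i]) { theta[i] = NA_REAL; continue; }
      double num = 0, den = 0;
      for (int j = 0; j < J; ++j)
        if (!mask[j + J * i]) { num += y[j + J * i] * phi[j]; den += phi[j] * phi[j]; }
      double t = (den > 0) ? num / den : NA_REAL;
      if (!ISNA(t) && !ISNA(theta[i]))
        delta = std::max(delta, std::fabs(t - theta[i]) / (std::fabs(theta[i]) + 1.0));
      theta[i] = t;
    }
    for (int j = 0; j < J; ++j) {
      if (!probe_active[j]) { phi[j] = NA_REAL; continue; }
      double num = 0, den = 0;
      for (int i = 0; i < I; ++i)
        if (!mask[j + J * i] && !ISNA(theta[i])) {
          num += y[j + J * i] * theta[i]; den += theta[i] * theta[i];
        }
      phi[j] = (den > 0) ? num / den : 0.0;
    }
    // identifiability: sum phi^2 = Jr over retained probes
    double s2 = 0;
    for (int j = 0; j < J; ++j) if (probe_active[j]) s2 += phi[j] * phi[j];
    if (s2 > 0) {
      double c = std::sqrt(s2 / Jr);
      for (int j = 0; j < J; ++j) if (probe_active[j]) phi[j] /= c;
      for (int i = 0; i < I; ++i) if (!ISNA(theta[i])) theta[i] *= c;
    }
    if (delta < 1e-12 && it > 0) break;
  }
}

// Total squared relative residual of the ALS fit on a given mask;
// measurement noise scales with the fitted magnitude, so residuals are
// judged relative to max(|theta*phi|, floor).
double rel_rss(const std::vector<double>& y, const std::vector<int>& mask,
               int J, int I, double fit_floor) {
  std::vector<double> theta(I), phi(J);
  als_fit(y, mask, J, I, theta, phi, 25);
  double s = 0;
  for (int i = 0; i < I; ++i) {
    if (ISNA(theta[i])) continue;
    for (int j = 0; j < J; ++j)
      if (!mask[j + J * i] && !ISNA(phi[j])) {
        double fit = theta[i] * phi[j];
        double r = (y[j + J * i] - fit) / std::max(std::fabs(fit), fit_floor);
        s += r * r;
      }
  }
  return s;
}

// Worst cell by relative residual against a leverage-robust per-array
// index (the median over probes of y/phi_det), provided it exceeds
// outlier_z robust standard deviations (or, when the fit is essentially
// exact, a small relative tolerance).  Returns cell index or -1.
int worst_cell_view(const std::vector<double>& y, const std::vector<int>& mask,
                    int J, int I, const std::vector<double>& phi_det,
                    double outlier_z, double fit_floor) {
  std::vector<double> theta_rob(I, NA_REAL);
  for (int i = 0; i < I; ++i) {
    std::vector<double> ratios;
    for (int j = 0; j < J; ++j)
      if (!mask[j + J * i] && !ISNA(phi_det[j]) &&
          std::fabs(phi_det[j]) > 1e-12)
        ratios.push_back(y[j + J * i] / phi_det[j]);
    theta_rob[i] = median_of(ratios);
  }
  std::vector<double> absr;
  std::vector<int> cell;
  for (int i = 0; i < I; ++i) {
    if (ISNA(theta_rob[i])) continue;
    for (int j = 0; j < J; ++j)
      if (!mask[j + J * i] && !ISNA(phi_det[j])) {
        double fit = theta_rob[i] * phi_det[j];
        double den = std::max(std::fabs(fit), fit_floor);
        absr.push_back(std::fabs(y[j + J * i] - fit) / den);
        cell.push_back(j + J * i);
      }
  }
  if (absr.empty()) return -1;
  double sig = 1.4826 * median_of(absr);
  double thr = (sig > 1e-10) ? outlier_z * sig : 1e-8;
  double worst = thr; int worst_cell = -1;
  for (size_t k = 0; k < absr.size(); ++k)
    if (absr[k] > worst) { worst = absr[k]; worst_cell = cell[k]; }
  return worst_cell;
}

FitResult fit_one(const std::vector<double>& y, int J, int I,
                  double outlier_z, int max_rounds, double theta_floor) {
  FitResult res;
  res.theta.assign(I, NA_REAL);
  res.se.assign(I, NA_REAL);
  res.phi.assign(J, NA_REAL);
  res.mask.assign(J * I, 0);
  res.unreliable = false;

  double ymax = 0;
  for (size_t k = 0; k < y.size(); ++k) ymax = std::max(ymax, std::fabs(y[k]));
  double fit_floor = std::max(theta_floor, 1e-8 * std::max(ymax, 1.0));

  std::vector<double> theta(I), phi(J);
  for (int round = 0; ; ++round) {
    int n_ret = 0;
    for (size_t k = 0; k < res.mask.size(); ++k) if (!res.mask[k]) ++n_ret;
    if (n_ret == 0) { res.unreliable = true; return res; }

    als_fit(y, res.mask, J, I, theta, phi);
    if (round >= max_rounds) break;

    // A least-squares rank-1 fit can absorb a gross outlier into either
    // the array index or the probe-sensitivity vector, masking it from
    // its own residuals.  Candidate outliers are therefore taken from two
    // views -- residuals against the robust array index under the fitted
    // sensitivities, and under unit sensitivities -- and the candidate
    // whose trial deletion leaves the better relative fit is excluded
    // (one cell per round).
    // the fitted-sensitivity view gates the exclusion: when it is clean,
    // the unit view's disagreements are probe-sensitivity spread, not
    // outliers
    int cand_a = worst_cell_view(y, res.mask, J, I, phi, outlier_z, fit_floor);
    if (cand_a < 0) break;
    std::vector<double> ones(J, 1.0);
    int cand_b = worst_cell_view(y, res.mask, J, I, ones, outlier_z, fit_floor);
    int chosen = -1;
    if (cand_b < 0 || cand_a == cand_b) chosen = cand_a;
    else {
      std::vector<int> ma(res.mask), mb(res.mask);
      ma[cand_a] = 1; mb[cand_b] = 1;
      chosen = (rel_rss(y, ma, J, I, fit_floor) <=
                rel_rss(y, mb, J, I, fit_floor)) ? cand_a : cand_b;
    }
    res.mask[chosen] = 1;

    // exclude whole probes/arrays with more than half their cells masked
    std::vector<int> col_n(I, 0), row_n(J, 0);
    for (int i = 0; i < I; ++i)
      for (int j = 0; j < J; ++j)
        if (res.mask[j + J * i]) { ++col_n[i]; ++row_n[j]; }
    for (int j = 0; j < J; ++j)
      if (row_n[j] * 2 > I)
        for (int i = 0; i < I; ++i) res.mask[j + J * i] = 1;
    for (int i = 0; i < I; ++i)
      if (col_n[i] * 2 > J)
        for (int j = 0; j < J; ++j) res.mask[j + J * i] = 1;
  }

  // Standard errors from per-array residual variance: measurement noise
  // scales with intensity, so a probeset-wide variance would export the
  // bright arrays' scatter into the dim arrays' standard errors.
  int n_ret = 0;
  std::vector<bool> arr_act(I, false);
  for (int i = 0; i < I; ++i) {
    if (ISNA(theta[i])) continue;
    for (int j = 0; j < J; ++j)
      if (!res.mask[j + J * i] && !ISNA(phi[j])) { ++n_ret; arr_act[i] = true; }
  }
  int I_act = 0;
  for (int i = 0; i < I; ++i) if (arr_act[i]) ++I_act;
  if (n_ret == 0 || I_act == 0) { res.unreliable = true; return res; }

  for (int i = 0; i < I; ++i) {
    if (ISNA(theta[i]) || !arr_act[i]) {
      res.theta[i] = NA_REAL; res.se[i] = NA_REAL; continue;
    }
    double sphi2 = 0, rss_i = 0;
    int n_i = 0;
    for (int j = 0; j < J; ++j)
      if (!res.mask[j + J * i] && !ISNA(phi[j])) {
        double r = y[j + J * i] - theta[i] * phi[j];
        rss_i += r * r; sphi2 += phi[j] * phi[j]; ++n_i;
      }
    double sigma_i = (n_i >= 2) ? std::sqrt(rss_i / (n_i - 1)) : 0.0;
    if (rss_i < 1e-18) sigma_i = 0.0;
    res.theta[i] = std::max(theta[i], theta_floor);
    res.se[i] = (sphi2 > 0) ? sigma_i / std::sqrt(sphi2) : NA_REAL;
  }
  for (int j = 0; j < J; ++j) res.phi[j] = phi[j];
  return res;
}

} // namespace

// [[Rcpp::export]]
List mbei_fit_cpp(NumericMatrix y, IntegerVector set_sizes,
                  double outlier_z = 3.0, int max_rounds = 5,
                  double theta_floor = 0.0) {
  const int I = y.ncol();
  const int n_sets = set_sizes.size();
  NumericMatrix theta(n_sets, I), se(n_sets, I);
  NumericVector phi(y.nrow());
  IntegerMatrix mask(y.nrow(), I);
  LogicalVector unreliable(n_sets);

  int row0 = 0;
  for (int s = 0; s < n_sets; ++s) {
    const int J = set_sizes[s];
    std::vector<double> ys(J * I);
    for (int i = 0; i < I; ++i)
      for (int j = 0; j < J; ++j)
        ys[j + J * i] = y(row0 + j, i);
    FitResult r = fit_one(ys, J, I, outlier_z, max_rounds, theta_floor);
    for (int i = 0; i < I; ++i) {
      theta(s, i) = r.theta[i];
      se(s, i) = r.se[i];
      for (int j = 0; j < J; ++j) mask(row0 + j, i) = r.mask[j + J * i];
    }
    for (int j = 0; j < J; ++j) phi[row0 + j] = r.phi[j];
    unreliable[s] = r.unreliable;
    row0 += J;
  }
  return List::create(_["theta"] = theta, _["se"] = se, _["phi"] = phi,
                      _["mask"] = mask, _["unreliable"] = unreliable);
}
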