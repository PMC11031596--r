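#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Zero-phase (forward-backward) IIR filtering of matrix columns with a
// cascade of second-order sections. Mirrors the standard sosfiltfilt
// procedure: odd-reflection padding at both ends, per-section steady-state
// initial conditions scaled by the first sample, one forward and one
// backward pass. sos is [n_sections x 6] rows (b0, b1, b2, 1, a1, a2).

static void sos_pass(const std::vector<double>& b0, const std::vector<double>& b1,
                     const std::vector<double>& b2, const std::vector<double>& a1,
                     const std::vector<double>& a2, const std::vector<double>& zi1,
                     const std::vector<double>& zi2, std::vector<double>& x) {
  const int ns = (int)b0.size();
  const int n = (int)x.size();
  for (int s = 0; s < ns; s++) {
    double z1 = zi1[s] * x[0];
    double z2 = zi2[s] * x[0];
    const double B0 = b0[s], B1 = b1[s], B2 = b2[s], A1 = a1[s], A2 = a2[s];
    for (int i = 0; i < n; i++) {
      double xi = x[i];
      double yi = B0 * xi + z1;
      z1 = B1 * xi - A1 * yi + z2;
      z2 = B2 * xi - A2 * yi;
      x[i] = yi;
    }
  }
}

// Peak absolute amplitude per trial over selected channels and samples.
// data is a [trials x channels x samples] array.
// [[Rcpp::export]]
NumericVector trial_peak_abs(NumericVector data, IntegerVector dims,
                             IntegerVector chan_idx, LogicalVector samp_keep) {
  const int n = dims[0], C = dims[1], S = dims[2];
  const double* d = data.begin();
  NumericVector peak(n, 0.0);
  for (int s = 0; s < S; s++) {
    if (!samp_keep[s]) continue;
    for (int ci = 0; ci < chan_idx.size(); ci++) {
      const int c = chan_idx[ci] - 1;
      const double* col = d + (R_xlen_t)n * (c + (R_xlen_t)C * s);
      for (int i = 0; i < n; i++) {
        double v = std::abs(col[i]);
        if (v > peak[i]) peak[i] = v;
      }
    }
  }
  return peak;
}

// [[Rcpp::export]]
NumericMatrix sosfiltfilt_mat(NumericMatrix sos, NumericMatrix x, int padlen) {
  const int ns = sos.nrow();
  const int n = x.nrow(), nc = x.ncol();
  if (padlen >= n) stop("padlen must be smaller than the signal length");
  std::vector<double> b0(ns), b1(ns), b2(ns), a1(ns), a2(ns), zi1(ns), zi2(ns);
  for (int s = 0; s < ns; s++) {
    b0[s] = sos(s, 0); b1[s] = sos(s, 1); b2[s] = sos(s, 2);
    a1[s] = sos(s, 4); a2[s] = sos(s, 5);
    // steady-state response to a unit constant input (lfilter_zi)
    double den = 1.0 + a1[s] + a2[s];
    double S = (den != 0.0) ? (b0[s] + b1[s] + b2[s]) / den : 0.0;
    zi1[s] = (b1[s] + b2[s]) - (a1[s] + a2[s]) * S;
    zi2[s] = b2[s] - a2[s] * S;
  }
  NumericMatrix out(n, nc);
  const int next = n + 2 * padlen;
  std::vector<double> ext(next);
  for (int j = 0; j < nc; j++) {
    const double* xc = &x(0, j);
    for (int i = 0; i < padlen; i++) ext[i] = 2.0 * xc[0] - xc[padlen - i];
    for (int i = 0; i < n; i++) ext[padlen + i] = xc[i];
    for (int i = 0; i < padlen; i++) ext[padlen + n + i] = 2.0 * xc[n - 1] - xc[n - 2 - i];
    sos_pass(b0, b1, b2, a1, a2, zi1, zi2, ext);
    std::reverse(ext.begin(), ext.end());
    sos_pass(b0, b1, b2, a1, a2, zi1, zi2, ext);
    std::reverse(ext.begin(), ext.end());
    for (int i = 0; i < n; i++) out(i, j) = ext[padlen + i];
  }
  return out;
}
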