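#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Levinson-Durbin recursion: autocorrelation r[0..p] -> LPC coefficients
// a[1..p] of the prediction polynomial A(z) = 1 + a1 z^-1 + ... + ap z^-p.
static bool levinson(const arma::vec& r, int p, arma::vec& a) {
  if (r(0) <= 0.0) return false;
  double err = r(0);
  a.zeros(p);
  arma::vec prev(p);
  for (int i = 1; i <= p; ++i) {
    double acc = r(i);
    for (int j = 1; j < i; ++j) acc += a(j - 1) * r(i - j);
    double k = -acc / err;
    prev = a;
    a(i - 1) = k;
    for (int j = 1; j < i; ++j) a(j - 1) = prev(j - 1) + k * prev(i - j - 1);
    err *= (1.0 - k * k);
    if (err <= 0.0) return false;
  }
  return true;
}

// Formant frequencies from the roots of the LPC polynomial, one frame per
// column. Roots with positive imaginary part, bandwidth < max_bw and
// frequency in [fmin, fmax] qualify; lowest three returned, zero-filled.
// Degenerate frames (zero autocorrelation, unstable recursion) give zeros.
// [[Rcpp::export]]
NumericMatrix cpp_formants(NumericMatrix frames, int order, double sr,
                           double max_bw, double fmin, double fmax) {
  const int n = frames.nrow(), nf = frames.ncol();
  if (order < 2 || order >= n) stop("lpc_order must be in [2, frame_len)");
  NumericMatrix out(3, nf);
  arma::vec r(order + 1), a;
  arma::vec poly(order + 1);
  for (int f = 0; f < nf; ++f) {
    NumericMatrix::Column col = frames(_, f);
    for (int lag = 0; lag <= order; ++lag) {
      double s = 0.0;
      for (int t = lag; t < n; ++t) s += col[t] * col[t - lag];
      r(lag) = s;
    }
    if (!levinson(r, order, a)) continue;
    poly(0) = 1.0;
    for (int j = 0; j < order; ++j) poly(j + 1) = a(j);
    arma::cx_vec rts;
    if (!arma::roots(rts, poly)) continue;
    std::vector<double> freqs;
    for (arma::uword k = 0; k < rts.n_elem; ++k) {
      if (rts(k).imag() <= 0.0) continue;
      double mag = std::abs(rts(k));
      if (mag <= 0.0 || mag >= 1.0) continue;
      double freq = std::atan2(rts(k).imag(), rts(k).real()) * sr / (2.0 * M_PI);
      double bw = -std::log(mag) * sr / M_PI;
      if (bw < max_bw && freq >= fmin && freq <= fmax) freqs.push_back(freq);
    }
    std::sort(freqs.begin(), freqs.end());
    for (int k = 0; k < 3 && k < (int)freqs.size(); ++k) out(k, f) = freqs[k];
  }
  return out;
}

// Soft-margin SVM dual via sequential minimal optimization on a precomputed
// kernel matrix. Deterministic: first index by scan order, partner by
// maximal |E_i - E_j|. Labels in {-1, +1}. Cvec holds the per-sample box
// constraint (class weighting multiplies the penalty per class).
// [[Rcpp::export]]
List cpp_smo(NumericMatrix K, NumericVector y, NumericVector Cvec, double tol,
             int max_passes) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n || Cvec.size() != n)
    stop("kernel/label size mismatch");
  std::vector<double> alpha(n, 0.0), E(n);
  double b = 0.0;
  auto fx = [&](int i) {
    double s = b;
    for (int j = 0; j < n; ++j)
      if (alpha[j] > 0.0) s += alpha[j] * y[j] * K(j, i);
    return s;
  };
  for (int i = 0; i < n; ++i) E[i] = fx(i) - y[i];
  int pass = 0;
  while (pass < max_passes) {
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      double ri = E[i] * y[i];
      if (!((ri < -tol && alpha[i] < Cvec[i]) || (ri > tol && alpha[i] > 0.0)))
        continue;
      int j = -1;
      double best = -1.0;
      for (int t = 0; t < n; ++t) {
        if (t == i) continue;
        double d = std::fabs(E[i] - E[t]);
        if (d > best) { best = d; j = t; }
      }
      if (j < 0) continue;
      double ai_old = alpha[i], aj_old = alpha[j];
      double Ci = Cvec[i], Cj = Cvec[j];
      double L, H;
      if (y[i] != y[j]) {
        L = std::max(0.0, aj_old - ai_old);
        H = std::min(Cj, Ci + aj_old - ai_old);
      } else {
        L = std::max(0.0, ai_old + aj_old - Ci);
        H = std::min(Cj, ai_old + aj_old);
      }
      if (L >= H) continue;
      double eta = 2.0 * K(i, j) - K(i, i) - K(j, j);
      if (eta >= 0.0) continue;
      double aj = aj_old - y[j] * (E[i] - E[j]) / eta;
      aj = std::min(H, std::max(L, aj));
      if (std::fabs(aj - aj_old) < 1e-7) continue;
      double ai = ai_old + y[i] * y[j] * (aj_old - aj);
      alpha[i] = ai;
      alpha[j] = aj;
      double b1 = b - E[i] - y[i] * (ai - ai_old) * K(i, i) -
                  y[j] * (aj - aj_old) * K(i, j);
      double b2 = b - E[j] - y[i] * (ai - ai_old) * K(i, j) -
                  y[j] * (aj - aj_old) * K(j, j);
      if (ai > 0.0 && ai < Ci) b = b1;
      else if (aj > 0.0 && aj < Cj) b = b2;
      else b = 0.5 * (b1 + b2);
      for (int t = 0; t < n; ++t) E[t] = fx(t) - y[t];
      ++changed;
    }
    if (changed == 0) break;
    ++pass;
  }
  return List::create(Named("alpha") = NumericVector(alpha.begin(), alpha.end()),
                      Named("b") = b, Named("passes") = pass);
}
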