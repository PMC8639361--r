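#include <Rcpp.h>
using namespace Rcpp;

// Weighted alternating-projection demeaning over several fixed-effect
// dimensions, with Irons-Tuck acceleration of the fixed-point sweep map.
// Sweeps run until the largest single-sweep group-mean adjustment drops
// below tol * scale(M).
//
// fe: list of integer vectors with 1-based group codes per row.
// Returns the demeaned copy of M; attribute "converged" reports success.

namespace {

struct FeDims {
  std::vector<std::vector<int> > idx;
  std::vector<std::vector<double> > wsum;
  std::vector<int> K;
};

// One full sweep over all dimensions and columns; returns the largest
// absolute adjustment applied.
double sweep_once(std::vector<double>& x, int n, int p, const FeDims& fd,
                  const double* w, std::vector<double>& gsum) {
  double delta = 0.0;
  const int D = (int) fd.idx.size();
  for (int d = 0; d < D; ++d) {
    const std::vector<int>& g = fd.idx[d];
    const std::vector<double>& ws = fd.wsum[d];
    const int K = fd.K[d];
    for (int j = 0; j < p; ++j) {
      double* col = &x[(size_t) j * n];
      gsum.assign(K, 0.0);
      for (int i = 0; i < n; ++i) gsum[g[i]] += col[i] * w[i];
      for (int k = 0; k < K; ++k) gsum[k] /= ws[k];
      for (int i = 0; i < n; ++i) {
        double adj = gsum[g[i]];
        col[i] -= adj;
        if (std::abs(adj) > delta) delta = std::abs(adj);
      }
    }
  }
  return delta;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_demean(NumericMatrix M, NumericVector w, List fe,
                         double tol, int max_sweeps) {
  const int n = M.nrow(), p = M.ncol(), D = fe.size();
  if (D == 0 || n == 0) return clone(M);

  FeDims fd;
  fd.idx.resize(D);
  fd.wsum.resize(D);
  fd.K.resize(D);
  for (int d = 0; d < D; ++d) {
    IntegerVector g = fe[d];
    int k = 0;
    fd.idx[d].resize(n);
    for (int i = 0; i < n; ++i) {
      fd.idx[d][i] = g[i] - 1;
      if (g[i] > k) k = g[i];
    }
    fd.K[d] = k;
    fd.wsum[d].assign(k, 0.0);
    for (int i = 0; i < n; ++i) fd.wsum[d][fd.idx[d][i]] += w[i];
  }

  const size_t np = (size_t) n * p;
  std::vector<double> x(np), fx(np), ffx(np);
  double scale = 1.0;
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) {
      double v = M(i, j);
      x[(size_t) j * n + i] = v;
      if (std::abs(v) > scale) scale = std::abs(v);
    }

  std::vector<double> gsum;
  const double* wp = REAL(w);
  bool converged = false;
  int sweeps = 0;
  while (sweeps < max_sweeps) {
    // Two plain sweeps give the fixed-point iterates F(x) and F(F(x)).
    fx = x;
    double d1 = sweep_once(fx, n, p, fd, wp, gsum);
    ++sweeps;
    if (d1 < tol * scale) { x = fx; converged = true; break; }
    ffx = fx;
    double d2 = sweep_once(ffx, n, p, fd, wp, gsum);
    ++sweeps;
    if (d2 < tol * scale) { x = ffx; converged = true; break; }
    // Irons-Tuck extrapolation: x <- FFx - c * (FFx - Fx) with
    // c = <GFx, D2> / <D2, D2>, GFx = FFx - Fx, D2 = GFx - (Fx - x).
    double num = 0.0, den = 0.0;
    for (size_t i = 0; i < np; ++i) {
      double gfx = ffx[i] - fx[i];
      double d2i = gfx - (fx[i] - x[i]);
      num += gfx * d2i;
      den += d2i * d2i;
    }
    if (den > 0.0) {
      double c = num / den;
      for (size_t i = 0; i < np; ++i) {
        x[i] = ffx[i] - c * (ffx[i] - fx[i]);
      }
    } else {
      x = ffx;
    }
  }

  NumericMatrix out(n, p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) out(i, j) = x[(size_t) j * n + i];
  out.attr("converged") = converged;
  out.attr("sweeps") = sweeps;
  return out;
}
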