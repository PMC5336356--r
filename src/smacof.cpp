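// SMACOF (Guttman transform) engine for the MDS lens.
// Raw stress sum_{i<j} (d_ij - ||z_i - z_j||)^2 decreases monotonically.
// One fused pass per iterate computes its stress together with the next
// configuration, accumulated pairwise:
//   z'_i = (1/n) * sum_{j != i} (d_ij / ||z_i - z_j||) (z_i - z_j)
// with a zero ratio wherever two points coincide.
#include <Rcpp.h>
#include <cmath>
#include <vector>

// [[Rcpp::export]]
Rcpp::List smacof_engine(const Rcpp::NumericMatrix& d,
                         const Rcpp::NumericMatrix& z0,
                         int max_iter, double tol) {
  const int n = d.nrow(), k = z0.ncol();
  const double* dp = d.begin();
  const double eps = std::numeric_limits<double>::epsilon();

  // point-contiguous (row-major) coordinate buffers
  std::vector<double> z_prev(n * k), z_cur(n * k), z_next(n * k);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < k; ++c) z_cur[i * k + c] = z0(i, c);

  // stress of `z` and, simultaneously, its Guttman update into `out`
  auto fused_pass = [&](const std::vector<double>& z,
                        std::vector<double>& out) {
    double s = 0.0;
    std::fill(out.begin(), out.end(), 0.0);
    for (int j = 1; j < n; ++j) {
      const double* zj = &z[j * k];
      const double* dcol = dp + static_cast<size_t>(j) * n;
      for (int i = 0; i < j; ++i) {
        const double* zi = &z[i * k];
        double dist2 = 0.0;
        for (int c = 0; c < k; ++c) {
          double diff = zi[c] - zj[c];
          dist2 += diff * diff;
        }
        double dist = std::sqrt(dist2);
        double e = dcol[i] - dist;
        s += e * e;
        double ratio = (dist > 0.0) ? dcol[i] / dist : 0.0;
        for (int c = 0; c < k; ++c) {
          double contrib = ratio * (zi[c] - zj[c]);
          out[i * k + c] += contrib;
          out[j * k + c] -= contrib;
        }
      }
    }
    for (int idx = 0; idx < n * k; ++idx) out[idx] /= n;
    return s;
  };

  std::vector<double> trace;
  int iter = 0;
  bool converged = false, reverted = false;
  double s_last = 0.0, s = 0.0;

  for (int pass = 0; pass <= max_iter; ++pass) {
    s = fused_pass(z_cur, z_next);
    trace.push_back(s);
    if (pass == 0) {
      if (s <= 0.0) { converged = true; break; }
    } else {
      iter = pass;
      if (s > s_last) { reverted = true; break; }   // fp guard; cannot rise
      if ((s_last - s) <= tol * std::max(s_last, eps)) {
        converged = true;
        break;
      }
    }
    if (pass == max_iter) break;                    // step budget exhausted
    s_last = s;
    z_prev.swap(z_cur);
    z_cur.swap(z_next);
  }

  const std::vector<double>& z_out_v = reverted ? z_prev : z_cur;
  double s_out = reverted ? s_last : s;
  Rcpp::NumericMatrix z_out(n, k);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < k; ++c) z_out(i, c) = z_out_v[i * k + c];
  return Rcpp::List::create(
      Rcpp::Named("z") = z_out, Rcpp::Named("stress") = s_out,
      Rcpp::Named("trace") = trace, Rcpp::Named("iterations") = iter,
      Rcpp::Named("converged") = converged);
}
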