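#include <Rcpp.h>
using namespace Rcpp;

// Two smallest electrode distances for every sample point.
// points: n x 3, centers: m x 3. Returns n x 2 matrix (d1 <= d2).
// d2 is +Inf when the layout has a single electrode.
// [[Rcpp::export]]
NumericMatrix nearest_two_dist(NumericMatrix points, NumericMatrix centers) {
  const int n = points.nrow();
  const int m = centers.nrow();
  NumericMatrix out(n, 2);
  const double *px = &points(0, 0);
  const double *py = &points(0, 1);
  const double *pz = &points(0, 2);
  std::vector<double> cx(m), cy(m), cz(m);
  for (int j = 0; j < m; ++j) {
    cx[j] = centers(j, 0);
    cy[j] = centers(j, 1);
    cz[j] = centers(j, 2);
  }
  for (int i = 0; i < n; ++i) {
    double d1 = R_PosInf, d2 = R_PosInf;
    const double x = px[i], y = py[i], z = pz[i];
    for (int j = 0; j < m; ++j) {
      const double dx = x - cx[j], dy = y - cy[j], dz = z - cz[j];
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < d1) {
        d2 = d1;
        d1 = d;
      } else if (d < d2) {
        d2 = d;
      }
    }
    out(i, 0) = std::sqrt(d1);
    out(i, 1) = std::sqrt(d2);
  }
  return out;
}
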