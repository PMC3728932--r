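#include <Rcpp.h>
using namespace Rcpp;

// Overtopped crown fraction per tree.
//
// Crowns are discs of radius coef * height. A subcell (of side `sub`)
// belongs to a crown if its centre lies inside the disc. For each tree
// the returned value is the fraction of its crown subcells whose
// tallest covering crown is strictly taller than the tree itself.
// Trees whose crown covers no subcell centre (radius < sub/2 away from
// all centres) are treated as not overtopped.
// [[Rcpp::export]]
NumericVector overtop_fraction_cpp(NumericVector x, NumericVector y,
                                   NumericVector h, double coef,
                                   double sub) {
  int n = x.size();
  NumericVector frac(n);
  if (n == 0) return frac;

  double rmax = coef * Rcpp::max(h);
  double xmin = Rcpp::min(x) - rmax, xmax = Rcpp::max(x) + rmax;
  double ymin = Rcpp::min(y) - rmax, ymax = Rcpp::max(y) + rmax;
  int nxc = (int)std::ceil((xmax - xmin) / sub) + 1;
  int nyc = (int)std::ceil((ymax - ymin) / sub) + 1;

  std::vector<double> H((size_t)nxc * nyc, R_NegInf);

  // pass 1: tallest crown covering each subcell centre
  for (int t = 0; t < n; ++t) {
    double r = coef * h[t], r2 = r * r;
    int j0 = (int)std::floor((x[t] - r - xmin) / sub);
    int j1 = (int)std::ceil((x[t] + r - xmin) / sub);
    int i0 = (int)std::floor((y[t] - r - ymin) / sub);
    int i1 = (int)std::ceil((y[t] + r - ymin) / sub);
    if (j0 < 0) j0 = 0; if (i0 < 0) i0 = 0;
    if (j1 >= nxc) j1 = nxc - 1; if (i1 >= nyc) i1 = nyc - 1;
    for (int i = i0; i <= i1; ++i) {
      double cy = ymin + (i + 0.5) * sub, dy = cy - y[t];
      for (int j = j0; j <= j1; ++j) {
        double cx = xmin + (j + 0.5) * sub, dx = cx - x[t];
        if (dx * dx + dy * dy <= r2) {
          size_t k = (size_t)i * nxc + j;
          if (h[t] > H[k]) H[k] = h[t];
        }
      }
    }
  }

  // pass 2: per-tree covered fraction by strictly taller crowns
  for (int t = 0; t < n; ++t) {
    double r = coef * h[t], r2 = r * r;
    int j0 = (int)std::floor((x[t] - r - xmin) / sub);
    int j1 = (int)std::ceil((x[t] + r - xmin) / sub);
    int i0 = (int)std::floor((y[t] - r - ymin) / sub);
    int i1 = (int)std::ceil((y[t] + r - ymin) / sub);
    if (j0 < 0) j0 = 0; if (i0 < 0) i0 = 0;
    if (j1 >= nxc) j1 = nxc - 1; if (i1 >= nyc) i1 = nyc - 1;
    long tot = 0, cov = 0;
    for (int i = i0; i <= i1; ++i) {
      double cy = ymin + (i + 0.5) * sub, dy = cy - y[t];
      for (int j = j0; j <= j1; ++j) {
        double cx = xmin + (j + 0.5) * sub, dx = cx - x[t];
        if (dx * dx + dy * dy <= r2) {
          ++tot;
          if (H[(size_t)i * nxc + j] > h[t]) ++cov;
        }
      }
    }
    frac[t] = tot > 0 ? (double)cov / tot : 0.0;
  }
  return frac;
}
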