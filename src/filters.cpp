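#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// reflect index into [0, n-1] (mirror without repeating the edge pixel,
// i.e. -1 -> 1, n -> n-2), the usual "reflect" convention for filters
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix x, int k) {
  if (k < 1 || k % 2 == 0) stop("kernel size must be a positive odd integer");
  int nr = x.nrow(), nc = x.ncol(), h = k / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(k * k);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int m = 0;
      for (int dc = -h; dc <= h; ++dc) {
        int cc = reflect(c + dc, nc);
        for (int dr = -h; dr <= h; ++dr)
          buf[m++] = x(reflect(r + dr, nr), cc);
      }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
      out(r, c) = buf[m / 2];
    }
  }
  return out;
}

// connected components of a binary raster, 4- or 8-connectivity,
// labels 1..n in scan order of first pixel encountered
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix x, int connectivity) {
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = connectivity == 4 ? dr4 : dr8;
  const int *dc = connectivity == 4 ? dc4 : dc8;
  int nn = connectivity;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (x(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int j = 0; j < nn; ++j) {
          int r2 = rr + dr[j], c2 = cc + dc[j];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (x(r2, c2) != 0 && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Perona-Malik anisotropic diffusion, 4-neighbour explicit scheme,
// exponential conductance g(d) = exp(-(d/kappa)^2); reflected border
// (zero flux across the image edge)
// [[Rcpp::export]]
NumericMatrix perona_malik_cpp(NumericMatrix x, int iterations,
                               double kappa, double lambda) {
  if (iterations < 0) stop("iterations must be >= 0");
  if (kappa <= 0) stop("kappa must be > 0");
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix cur(clone(x)), nxt(nr, nc);
  double ik2 = 1.0 / (kappa * kappa);
  for (int it = 0; it < iterations; ++it) {
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        double v = cur(r, c), flux = 0.0;
        double dN = (r > 0      ? cur(r - 1, c) : v) - v;
        double dS = (r < nr - 1 ? cur(r + 1, c) : v) - v;
        double dW = (c > 0      ? cur(r, c - 1) : v) - v;
        double dE = (c < nc - 1 ? cur(r, c + 1) : v) - v;
        flux += std::exp(-dN * dN * ik2) * dN;
        flux += std::exp(-dS * dS * ik2) * dS;
        flux += std::exp(-dW * dW * ik2) * dW;
        flux += std::exp(-dE * dE * ik2) * dE;
        nxt(r, c) = v + lambda * flux;
      }
    }
    std::swap(cur, nxt);
  }
  return cur;
}

// stamp disks of given radii at centre points into a logical mask
// (vessel tube rasterisation); points outside the canvas are clipped
// [[Rcpp::export]]
LogicalMatrix stamp_disks_cpp(IntegerVector rows, IntegerVector cols,
                              NumericVector radii, int nr, int nc) {
  if (rows.size() != cols.size() || rows.size() != radii.size())
    stop("rows, cols and radii must have equal length");
  LogicalMatrix out(nr, nc);
  for (int i = 0; i < rows.size(); ++i) {
    double rad = radii[i];
    int r0 = rows[i] - 1, c0 = cols[i] - 1;  // 1-based in, 0-based here
    int ir = (int)std::floor(rad);
    for (int dc = -ir; dc <= ir; ++dc) {
      int c = c0 + dc;
      if (c < 0 || c >= nc) continue;
      for (int dr = -ir; dr <= ir; ++dr) {
        int r = r0 + dr;
        if (r < 0 || r >= nr) continue;
        if (dr * dr + dc * dc <= rad * rad) out(r, c) = true;
      }
    }
  }
  return out;
}
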