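#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// reflect index into [0, n-1] (symmetric half-sample-free reflection)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// Bilateral filter: J(x) = (1/k) sum_{n in Omega} s(n-x) r(f(n)-f(x)) f(n),
// Gaussian spatial kernel s (sd sigma_s) truncated at `radius`, Gaussian range
// kernel r (sd sigma_r). Border handled by reflection.
// [[Rcpp::export]]
NumericMatrix bilateral_cpp(NumericMatrix img, double sigma_s, double sigma_r,
                            int radius) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  int w = 2 * radius + 1;
  std::vector<double> sk(w * w);
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx)
      sk[(dy + radius) * w + (dx + radius)] =
        std::exp(-0.5 * (dy * dy + dx * dx) / (sigma_s * sigma_s));
  double inv2r2 = 0.5 / (sigma_r * sigma_r);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double fc = img(i, j), num = 0.0, den = 0.0;
      for (int dy = -radius; dy <= radius; ++dy) {
        int ii = reflect_idx(i + dy, H);
        for (int dx = -radius; dx <= radius; ++dx) {
          int jj = reflect_idx(j + dx, W);
          double fn = img(ii, jj);
          double d = fn - fc;
          double wgt = sk[(dy + radius) * w + (dx + radius)] *
                       std::exp(-d * d * inv2r2);
          num += wgt * fn;
          den += wgt;
        }
      }
      out(i, j) = num / den;
    }
  }
  return out;
}

// Connected-component labeling of a binary mask, BFS, 4- or 8-connectivity.
// Labels 1..K in raster order of first encounter; 0 is background.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  const int dx8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dy8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nd = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int d = 0; d < nd; ++d) {
          int ii = p.first + dy8[d], jj = p.second + dx8[d];
          if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}
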