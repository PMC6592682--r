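#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Zero-mean normalized cross-correlation (Pearson) of a template window
// against every integer lag of a search region.  A is win x win, B is
// (win + 2*radius) x (win + 2*radius); both column-major (R layout).
// Plane rows index dy (-radius..radius), columns dx.  Degenerate windows
// (zero variance on either side) contribute correlation 0 at that lag.

static inline double window_zncc(const double* a0, double ssa,
                                 const double* B, int nb,
                                 int row0, int col0, int win) {
  // a0: zero-mean template (win*win, column-major); B region with its
  // top-left pixel of the lag window at (row0, col0)
  double s1 = 0.0, s2 = 0.0, sab = 0.0;
  for (int j = 0; j < win; ++j) {
    const double* bcol = B + (size_t)(col0 + j) * nb + row0;
    const double* acol = a0 + (size_t)j * win;
    for (int i = 0; i < win; ++i) {
      double b = bcol[i];
      s1 += b; s2 += b * b; sab += acol[i] * b;
    }
  }
  double n = (double)win * win;
  double ssb = s2 - s1 * s1 / n;
  double denom = ssa * ssb;
  if (denom <= 1e-12) return 0.0;
  return sab / std::sqrt(denom);
}

// [[Rcpp::export]]
NumericMatrix cpp_zncc_plane(NumericMatrix A, NumericMatrix B, int radius) {
  int win = A.nrow();
  if (A.ncol() != win) stop("template window must be square");
  int side = 2 * radius + 1;
  if (B.nrow() != win + 2 * radius || B.ncol() != win + 2 * radius)
    stop("search region must be win + 2*radius on each side");
  std::vector<double> a0((size_t)win * win);
  double mean = 0.0;
  for (int k = 0; k < win * win; ++k) mean += A[k];
  mean /= (double)(win * win);
  double ssa = 0.0;
  for (int k = 0; k < win * win; ++k) {
    a0[k] = A[k] - mean;
    ssa += a0[k] * a0[k];
  }
  NumericMatrix plane(side, side);
  if (ssa <= 1e-12) return plane;  // degenerate: all-zero plane
  for (int dx = -radius; dx <= radius; ++dx)
    for (int dy = -radius; dy <= radius; ++dy)
      plane(dy + radius, dx + radius) =
        window_zncc(a0.data(), ssa, &B[0], B.nrow(),
                    radius + dy, radius + dx, win);
  return plane;
}

// Ensemble-averaged correlation planes for a set of interrogation windows
// over a set of frame pairs.  stack: H x W x nframes array (column-major).
// centers: n x 2 matrix of 0-based (x=col, y=row) window centers.
// pred: n x 2 integer predictor shifts applied to the b-window.
// Windows of even size `win` centered at c cover pixels c-win/2 .. c+win/2-1.
// Returns a (side*side) x n matrix of mean planes; windows whose a- or
// b-window (including search margin) leaves the frame are all-NA.
// [[Rcpp::export]]
List cpp_ensemble_planes(NumericVector stack, IntegerVector dims,
                         IntegerVector pair_a, IntegerVector pair_b,
                         IntegerMatrix centers, IntegerMatrix pred,
                         int win, int radius) {
  int H = dims[0], W = dims[1];
  int npair = pair_a.size();
  int nwin = centers.nrow();
  int side = 2 * radius + 1;
  int h = win / 2;
  NumericMatrix planes(side * side, nwin);
  IntegerVector npool(nwin);
  LogicalVector inside(nwin);
  std::vector<double> a0((size_t)win * win);

  // bounds check per window (frame-independent)
  for (int w = 0; w < nwin; ++w) {
    int cx = centers(w, 0), cy = centers(w, 1);
    int bx = cx + pred(w, 0), by = cy + pred(w, 1);
    bool ok = (cx - h >= 0) && (cx + win - h - 1 < W) &&
              (cy - h >= 0) && (cy + win - h - 1 < H) &&
              (bx - h - radius >= 0) && (bx + win - h - 1 + radius < W) &&
              (by - h - radius >= 0) && (by + win - h - 1 + radius < H);
    inside[w] = ok;
    if (!ok)
      for (int k = 0; k < side * side; ++k) planes(k, w) = NA_REAL;
  }

  const double* st = &stack[0];
  size_t fsz = (size_t)H * W;
  std::vector<double> Breg;
  for (int p = 0; p < npair; ++p) {
    const double* fa = st + fsz * (size_t)(pair_a[p] - 1);
    const double* fb = st + fsz * (size_t)(pair_b[p] - 1);
    for (int w = 0; w < nwin; ++w) {
      if (!inside[w]) continue;
      int cx = centers(w, 0), cy = centers(w, 1);
      int bx = cx + pred(w, 0), by = cy + pred(w, 1);
      // template from frame a
      double mean = 0.0;
      for (int j = 0; j < win; ++j) {
        const double* col = fa + (size_t)(cx - h + j) * H + (cy - h);
        for (int i = 0; i < win; ++i) mean += col[i];
      }
      mean /= (double)(win * win);
      double ssa = 0.0;
      for (int j = 0; j < win; ++j) {
        const double* col = fa + (size_t)(cx - h + j) * H + (cy - h);
        for (int i = 0; i < win; ++i) {
          double v = col[i] - mean;
          a0[(size_t)j * win + i] = v;
          ssa += v * v;
        }
      }
      npool[w] += 1;
      if (ssa <= 1e-12) continue;  // degenerate pair: contributes zeros
      // search region from frame b
      int nb = win + 2 * radius;
      Breg.assign((size_t)nb * nb, 0.0);
      for (int j = 0; j < nb; ++j) {
        const double* col = fb + (size_t)(bx - h - radius + j) * H +
                            (by - h - radius);
        double* dst = Breg.data() + (size_t)j * nb;
        for (int i = 0; i < nb; ++i) dst[i] = col[i];
      }
      for (int dx = -radius; dx <= radius; ++dx)
        for (int dy = -radius; dy <= radius; ++dy)
          planes((dx + radius) * side + (dy + radius), w) +=
            window_zncc(a0.data(), ssa, Breg.data(), nb,
                        radius + dy, radius + dx, win);
    }
    if (p % 8 == 0) Rcpp::checkUserInterrupt();
  }
  for (int w = 0; w < nwin; ++w)
    if (inside[w] && npool[w] > 0)
      for (int k = 0; k < side * side; ++k) planes(k, w) /= npool[w];
  return List::create(_["planes"] = planes, _["n_pooled"] = npool,
                      _["inside"] = inside);
}

// Render particles as pixel-integrated isotropic Gaussian spots.
// x, y: particle centers in 0-based pixel coordinates (pixel centers at
// integers); bright: per-particle total intensity mass; sigma in px.
// [[Rcpp::export]]
NumericMatrix cpp_render(NumericVector x, NumericVector y,
                         NumericVector bright, double sigma,
                         int H, int W) {
  NumericMatrix img(H, W);
  int n = x.size();
  double r = std::ceil(4.0 * sigma);
  double inv = 1.0 / (sigma * std::sqrt(2.0));
  for (int p = 0; p < n; ++p) {
    int j0 = std::max(0, (int)std::floor(x[p] - r));
    int j1 = std::min(W - 1, (int)std::ceil(x[p] + r));
    int i0 = std::max(0, (int)std::floor(y[p] - r));
    int i1 = std::min(H - 1, (int)std::ceil(y[p] + r));
    if (j0 > j1 || i0 > i1) continue;
    for (int j = j0; j <= j1; ++j) {
      double fx = 0.5 * (std::erf((j + 0.5 - x[p]) * inv) -
                         std::erf((j - 0.5 - x[p]) * inv));
      double bfx = bright[p] * fx;
      for (int i = i0; i <= i1; ++i) {
        double fy = 0.5 * (std::erf((i + 0.5 - y[p]) * inv) -
                           std::erf((i - 0.5 - y[p]) * inv));
        img(i, j) += bfx * fy;
      }
    }
  }
  return img;
}
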