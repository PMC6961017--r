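#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// SLIC superpixel segmentation for a single-channel image in [0,1].
// Windowed k-means in (intensity, x, y) space followed by connectivity
// enforcement. Intensity is scaled by 100 so that the compactness parameter
// acts on the same scale as it does for an L channel in [0,100]; spatial
// distances are divided by the grid interval S. Deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_slic(NumericMatrix img, int nseg, double compactness,
                       int maxiter, double minsize_factor) {
  const int H = img.nrow(), W = img.ncol();
  const int n = H * W;
  if (nseg < 1) stop("number of segments must be >= 1");
  if (nseg > n) nseg = n;
  const double S = std::sqrt((double)n / nseg);

  int gh = (int)std::lround(H / S); if (gh < 1) gh = 1;
  int gw = (int)std::lround(W / S); if (gw < 1) gw = 1;
  const int nc = gh * gw;

  std::vector<double> cy(nc), cx(nc), ci(nc);
  {
    int c = 0;
    for (int i = 0; i < gh; ++i)
      for (int j = 0; j < gw; ++j, ++c) {
        cy[c] = (i + 0.5) * H / gh;
        cx[c] = (j + 0.5) * W / gw;
        int py = std::min(H - 1, (int)cy[c]);
        int px = std::min(W - 1, (int)cx[c]);
        ci[c] = img(py, px);
      }
  }

  std::vector<int> lab(n, -1);
  std::vector<double> dist(n);
  const double invS2 = (compactness / S) * (compactness / S);
  const int win = (int)std::ceil(1.5 * S);

  for (int it = 0; it < maxiter; ++it) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    for (int c = 0; c < nc; ++c) {
      int y0 = std::max(0, (int)cy[c] - win), y1 = std::min(H - 1, (int)cy[c] + win);
      int x0 = std::max(0, (int)cx[c] - win), x1 = std::min(W - 1, (int)cx[c] + win);
      for (int x = x0; x <= x1; ++x) {
        double dx = x - cx[c];
        for (int y = y0; y <= y1; ++y) {
          double dy = y - cy[c];
          double di = 100.0 * (img(y, x) - ci[c]);
          double d = di * di + invS2 * (dx * dx + dy * dy);
          int p = y + H * x;
          if (d < dist[p]) { dist[p] = d; lab[p] = c; }
        }
      }
    }
    // recompute centers
    std::vector<double> sy(nc, 0), sx(nc, 0), si(nc, 0); std::vector<int> cnt(nc, 0);
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        int p = y + H * x, c = lab[p];
        if (c >= 0) { sy[c] += y; sx[c] += x; si[c] += img(y, x); ++cnt[c]; }
      }
    for (int c = 0; c < nc; ++c)
      if (cnt[c] > 0) { cy[c] = sy[c] / cnt[c]; cx[c] = sx[c] / cnt[c]; ci[c] = si[c] / cnt[c]; }
  }

  // safety net: pixels outside every window get the spatially nearest center
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      int p = y + H * x;
      if (lab[p] < 0) {
        double best = R_PosInf; int bc = 0;
        for (int c = 0; c < nc; ++c) {
          double d = (y - cy[c]) * (y - cy[c]) + (x - cx[c]) * (x - cx[c]);
          if (d < best) { best = d; bc = c; }
        }
        lab[p] = bc;
      }
    }

  // connectivity enforcement: flood-fill components of equal label; components
  // smaller than minsize are absorbed into the previously visited neighbor.
  const int minsize = std::max(1, (int)(minsize_factor * n / nseg));
  std::vector<int> newlab(n, -1);
  std::vector<int> comp; comp.reserve(n);
  int next = 0;
  const int dyv[4] = {1, -1, 0, 0}, dxv[4] = {0, 0, 1, -1};
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      int p = y + H * x;
      if (newlab[p] >= 0) continue;
      int adj = -1;
      comp.clear();
      comp.push_back(p);
      newlab[p] = next;
      size_t head = 0;
      while (head < comp.size()) {
        int q = comp[head++];
        int qy = q % H, qx = q / H;
        for (int k = 0; k < 4; ++k) {
          int ny = qy + dyv[k], nx = qx + dxv[k];
          if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
          int np = ny + H * nx;
          if (newlab[np] < 0 && lab[np] == lab[p]) {
            newlab[np] = next;
            comp.push_back(np);
          } else if (newlab[np] >= 0 && newlab[np] != next) {
            adj = newlab[np];
          }
        }
      }
      if ((int)comp.size() < minsize && adj >= 0) {
        for (int q : comp) newlab[q] = adj;
      } else {
        ++next;
      }
    }

  // labels from absorbed components leave gaps: compact to 1..K
  std::vector<int> remap(next, -1);
  int K = 0;
  IntegerMatrix out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      int l = newlab[y + H * x];
      if (remap[l] < 0) remap[l] = K++;
      out(y, x) = remap[l] + 1;
    }
  return out;
}
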