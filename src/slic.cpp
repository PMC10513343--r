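#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// SLIC superpixels on a CIELAB image. Grid-seeded k-means with the usual
// combined distance D^2 = d_lab^2 + (m/S)^2 d_xy^2, local 2S window search,
// followed by an orphan-absorbing connectivity pass. Deterministic.
// lab: h x w x 3 array (column-major), labels returned 1-based.
// [[Rcpp::export]]
IntegerVector slic_cpp(NumericVector lab, int h, int w, int k,
                       double compactness, int iters) {
  const int npix = h * w;
  const double *L = REAL(lab);
  const double *A = L + npix;
  const double *B = L + 2 * npix;
  double S = std::sqrt((double)npix / k);
  int gx = std::max(1, (int)std::lround(w / S));
  int gy = std::max(1, (int)std::lround(h / S));
  int nc = gx * gy;
  std::vector<double> cx(nc), cy(nc), cl(nc), ca(nc), cb(nc);
  int ci = 0;
  for (int j = 0; j < gx; ++j)
    for (int i = 0; i < gy; ++i) {
      double x = (j + 0.5) * w / gx, y = (i + 0.5) * h / gy;
      int px = std::min(w - 1, (int)x), py = std::min(h - 1, (int)y);
      int idx = py + px * h;
      cx[ci] = x; cy[ci] = y; cl[ci] = L[idx]; ca[ci] = A[idx]; cb[ci] = B[idx];
      ++ci;
    }
  std::vector<int> label(npix, -1);
  std::vector<double> dist(npix);
  double invS2 = (compactness * compactness) / (S * S);
  int win = (int)std::ceil(2.0 * S);
  for (int it = 0; it < iters; ++it) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    for (int c = 0; c < nc; ++c) {
      int x0 = std::max(0, (int)cx[c] - win), x1 = std::min(w - 1, (int)cx[c] + win);
      int y0 = std::max(0, (int)cy[c] - win), y1 = std::min(h - 1, (int)cy[c] + win);
      for (int x = x0; x <= x1; ++x)
        for (int y = y0; y <= y1; ++y) {
          int idx = y + x * h;
          double dl = L[idx] - cl[c], da = A[idx] - ca[c], db = B[idx] - cb[c];
          double dx = x - cx[c], dy = y - cy[c];
          double D = dl * dl + da * da + db * db + (dx * dx + dy * dy) * invS2;
          if (D < dist[idx]) { dist[idx] = D; label[idx] = c; }
        }
    }
    // update centers
    std::vector<double> sx(nc, 0), sy(nc, 0), sl(nc, 0), sa(nc, 0), sb(nc, 0);
    std::vector<int> cnt(nc, 0);
    for (int x = 0; x < w; ++x)
      for (int y = 0; y < h; ++y) {
        int idx = y + x * h, c = label[idx];
        if (c < 0) continue;
        sx[c] += x; sy[c] += y; sl[c] += L[idx]; sa[c] += A[idx]; sb[c] += B[idx];
        cnt[c]++;
      }
    for (int c = 0; c < nc; ++c)
      if (cnt[c] > 0) {
        cx[c] = sx[c] / cnt[c]; cy[c] = sy[c] / cnt[c];
        cl[c] = sl[c] / cnt[c]; ca[c] = sa[c] / cnt[c]; cb[c] = sb[c] / cnt[c];
      }
  }
  // any pixel never visited (possible on degenerate geometry): nearest center
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y) {
      int idx = y + x * h;
      if (label[idx] >= 0) continue;
      double best = R_PosInf; int bc = 0;
      for (int c = 0; c < nc; ++c) {
        double dx = x - cx[c], dy = y - cy[c], D = dx * dx + dy * dy;
        if (D < best) { best = D; bc = c; }
      }
      label[idx] = bc;
    }
  // connectivity: relabel connected components; absorb small ones into the
  // previously finalized neighbor (standard SLIC post-processing)
  std::vector<int> out(npix, -1);
  int nlab = 0;
  int minsz = npix / (k * 4);
  const int dx4[4] = {-1, 1, 0, 0}, dy4[4] = {0, 0, -1, 1};
  std::vector<int> comp;
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y) {
      int idx = y + x * h;
      if (out[idx] >= 0) continue;
      int adj = -1;
      comp.clear();
      std::queue<std::pair<int,int> > q;
      q.push(std::make_pair(x, y));
      out[idx] = nlab;
      comp.push_back(idx);
      while (!q.empty()) {
        std::pair<int,int> p = q.front(); q.pop();
        for (int d = 0; d < 4; ++d) {
          int xn = p.first + dx4[d], yn = p.second + dy4[d];
          if (xn < 0 || xn >= w || yn < 0 || yn >= h) continue;
          int in = yn + xn * h;
          if (out[in] >= 0) {
            if (out[in] != nlab) adj = out[in];
            continue;
          }
          if (label[in] == label[idx]) {
            out[in] = nlab;
            comp.push_back(in);
            q.push(std::make_pair(xn, yn));
          }
        }
      }
      if ((int)comp.size() <= minsz && adj >= 0) {
        for (size_t t = 0; t < comp.size(); ++t) out[comp[t]] = adj;
      } else {
        ++nlab;
      }
    }
  // compact label ids to 1..n
  std::vector<int> remap(nlab + 1, -1);
  int nfinal = 0;
  IntegerVector res(npix);
  for (int i = 0; i < npix; ++i) {
    int c = out[i];
    if (remap[c] < 0) remap[c] = nfinal++;
    res[i] = remap[c] + 1;
  }
  res.attr("dim") = Dimension(h, w);
  return res;
}
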