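#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cmath>
using namespace Rcpp;

// sliding max/min of row x over the clipped window [c-w, c+w]
// (monotonic deque, O(n) per row)
static void slide_minmax(const int *x, const int n, const int w,
                         int *omax, int *omin) {
  std::deque<int> qmax, qmin;
  int added = -1;
  for (int c = 0; c < n; ++c) {
    const int hi = std::min(n - 1, c + w);
    while (added < hi) {
      ++added;
      while (!qmax.empty() && x[qmax.back()] <= x[added]) qmax.pop_back();
      qmax.push_back(added);
      while (!qmin.empty() && x[qmin.back()] >= x[added]) qmin.pop_back();
      qmin.push_back(added);
    }
    const int lo = c - w;
    while (qmax.front() < lo) qmax.pop_front();
    while (qmin.front() < lo) qmin.pop_front();
    omax[c] = x[qmax.front()];
    omin[c] = x[qmin.front()];
  }
}

// Bernsen adaptive local threshold over a circular window.
//
// For every pixel the window extrema (local max/min) are taken over all
// pixels whose centre lies within Euclidean distance <= radius, the window
// being clipped at the image border (no padding).  The disc is decomposed
// into horizontal segments of half-width wx[dy] = floor(sqrt(r^2 - dy^2));
// per-row sliding extrema are precomputed for each distinct segment width
// and combined over the rows of the disc, giving O(n * r) overall.
//
// All comparisons are done in integer arithmetic: midgray >= cut  <=>
// (max + min) >= 2*cut and I(p) > midgray  <=>  2*I(p) > (max + min), so the
// half-integer midgray is handled exactly.
// [[Rcpp::export]]
LogicalMatrix bernsen_cpp(const IntegerMatrix img, const int radius,
                          const int contrast_threshold,
                          const int low_contrast_cut) {
  const int nr = img.nrow(), nc = img.ncol();
  if (nr < 1 || nc < 1) stop("empty image");
  if (radius < 1) stop("radius must be >= 1");

  // disc row half-widths and the set of distinct widths
  std::vector<int> wx(2 * radius + 1);
  for (int dy = -radius; dy <= radius; ++dy)
    wx[dy + radius] =
        (int)std::floor(std::sqrt((double)radius * radius - (double)dy * dy));
  std::vector<int> widths;           // distinct, ascending
  std::vector<int> widx(2 * radius + 1);
  for (int k = 0; k <= 2 * radius; ++k) {
    int w = wx[k], pos = -1;
    for (size_t t = 0; t < widths.size(); ++t)
      if (widths[t] == w) { pos = (int)t; break; }
    if (pos < 0) { widths.push_back(w); pos = (int)widths.size() - 1; }
    widx[k] = pos;
  }
  const int nwid = (int)widths.size();

  // per-width row-wise sliding extrema, stored row-major per width
  std::vector<std::vector<int>> rowmax(nwid), rowmin(nwid);
  std::vector<int> buf(nc);
  for (int t = 0; t < nwid; ++t) {
    rowmax[t].resize((size_t)nr * nc);
    rowmin[t].resize((size_t)nr * nc);
    for (int r = 0; r < nr; ++r) {
      for (int c = 0; c < nc; ++c) buf[c] = img(r, c);
      slide_minmax(buf.data(), nc, widths[t],
                   rowmax[t].data() + (size_t)r * nc,
                   rowmin[t].data() + (size_t)r * nc);
    }
  }

  LogicalMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    const int d0 = std::max(-radius, -r), d1 = std::min(radius, nr - 1 - r);
    for (int c = 0; c < nc; ++c) {
      int lmax = -1, lmin = INT_MAX;
      for (int dy = d0; dy <= d1; ++dy) {
        const int t = widx[dy + radius];
        const size_t off = (size_t)(r + dy) * nc + c;
        const int vmax = rowmax[t][off], vmin = rowmin[t][off];
        if (vmax > lmax) lmax = vmax;
        if (vmin < lmin) lmin = vmin;
      }
      const int contrast = lmax - lmin;
      const int mid2 = lmax + lmin;  // 2 * midgray
      bool obj;
      if (contrast < contrast_threshold)
        obj = mid2 >= 2 * low_contrast_cut;
      else
        obj = 2 * img(r, c) > mid2;
      out(r, c) = obj;
    }
  }
  return out;
}

// 8-connected component labelling.  Components are labelled 1..n in raster
// order (row by row, left to right) of their first pixel.
// [[Rcpp::export]]
IntegerMatrix label8_cpp(const LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);  // zero-initialised
  int next = 0;
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + nr * c);
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pr = p % nr, pc = p / nr;
        for (int i = -1; i <= 1; ++i) {
          for (int j = -1; j <= 1; ++j) {
            if (i == 0 && j == 0) continue;
            const int rr = pr + i, cc = pc + j;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              stack.push_back(rr + nr * cc);
            }
          }
        }
      }
    }
  }
  return lab;
}
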