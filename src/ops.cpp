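// Video-level primitives: per-pixel temporal matched filtering, per-pixel
// temporal quantiles, 8-connected component labeling, component extraction
// over a probability-map stack, and transitive-closure merging of components
// across frames.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Reflect index into [0, n-1] (mirror across the array edge: -1 -> 0, n -> n-1).
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Correlate every pixel trace with template u (peak at 1-based index `peak`),
// so a transient matching u peaks at the transient's peak frame.
// video: H x W x T array.
// [[Rcpp::export]]
NumericVector cpp_temporal_filter(NumericVector video, NumericVector u,
                                  int peak) {
  IntegerVector dim = video.attr("dim");
  if (dim.size() != 3) stop("video must be an H x W x T array");
  const int H = dim[0], W = dim[1], T = dim[2];
  const int K = u.size(), p = peak - 1;
  if (K > T) stop("kernel longer than video (%d > %d frames)", K, T);
  NumericVector out(video.size());
  out.attr("dim") = dim;
  const size_t HW = (size_t)H * W;
  std::vector<double> buf(T);
  for (size_t px = 0; px < HW; ++px) {
    for (int t = 0; t < T; ++t) buf[t] = video[px + HW * t];
    for (int t = 0; t < T; ++t) {
      double acc = 0.0;
      for (int s = 0; s < K; ++s) acc += u[s] * buf[reflect_idx(t + s - p, T)];
      out[px + HW * t] = acc;
    }
  }
  return out;
}

// Type-7 quantiles of each row of m (rows = pixels, cols = frames).
// [[Rcpp::export]]
NumericMatrix cpp_row_quantiles(NumericMatrix m, NumericVector probs) {
  const int n = m.nrow(), T = m.ncol(), q = probs.size();
  NumericMatrix out(n, q);
  std::vector<double> buf(T);
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < T; ++t) buf[t] = m(i, t);
    std::sort(buf.begin(), buf.end());
    for (int k = 0; k < q; ++k) {
      const double h = (T - 1) * probs[k];
      const int lo = (int)std::floor(h);
      const double frac = h - lo;
      out(i, k) = (lo + 1 < T) ? buf[lo] * (1.0 - frac) + buf[lo + 1] * frac
                               : buf[lo];
    }
  }
  return out;
}

struct DSU {
  std::vector<int> parent;
  explicit DSU(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[b] = a;
  }
};

// 8-connected labeling of a binary matrix; labels 1..k, background 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix bin) {
  const int H = bin.nrow(), W = bin.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int c0 = 0; c0 < W; ++c0) {
    for (int r0 = 0; r0 < H; ++r0) {
      if (bin(r0, c0) == 0 || lab(r0, c0) != 0) continue;
      ++next;
      stack.push_back({r0, c0});
      lab(r0, c0) = next;
      while (!stack.empty()) {
        auto [r, c] = stack.back();
        stack.pop_back();
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            const int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            if (bin(rr, cc) != 0 && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              stack.push_back({rr, cc});
            }
          }
        }
      }
    }
  }
  return lab;
}

// Binarize (strictly > p_thresh), label 8-connected components and drop those
// below min_area, over a whole H x W x T stack. Pixel indices are 1-based
// linear indices into an H x W matrix, sorted ascending.
// [[Rcpp::export]]
List cpp_extract_stack(NumericVector probs, double p_thresh, int min_area) {
  IntegerVector dim = probs.attr("dim");
  if (dim.size() != 3) stop("probability stack must be H x W x T");
  const int H = dim[0], W = dim[1], T = dim[2];
  const size_t HW = (size_t)H * W;

  std::vector<int> comp_frame;
  std::vector<double> comp_cr, comp_cc;
  List pixels_out;
  std::vector<std::vector<int>> all_pixels;

  IntegerMatrix bin(H, W);
  for (int t = 0; t < T; ++t) {
    const double* fr = probs.begin() + HW * t;
    bool any = false;
    for (size_t j = 0; j < HW; ++j) {
      bin[j] = fr[j] > p_thresh ? 1 : 0;
      any = any || bin[j];
    }
    if (!any) continue;
    IntegerMatrix lab = cpp_label_components(bin);
    int k = 0;
    for (size_t j = 0; j < HW; ++j) k = std::max(k, lab[j]);
    std::vector<std::vector<int>> px(k);
    for (size_t j = 0; j < HW; ++j)
      if (lab[j] > 0) px[lab[j] - 1].push_back((int)j + 1);
    for (int i = 0; i < k; ++i) {
      if ((int)px[i].size() < min_area) continue;
      double sr = 0, sc = 0;
      for (int id : px[i]) {
        sr += (id - 1) % H;
        sc += (id - 1) / H;
      }
      comp_frame.push_back(t + 1);
      comp_cr.push_back(sr / px[i].size() + 1);
      comp_cc.push_back(sc / px[i].size() + 1);
      all_pixels.push_back(std::move(px[i]));
    }
  }
  const int n = comp_frame.size();
  List plist(n);
  IntegerVector area(n);
  for (int i = 0; i < n; ++i) {
    plist[i] = IntegerVector(all_pixels[i].begin(), all_pixels[i].end());
    area[i] = all_pixels[i].size();
  }
  return List::create(_["frame"] = IntegerVector(comp_frame.begin(), comp_frame.end()),
                      _["area"] = area,
                      _["cr"] = NumericVector(comp_cr.begin(), comp_cr.end()),
                      _["cc"] = NumericVector(comp_cc.begin(), comp_cc.end()),
                      _["pixels"] = plist);
}

static int intersect_size(const IntegerVector& a, const IntegerVector& b) {
  int i = 0, j = 0, n = 0;
  const int na = a.size(), nb = b.size();
  while (i < na && j < nb) {
    if (a[i] < b[j]) ++i;
    else if (a[i] > b[j]) ++j;
    else { ++n; ++i; ++j; }
  }
  return n;
}

// Transitive closure of pairwise colocalization over all components:
// colocalized iff COM distance < centroid_dist, or IoU > 0.5, or
// consume(larger, smaller) = |inter|/|smaller| > 0.75. Pixel vectors must be
// sorted 1-based linear indices into an H x W matrix. Returns 1-based group
// ids in order of first appearance.
// [[Rcpp::export]]
IntegerVector cpp_merge_components(List pixels, NumericVector cr,
                                   NumericVector cc, IntegerVector area,
                                   int H, double centroid_dist) {
  const int n = pixels.size();
  std::vector<IntegerVector> px(n);
  std::vector<int> rmin(n), rmax(n), cmin(n), cmax(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pixels[i];
    int r0 = H, r1 = -1, c0 = INT_MAX, c1 = -1;
    for (int id : px[i]) {
      const int r = (id - 1) % H, c = (id - 1) / H;
      r0 = std::min(r0, r); r1 = std::max(r1, r);
      c0 = std::min(c0, c); c1 = std::max(c1, c);
    }
    rmin[i] = r0; rmax[i] = r1; cmin[i] = c0; cmax[i] = c1;
  }
  DSU dsu(n);
  const double cd2 = centroid_dist * centroid_dist;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dr = cr[i] - cr[j], dc = cc[i] - cc[j];
      const bool near = dr * dr + dc * dc < cd2;
      if (near) { dsu.unite(i, j); continue; }
      // Overlap branches need intersecting masks, hence overlapping boxes.
      if (rmax[i] < rmin[j] || rmax[j] < rmin[i] ||
          cmax[i] < cmin[j] || cmax[j] < cmin[i])
        continue;
      const int inter = intersect_size(px[i], px[j]);
      if (inter == 0) continue;
      const double uni = area[i] + area[j] - inter;
      const int smaller = std::min(area[i], area[j]);
      if (inter / uni > 0.5 || (double)inter / smaller > 0.75) dsu.unite(i, j);
    }
  }
  IntegerVector group(n);
  std::vector<int> relabel(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    const int root = dsu.find(i);
    if (relabel[root] == 0) relabel[root] = ++next;
    group[i] = relabel[root];
  }
  return group;
}
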