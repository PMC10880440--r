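// Shallow U-Net (3 levels, 3x3 convs, max-pool / nearest-upsample, sigmoid
// head) with hand-written forward and backward passes. The networks are tiny
// (<10k parameters) and run on CPU; feature maps are arma::cube (H, W, C).
//
// Convolution convention (cross-correlation, zero padding, "same" output):
//   y(r,c,o) = b(o) + sum_{i,du,dv in {-1,0,1}} w(du,dv,i,o) * x(r+du, c+dv, i)
// Weight layout in the flat parameter vector, per layer:
//   w index = ((o*ci + i)*3 + (dv+1))*3 + (du+1), followed by ci biases.
// Dropout draws come from R's RNG so set.seed() governs everything.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;

static const double CLIP_EPS = 1e-7;

struct ConvShape {
  int ci, co;
  int nw() const { return 9 * ci * co; }
  int nb() const { return co; }
};

// Layer order: enc1, enc2, enc3, bottleneck, dec3, dec2, dec1, out
static std::vector<ConvShape> conv_shapes(const IntegerVector& enc, int bott,
                                          const IntegerVector& dec) {
  std::vector<ConvShape> s;
  s.push_back({1, enc[0]});
  s.push_back({enc[0], enc[1]});
  s.push_back({enc[1], enc[2]});
  s.push_back({enc[2], bott});
  s.push_back({bott + enc[2], dec[0]});
  s.push_back({dec[0] + enc[1], dec[1]});
  s.push_back({dec[1] + enc[0], dec[2]});
  s.push_back({dec[2], 1});
  return s;
}

// [[Rcpp::export]]
int cpp_unet_nparam(IntegerVector enc, int bott, IntegerVector dec) {
  int n = 0;
  for (const ConvShape& cs : conv_shapes(enc, bott, dec)) n += cs.nw() + cs.nb();
  return n;
}

// One row per conv layer: n_weights, n_biases, fan_in (= 9 * in_channels)
// [[Rcpp::export]]
IntegerMatrix cpp_unet_layers(IntegerVector enc, int bott, IntegerVector dec) {
  std::vector<ConvShape> s = conv_shapes(enc, bott, dec);
  IntegerMatrix out(s.size(), 3);
  for (size_t l = 0; l < s.size(); ++l) {
    out(l, 0) = s[l].nw();
    out(l, 1) = s[l].nb();
    out(l, 2) = 9 * s[l].ci;
  }
  colnames(out) = CharacterVector::create("n_weights", "n_biases", "fan_in");
  return out;
}

static void conv3x3_forward(const cube& x, const double* W, const double* b,
                            cube& y) {
  const int H = x.n_rows, Wd = x.n_cols, ci = x.n_slices, co = y.n_slices;
  for (int o = 0; o < co; ++o) {
    mat& ys = y.slice(o);
    ys.fill(b[o]);
    for (int i = 0; i < ci; ++i) {
      const mat& xs = x.slice(i);
      const double* wk = W + (o * ci + i) * 9;
      for (int dv = -1; dv <= 1; ++dv) {
        for (int du = -1; du <= 1; ++du) {
          const double w = wk[(dv + 1) * 3 + (du + 1)];
          const int r0 = std::max(0, -du), r1 = std::min(H - 1, H - 1 - du);
          const int c0 = std::max(0, -dv), c1 = std::min(Wd - 1, Wd - 1 - dv);
          if (r0 > r1 || c0 > c1) continue;
          ys.submat(r0, c0, r1, c1) +=
              w * xs.submat(r0 + du, c0 + dv, r1 + du, c1 + dv);
        }
      }
    }
  }
}

// Accumulates dW/db; overwrites dx (caller zeroes it).
static void conv3x3_backward(const cube& x, const double* W, const cube& dy,
                             cube& dx, double* dW, double* db) {
  const int H = x.n_rows, Wd = x.n_cols, ci = x.n_slices, co = dy.n_slices;
  for (int o = 0; o < co; ++o) {
    const mat& dys = dy.slice(o);
    db[o] += arma::accu(dys);
    for (int i = 0; i < ci; ++i) {
      const mat& xs = x.slice(i);
      mat& dxs = dx.slice(i);
      const double* wk = W + (o * ci + i) * 9;
      double* dwk = dW + (o * ci + i) * 9;
      for (int dv = -1; dv <= 1; ++dv) {
        for (int du = -1; du <= 1; ++du) {
          const int r0 = std::max(0, -du), r1 = std::min(H - 1, H - 1 - du);
          const int c0 = std::max(0, -dv), c1 = std::min(Wd - 1, Wd - 1 - dv);
          if (r0 > r1 || c0 > c1) continue;
          dwk[(dv + 1) * 3 + (du + 1)] += arma::accu(
              xs.submat(r0 + du, c0 + dv, r1 + du, c1 + dv) %
              dys.submat(r0, c0, r1, c1));
          dxs.submat(r0 + du, c0 + dv, r1 + du, c1 + dv) +=
              wk[(dv + 1) * 3 + (du + 1)] * dys.submat(r0, c0, r1, c1);
        }
      }
    }
  }
}

static void maxpool2(const cube& x, cube& y, arma::ucube& amax) {
  const int Ho = y.n_rows, Wo = y.n_cols, C = x.n_slices;
  for (int ch = 0; ch < C; ++ch) {
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        double best = x(2 * r, 2 * c, ch);
        unsigned which = 0;
        const double v1 = x(2 * r + 1, 2 * c, ch);
        const double v2 = x(2 * r, 2 * c + 1, ch);
        const double v3 = x(2 * r + 1, 2 * c + 1, ch);
        if (v1 > best) { best = v1; which = 1; }
        if (v2 > best) { best = v2; which = 2; }
        if (v3 > best) { best = v3; which = 3; }
        y(r, c, ch) = best;
        amax(r, c, ch) = which;
      }
    }
  }
}

static void maxpool2_backward(const cube& dy, const arma::ucube& amax, cube& dx) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  dx.zeros();
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r) {
        const unsigned w = amax(r, c, ch);
        dx(2 * r + (w & 1u), 2 * c + (w >> 1), ch) += dy(r, c, ch);
      }
}

static void upsample2(const cube& x, cube& y) {
  const int Hi = x.n_rows, Wi = x.n_cols, C = x.n_slices;
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < Wi; ++c)
      for (int r = 0; r < Hi; ++r) {
        const double v = x(r, c, ch);
        y(2 * r, 2 * c, ch) = v;
        y(2 * r + 1, 2 * c, ch) = v;
        y(2 * r, 2 * c + 1, ch) = v;
        y(2 * r + 1, 2 * c + 1, ch) = v;
      }
}

static void upsample2_backward(const cube& dy, cube& dx) {
  const int Hi = dx.n_rows, Wi = dx.n_cols, C = dx.n_slices;
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < Wi; ++c)
      for (int r = 0; r < Hi; ++r)
        dx(r, c, ch) = dy(2 * r, 2 * c, ch) + dy(2 * r + 1, 2 * c, ch) +
                       dy(2 * r, 2 * c + 1, ch) + dy(2 * r + 1, 2 * c + 1, ch);
}

// ReLU followed by inverted dropout; `gate` stores d(out)/d(pre-activation)
// so the backward pass is a single elementwise product.
static void relu_dropout(cube& a, cube& gate, double p_drop, bool training) {
  const arma::uword n = a.n_elem;
  double* av = a.memptr();
  double* gv = gate.memptr();
  if (training && p_drop > 0) {
    const double scale = 1.0 / (1.0 - p_drop);
    for (arma::uword j = 0; j < n; ++j) {
      if (av[j] <= 0) { av[j] = 0; gv[j] = 0; continue; }
      if (R::unif_rand() < p_drop) { av[j] = 0; gv[j] = 0; }
      else { av[j] *= scale; gv[j] = scale; }
    }
  } else {
    for (arma::uword j = 0; j < n; ++j) {
      if (av[j] <= 0) { av[j] = 0; gv[j] = 0; }
      else gv[j] = 1.0;
    }
  }
}

struct Work {
  // Activations (post ReLU/dropout) and gates at each stage, one frame.
  cube a0, a1, p1, a2, p2, a3, p3, ab;
  cube u3, cat3, d3, u2, cat2, d2, u1, cat1, d1, prob;
  cube g1, g2, g3, gb, gd3, gd2, gd1;
  arma::ucube i1, i2, i3;
};

struct Offsets {
  std::vector<int> w_off, b_off;
};

static Offsets layer_offsets(const std::vector<ConvShape>& s) {
  Offsets o;
  int pos = 0;
  for (const ConvShape& cs : s) {
    o.w_off.push_back(pos);
    pos += cs.nw();
    o.b_off.push_back(pos);
    pos += cs.nb();
  }
  return o;
}

static void unet_forward_one(const double* par, const std::vector<ConvShape>& s,
                             const Offsets& off, const mat& x, double d1r,
                             double d2r, double d3r, bool training, Work& w) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int c1 = s[0].co, c2 = s[1].co, c3 = s[2].co, cb = s[3].co;
  const int e3 = s[4].co, e2 = s[5].co, e1 = s[6].co;
  w.a0 = cube(H, Wd, 1);
  w.a0.slice(0) = x;

  w.a1.set_size(H, Wd, c1); w.g1.set_size(H, Wd, c1);
  conv3x3_forward(w.a0, par + off.w_off[0], par + off.b_off[0], w.a1);
  relu_dropout(w.a1, w.g1, d1r, training);
  w.p1.set_size(H / 2, Wd / 2, c1); w.i1.set_size(H / 2, Wd / 2, c1);
  maxpool2(w.a1, w.p1, w.i1);

  w.a2.set_size(H / 2, Wd / 2, c2); w.g2.set_size(H / 2, Wd / 2, c2);
  conv3x3_forward(w.p1, par + off.w_off[1], par + off.b_off[1], w.a2);
  relu_dropout(w.a2, w.g2, d2r, training);
  w.p2.set_size(H / 4, Wd / 4, c2); w.i2.set_size(H / 4, Wd / 4, c2);
  maxpool2(w.a2, w.p2, w.i2);

  w.a3.set_size(H / 4, Wd / 4, c3); w.g3.set_size(H / 4, Wd / 4, c3);
  conv3x3_forward(w.p2, par + off.w_off[2], par + off.b_off[2], w.a3);
  relu_dropout(w.a3, w.g3, d3r, training);
  w.p3.set_size(H / 8, Wd / 8, c3); w.i3.set_size(H / 8, Wd / 8, c3);
  maxpool2(w.a3, w.p3, w.i3);

  w.ab.set_size(H / 8, Wd / 8, cb); w.gb.set_size(H / 8, Wd / 8, cb);
  conv3x3_forward(w.p3, par + off.w_off[3], par + off.b_off[3], w.ab);
  relu_dropout(w.ab, w.gb, 0.0, false);

  w.u3.set_size(H / 4, Wd / 4, cb);
  upsample2(w.ab, w.u3);
  w.cat3 = arma::join_slices(w.u3, w.a3);
  w.d3.set_size(H / 4, Wd / 4, e3); w.gd3.set_size(H / 4, Wd / 4, e3);
  conv3x3_forward(w.cat3, par + off.w_off[4], par + off.b_off[4], w.d3);
  relu_dropout(w.d3, w.gd3, 0.0, false);

  w.u2.set_size(H / 2, Wd / 2, e3);
  upsample2(w.d3, w.u2);
  w.cat2 = arma::join_slices(w.u2, w.a2);
  w.d2.set_size(H / 2, Wd / 2, e2); w.gd2.set_size(H / 2, Wd / 2, e2);
  conv3x3_forward(w.cat2, par + off.w_off[5], par + off.b_off[5], w.d2);
  relu_dropout(w.d2, w.gd2, 0.0, false);

  w.u1.set_size(H, Wd, e2);
  upsample2(w.d2, w.u1);
  w.cat1 = arma::join_slices(w.u1, w.a1);
  w.d1.set_size(H, Wd, e1); w.gd1.set_size(H, Wd, e1);
  conv3x3_forward(w.cat1, par + off.w_off[6], par + off.b_off[6], w.d1);
  relu_dropout(w.d1, w.gd1, 0.0, false);

  w.prob.set_size(H, Wd, 1);
  conv3x3_forward(w.d1, par + off.w_off[7], par + off.b_off[7], w.prob);
  w.prob.transform([](double z) { return 1.0 / (1.0 + std::exp(-z)); });
}

// dprob = dL/d(prob); accumulates into grad.
static void unet_backward_one(const double* par, const std::vector<ConvShape>& s,
                              const Offsets& off, const Work& w,
                              const mat& dprob, double* grad) {
  const int H = w.a0.n_rows, Wd = w.a0.n_cols;
  cube dz(H, Wd, 1);
  dz.slice(0) = dprob % w.prob.slice(0) % (1.0 - w.prob.slice(0));

  cube dd1(H, Wd, s[6].co, arma::fill::zeros);
  conv3x3_backward(w.d1, par + off.w_off[7], dz, dd1,
                   grad + off.w_off[7], grad + off.b_off[7]);
  dd1 %= w.gd1;

  cube dcat1(H, Wd, w.cat1.n_slices, arma::fill::zeros);
  conv3x3_backward(w.cat1, par + off.w_off[6], dd1, dcat1,
                   grad + off.w_off[6], grad + off.b_off[6]);
  const int e2 = s[5].co, c1 = s[0].co;
  cube du1 = dcat1.slices(0, e2 - 1);
  cube da1_skip = dcat1.slices(e2, e2 + c1 - 1);
  cube dd2(H / 2, Wd / 2, e2);
  upsample2_backward(du1, dd2);
  dd2 %= w.gd2;

  cube dcat2(H / 2, Wd / 2, w.cat2.n_slices, arma::fill::zeros);
  conv3x3_backward(w.cat2, par + off.w_off[5], dd2, dcat2,
                   grad + off.w_off[5], grad + off.b_off[5]);
  const int e3 = s[4].co, c2 = s[1].co;
  cube du2 = dcat2.slices(0, e3 - 1);
  cube da2_skip = dcat2.slices(e3, e3 + c2 - 1);
  cube dd3(H / 4, Wd / 4, e3);
  upsample2_backward(du2, dd3);
  dd3 %= w.gd3;

  cube dcat3(H / 4, Wd / 4, w.cat3.n_slices, arma::fill::zeros);
  conv3x3_backward(w.cat3, par + off.w_off[4], dd3, dcat3,
                   grad + off.w_off[4], grad + off.b_off[4]);
  const int cb = s[3].co, c3 = s[2].co;
  cube du3 = dcat3.slices(0, cb - 1);
  cube da3_skip = dcat3.slices(cb, cb + c3 - 1);
  cube dab(H / 8, Wd / 8, cb);
  upsample2_backward(du3, dab);
  dab %= w.gb;

  cube dp3(H / 8, Wd / 8, c3, arma::fill::zeros);
  conv3x3_backward(w.p3, par + off.w_off[3], dab, dp3,
                   grad + off.w_off[3], grad + off.b_off[3]);
  cube da3(H / 4, Wd / 4, c3);
  maxpool2_backward(dp3, w.i3, da3);
  da3 += da3_skip;
  da3 %= w.g3;

  cube dp2(H / 4, Wd / 4, c2, arma::fill::zeros);
  conv3x3_backward(w.p2, par + off.w_off[2], da3, dp2,
                   grad + off.w_off[2], grad + off.b_off[2]);
  cube da2(H / 2, Wd / 2, c2);
  maxpool2_backward(dp2, w.i2, da2);
  da2 += da2_skip;
  da2 %= w.g2;

  cube dp1(H / 2, Wd / 2, c1, arma::fill::zeros);
  conv3x3_backward(w.p1, par + off.w_off[1], da2, dp1,
                   grad + off.w_off[1], grad + off.b_off[1]);
  cube da1(H, Wd, c1);
  maxpool2_backward(dp1, w.i1, da1);
  da1 += da1_skip;
  da1 %= w.g1;

  cube da0(H, Wd, 1, arma::fill::zeros);
  conv3x3_backward(w.a0, par + off.w_off[0], da1, da0,
                   grad + off.w_off[0], grad + off.b_off[0]);
}

static void check_input(int H, int W, int npar, int need) {
  if (H % 8 != 0 || W % 8 != 0)
    stop("input height/width must be multiples of 8 (got %dx%d)", H, W);
  if (npar != need)
    stop("parameter vector has length %d, expected %d", npar, need);
}

// [[Rcpp::export]]
NumericVector cpp_unet_forward(NumericVector params, IntegerVector enc,
                               int bott, IntegerVector dec, NumericVector x,
                               bool training, NumericVector dropout) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 3) stop("input must be an H x W x B array");
  const int H = dim[0], W = dim[1], B = dim[2];
  std::vector<ConvShape> s = conv_shapes(enc, bott, dec);
  check_input(H, W, params.size(), cpp_unet_nparam(enc, bott, dec));
  Offsets off = layer_offsets(s);
  NumericVector out(H * W * B);
  out.attr("dim") = dim;
  Work w;
  for (int bi = 0; bi < B; ++bi) {
    mat xf(const_cast<double*>(x.begin()) + (size_t)bi * H * W, H, W, false);
    unet_forward_one(params.begin(), s, off, xf, dropout[0], dropout[1],
                     dropout[2], training, w);
    std::copy(w.prob.memptr(), w.prob.memptr() + H * W,
              out.begin() + (size_t)bi * H * W);
  }
  return out;
}

// loss_type: 0 = focal + dice_weight*dice (binary targets),
//            1 = binary cross-entropy against soft targets.
// Loss is the mean over frames of the per-frame loss.
// [[Rcpp::export]]
List cpp_unet_grad(NumericVector params, IntegerVector enc, int bott,
                   IntegerVector dec, NumericVector x, NumericVector y,
                   int loss_type, double gamma, double alpha,
                   double dice_weight, double dice_smooth, bool training,
                   NumericVector dropout) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 3) stop("input must be an H x W x B array");
  const int H = dim[0], W = dim[1], B = dim[2];
  if (y.size() != x.size()) stop("target shape must match input shape");
  std::vector<ConvShape> s = conv_shapes(enc, bott, dec);
  check_input(H, W, params.size(), cpp_unet_nparam(enc, bott, dec));
  Offsets off = layer_offsets(s);

  NumericVector grad(params.size());
  double loss = 0.0;
  const int N = H * W;
  Work w;
  mat dprob(H, W);

  for (int bi = 0; bi < B; ++bi) {
    mat xf(const_cast<double*>(x.begin()) + (size_t)bi * H * W, H, W, false);
    mat yf(const_cast<double*>(y.begin()) + (size_t)bi * H * W, H, W, false);
    unet_forward_one(params.begin(), s, off, xf, dropout[0], dropout[1],
                     dropout[2], training, w);
    const mat& p = w.prob.slice(0);

    if (loss_type == 1) {
      double L = 0.0;
      for (int j = 0; j < N; ++j) {
        const double pj = p(j), yj = yf(j);
        const double c = std::min(std::max(pj, CLIP_EPS), 1.0 - CLIP_EPS);
        L += -(yj * std::log(c) + (1.0 - yj) * std::log(1.0 - c));
        dprob(j) = (pj > CLIP_EPS && pj < 1.0 - CLIP_EPS)
                       ? (-(yj / c) + (1.0 - yj) / (1.0 - c)) / N
                       : 0.0;
      }
      loss += L / N;
    } else {
      double Lf = 0.0, S = 0.0, P = 0.0, Y = 0.0;
      for (int j = 0; j < N; ++j) {
        const double pj = p(j), yj = yf(j);
        const double pt = (yj > 0.5) ? pj : 1.0 - pj;
        const double c = std::min(std::max(pt, CLIP_EPS), 1.0 - CLIP_EPS);
        Lf += -alpha * std::pow(1.0 - c, gamma) * std::log(c);
        double dpt = 0.0;
        if (pt > CLIP_EPS && pt < 1.0 - CLIP_EPS) {
          dpt = -alpha * (std::pow(1.0 - c, gamma) / c -
                          (gamma > 0 ? gamma * std::pow(1.0 - c, gamma - 1.0) *
                                           std::log(c)
                                     : 0.0));
        }
        dprob(j) = ((yj > 0.5) ? dpt : -dpt) / N;
        S += pj * yj;
        P += pj;
        Y += yj;
      }
      const double denom = P + Y + dice_smooth;
      const double Ld = 1.0 - (2.0 * S + dice_smooth) / denom;
      for (int j = 0; j < N; ++j)
        dprob(j) += dice_weight *
                    (-(2.0 * yf(j) * denom - (2.0 * S + dice_smooth)) /
                     (denom * denom));
      loss += Lf / N + dice_weight * Ld;
    }
    dprob /= B;
    unet_backward_one(params.begin(), s, off, w, dprob, grad.begin());
  }
  return List::create(_["loss"] = loss / B, _["grad"] = grad);
}
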