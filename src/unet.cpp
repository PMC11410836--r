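// Compact U-net style encoder-decoder for bone-axis heatmap regression.
//
// Layout: n_levels resolution levels; one 3x3 conv + ReLU per encoder
// level with 2x2 max pooling in between; decoder levels do nearest 2x
// upsampling, concatenate the encoder skip, and apply one 3x3 conv +
// ReLU; a final 1x1 conv with sigmoid produces the 6 heatmap channels in
// [0,1]. Convolutions run as im2col GEMM. Loss is the per-image RMSE
// averaged over the minibatch; optimization is Adam with early stopping
// on a validation set.
//
// Activations are cubes (width x height x channels); weights for a 3x3
// conv with C_in inputs and C_out outputs form a (9*C_in) x C_out matrix
// whose rows are ordered channel-major, then dy, then dx (see im2col3).

#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <string>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

struct Conv {
  mat W;
  vec b;
};

struct Net {
  int n_levels;
  std::vector<Conv> enc;  // n_levels
  std::vector<Conv> dec;  // n_levels - 1 (index l = level, 0 = finest)
  Conv out;               // 1x1 conv
};

static Net net_from_list(const List& weights, int n_levels) {
  Net net;
  net.n_levels = n_levels;
  for (int l = 0; l < n_levels; ++l) {
    std::string base = "enc" + std::to_string(l + 1);
    Conv c;
    c.W = Rcpp::as<mat>(weights[base + "_W"]);
    c.b = Rcpp::as<vec>(weights[base + "_b"]);
    net.enc.push_back(c);
  }
  for (int l = 0; l < n_levels - 1; ++l) {
    std::string base = "dec" + std::to_string(l + 1);
    Conv c;
    c.W = Rcpp::as<mat>(weights[base + "_W"]);
    c.b = Rcpp::as<vec>(weights[base + "_b"]);
    net.dec.push_back(c);
  }
  net.out.W = Rcpp::as<mat>(weights["out_W"]);
  net.out.b = Rcpp::as<vec>(weights["out_b"]);
  return net;
}

static List net_to_list(const Net& net) {
  List out;
  for (int l = 0; l < net.n_levels; ++l) {
    std::string base = "enc" + std::to_string(l + 1);
    out[base + "_W"] = net.enc[l].W;
    out[base + "_b"] = net.enc[l].b;
  }
  for (int l = 0; l < net.n_levels - 1; ++l) {
    std::string base = "dec" + std::to_string(l + 1);
    out[base + "_W"] = net.dec[l].W;
    out[base + "_b"] = net.dec[l].b;
  }
  out["out_W"] = net.out.W;
  out["out_b"] = net.out.b;
  return out;
}

// im2col for a 3x3 same-padded convolution: (W*H) x (9*C) matrix.
// Column order: for each input channel c, for each dy in {-1,0,1}, for
// each dx in {-1,0,1}.
static mat im2col3(const cube& x) {
  const int W = x.n_rows, H = x.n_cols, C = x.n_slices;
  mat out(W * H, 9 * C, fill::zeros);
  int col = 0;
  mat tmp(W, H);
  for (int c = 0; c < C; ++c) {
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx, ++col) {
        tmp.zeros();
        const int x0 = std::max(0, -dx), x1 = W - 1 - std::max(0, dx);
        const int y0 = std::max(0, -dy), y1 = H - 1 - std::max(0, dy);
        if (x0 <= x1 && y0 <= y1) {
          tmp.submat(x0, y0, x1, y1) =
            x.slice(c).submat(x0 + dx, y0 + dy, x1 + dx, y1 + dy);
        }
        out.col(col) = vectorise(tmp);
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-add column gradients back to input shape.
static cube col2im3(const mat& cols, int W, int H, int C) {
  cube out(W, H, C, fill::zeros);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx, ++col) {
        const mat tmp = reshape(cols.col(col), W, H);
        const int x0 = std::max(0, -dx), x1 = W - 1 - std::max(0, dx);
        const int y0 = std::max(0, -dy), y1 = H - 1 - std::max(0, dy);
        if (x0 <= x1 && y0 <= y1) {
          out.slice(c).submat(x0 + dx, y0 + dy, x1 + dx, y1 + dy) +=
            tmp.submat(x0, y0, x1, y1);
        }
      }
    }
  }
  return out;
}

static cube cols_to_cube(const mat& Z, int W, int H) {
  cube out(W, H, Z.n_cols);
  for (uword k = 0; k < Z.n_cols; ++k) {
    out.slice(k) = reshape(Z.col(k), W, H);
  }
  return out;
}

static mat cube_to_cols(const cube& x) {
  mat out(x.n_rows * x.n_cols, x.n_slices);
  for (uword k = 0; k < x.n_slices; ++k) {
    out.col(k) = vectorise(x.slice(k));
  }
  return out;
}

// 2x2 max pooling; idx stores which corner (0..3 = dx + 2*dy) won.
static cube maxpool2(const cube& x, ucube& idx) {
  const int W = x.n_rows / 2, H = x.n_cols / 2, C = x.n_slices;
  cube out(W, H, C);
  idx.set_size(W, H, C);
  for (int c = 0; c < C; ++c) {
    for (int y = 0; y < H; ++y) {
      for (int xx = 0; xx < W; ++xx) {
        double best = x(2 * xx, 2 * y, c);
        uword bi = 0;
        for (int dy = 0; dy < 2; ++dy) {
          for (int dx = 0; dx < 2; ++dx) {
            const double v = x(2 * xx + dx, 2 * y + dy, c);
            if (v > best) { best = v; bi = dx + 2 * dy; }
          }
        }
        out(xx, y, c) = best;
        idx(xx, y, c) = bi;
      }
    }
  }
  return out;
}

static cube maxpool2_back(const cube& grad, const ucube& idx,
                          int W, int H) {
  cube out(W, H, grad.n_slices, fill::zeros);
  for (uword c = 0; c < grad.n_slices; ++c) {
    for (uword y = 0; y < grad.n_cols; ++y) {
      for (uword xx = 0; xx < grad.n_rows; ++xx) {
        const uword bi = idx(xx, y, c);
        out(2 * xx + (bi % 2), 2 * y + (bi / 2), c) += grad(xx, y, c);
      }
    }
  }
  return out;
}

static cube upsample2(const cube& x) {
  const int W = x.n_rows, H = x.n_cols, C = x.n_slices;
  cube out(2 * W, 2 * H, C);
  for (int c = 0; c < C; ++c) {
    for (int y = 0; y < H; ++y) {
      for (int xx = 0; xx < W; ++xx) {
        const double v = x(xx, y, c);
        out(2 * xx, 2 * y, c) = v;
        out(2 * xx + 1, 2 * y, c) = v;
        out(2 * xx, 2 * y + 1, c) = v;
        out(2 * xx + 1, 2 * y + 1, c) = v;
      }
    }
  }
  return out;
}

static cube upsample2_back(const cube& grad) {
  const int W = grad.n_rows / 2, H = grad.n_cols / 2, C = grad.n_slices;
  cube out(W, H, C);
  for (int c = 0; c < C; ++c) {
    for (int y = 0; y < H; ++y) {
      for (int xx = 0; xx < W; ++xx) {
        out(xx, y, c) = grad(2 * xx, 2 * y, c) +
          grad(2 * xx + 1, 2 * y, c) + grad(2 * xx, 2 * y + 1, c) +
          grad(2 * xx + 1, 2 * y + 1, c);
      }
    }
  }
  return out;
}

struct Cache {
  std::vector<mat> enc_cols;   // im2col input of each encoder conv
  std::vector<cube> enc_act;   // post-ReLU encoder activations
  std::vector<ucube> pool_idx; // argmax of each pooling (n_levels - 1)
  std::vector<mat> dec_cols;   // im2col of each decoder concat input
  std::vector<cube> dec_act;   // post-ReLU decoder activations
  mat out_in;                  // flattened input of the 1x1 conv
  cube pred;                   // sigmoid output
};

static cube forward(const Net& net, const mat& image, Cache* cache) {
  const int NL = net.n_levels;
  cube a(image.n_rows, image.n_cols, 1);
  a.slice(0) = image;
  std::vector<cube> enc_act(NL);
  if (cache) {
    cache->enc_cols.resize(NL);
    cache->pool_idx.resize(NL - 1);
    cache->dec_cols.resize(NL - 1);
    cache->dec_act.resize(NL - 1);
  }
  for (int l = 0; l < NL; ++l) {
    mat cols = im2col3(a);
    mat Z = cols * net.enc[l].W;
    Z.each_row() += net.enc[l].b.t();
    Z.transform([](double v) { return v > 0 ? v : 0.0; });
    enc_act[l] = cols_to_cube(Z, a.n_rows, a.n_cols);
    if (cache) cache->enc_cols[l] = std::move(cols);
    if (l < NL - 1) {
      ucube idx;
      a = maxpool2(enc_act[l], idx);
      if (cache) cache->pool_idx[l] = std::move(idx);
    }
  }
  cube d = enc_act[NL - 1];
  for (int l = NL - 2; l >= 0; --l) {
    cube cat = join_slices(upsample2(d), enc_act[l]);
    mat cols = im2col3(cat);
    mat Z = cols * net.dec[l].W;
    Z.each_row() += net.dec[l].b.t();
    Z.transform([](double v) { return v > 0 ? v : 0.0; });
    d = cols_to_cube(Z, cat.n_rows, cat.n_cols);
    if (cache) {
      cache->dec_cols[l] = std::move(cols);
      cache->dec_act[l] = d;
    }
  }
  mat flat = cube_to_cols(d);
  mat Zo = flat * net.out.W;
  Zo.each_row() += net.out.b.t();
  Zo.transform([](double v) { return 1.0 / (1.0 + std::exp(-v)); });
  cube pred = cols_to_cube(Zo, d.n_rows, d.n_cols);
  if (cache) {
    cache->enc_act = std::move(enc_act);
    cache->out_in = std::move(flat);
    cache->pred = pred;
  }
  return pred;
}

// Accumulate gradients for one image given dL/dpred; returns nothing,
// adds into `grad` (same structure as the network weights).
static void backward(const Net& net, const Cache& cache, const cube& dpred,
                     Net& grad) {
  const int NL = net.n_levels;
  // sigmoid output layer
  mat dZo = cube_to_cols(dpred % (cache.pred % (1.0 - cache.pred)));
  grad.out.W += cache.out_in.t() * dZo;
  grad.out.b += sum(dZo, 0).t();
  mat dflat = dZo * net.out.W.t();
  cube dd = cols_to_cube(dflat, cache.pred.n_rows, cache.pred.n_cols);

  std::vector<cube> dskip(NL);  // gradient flowing into enc_act via skips
  for (int l = 0; l < NL - 1; ++l) {
    // backward through decoder level l (finest processed last in forward)
    const cube& act = cache.dec_act[l];
    cube dZ = dd;
    for (uword i = 0; i < dZ.n_elem; ++i) {
      if (act(i) <= 0) dZ(i) = 0;
    }
    mat dZcols = cube_to_cols(dZ);
    grad.dec[l].W += cache.dec_cols[l].t() * dZcols;
    grad.dec[l].b += sum(dZcols, 0).t();
    mat dcat_cols = dZcols * net.dec[l].W.t();
    const int C_up = net.enc[l + 1].W.n_cols;  // channels of upsampled input
    const int C_skip = net.enc[l].W.n_cols;
    cube dcat = col2im3(dcat_cols, act.n_rows, act.n_cols, C_up + C_skip);
    dskip[l] = dcat.slices(C_up, C_up + C_skip - 1);
    dd = upsample2_back(dcat.slices(0, C_up - 1));
  }
  // encoder chain, deepest first; dd currently holds the gradient at the
  // bottleneck activation
  cube dabove;
  for (int l = NL - 1; l >= 0; --l) {
    cube de = (l == NL - 1) ? dd : dskip[l];
    if (l < NL - 1) {
      de += maxpool2_back(dabove, cache.pool_idx[l],
                          de.n_rows, de.n_cols);
    }
    const cube& act = cache.enc_act[l];
    for (uword i = 0; i < de.n_elem; ++i) {
      if (act(i) <= 0) de(i) = 0;
    }
    mat dZcols = cube_to_cols(de);
    grad.enc[l].W += cache.enc_cols[l].t() * dZcols;
    grad.enc[l].b += sum(dZcols, 0).t();
    if (l > 0) {
      const int C_in = net.enc[l].W.n_rows / 9;
      mat dcols = dZcols * net.enc[l].W.t();
      dabove = col2im3(dcols, de.n_rows, de.n_cols, C_in);
    }
  }
}

static Net zeros_like(const Net& net) {
  Net g = net;
  for (auto& c : g.enc) { c.W.zeros(); c.b.zeros(); }
  for (auto& c : g.dec) { c.W.zeros(); c.b.zeros(); }
  g.out.W.zeros();
  g.out.b.zeros();
  return g;
}

struct Adam {
  Net m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  explicit Adam(const Net& net) : m(zeros_like(net)), v(zeros_like(net)) {}
  void step_one(mat& w, mat& mw, mat& vw, const mat& g, double lr) {
    mw = b1 * mw + (1 - b1) * g;
    vw = b2 * vw + (1 - b2) * (g % g);
    const double c1 = 1 - std::pow(b1, (double)t);
    const double c2 = 1 - std::pow(b2, (double)t);
    w -= lr * (mw / c1) / (sqrt(vw / c2) + eps);
  }
  void step_vec(vec& w, vec& mw, vec& vw, const vec& g, double lr) {
    mw = b1 * mw + (1 - b1) * g;
    vw = b2 * vw + (1 - b2) * (g % g);
    const double c1 = 1 - std::pow(b1, (double)t);
    const double c2 = 1 - std::pow(b2, (double)t);
    w -= lr * (mw / c1) / (sqrt(vw / c2) + eps);
  }
  void update(Net& net, const Net& g, double lr) {
    ++t;
    for (size_t l = 0; l < net.enc.size(); ++l) {
      step_one(net.enc[l].W, m.enc[l].W, v.enc[l].W, g.enc[l].W, lr);
      step_vec(net.enc[l].b, m.enc[l].b, v.enc[l].b, g.enc[l].b, lr);
    }
    for (size_t l = 0; l < net.dec.size(); ++l) {
      step_one(net.dec[l].W, m.dec[l].W, v.dec[l].W, g.dec[l].W, lr);
      step_vec(net.dec[l].b, m.dec[l].b, v.dec[l].b, g.dec[l].b, lr);
    }
    step_one(net.out.W, m.out.W, v.out.W, g.out.W, lr);
    step_vec(net.out.b, m.out.b, v.out.b, g.out.b, lr);
  }
};

static double image_rmse(const cube& pred, const cube& target) {
  const cube d = pred - target;
  return std::sqrt(accu(d % d) / d.n_elem);
}

static double eval_set(const Net& net, const std::vector<mat>& xs,
                       const std::vector<cube>& ys) {
  double total = 0;
  for (size_t i = 0; i < xs.size(); ++i) {
    total += image_rmse(forward(net, xs[i], nullptr), ys[i]);
  }
  return total / xs.size();
}

static std::vector<mat> mats_from_list(const List& lst) {
  std::vector<mat> out;
  out.reserve(lst.size());
  for (R_xlen_t i = 0; i < lst.size(); ++i) {
    out.push_back(Rcpp::as<mat>(lst[i]));
  }
  return out;
}

static std::vector<cube> cubes_from_list(const List& lst) {
  std::vector<cube> out;
  out.reserve(lst.size());
  for (R_xlen_t i = 0; i < lst.size(); ++i) {
    out.push_back(Rcpp::as<cube>(lst[i]));
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_unet_forward(Rcpp::List weights, arma::mat image,
                            int n_levels) {
  const Net net = net_from_list(weights, n_levels);
  return forward(net, image, nullptr);
}

// Analytic gradient of the per-image RMSE for one (image, target) pair;
// used by the finite-difference correctness tests.
// [[Rcpp::export]]
Rcpp::List cpp_unet_grad(Rcpp::List weights, arma::mat image,
                         arma::cube target, int n_levels) {
  const Net net = net_from_list(weights, n_levels);
  Cache cache;
  const cube pred = forward(net, image, &cache);
  const double r = image_rmse(pred, target);
  Net grad = zeros_like(net);
  if (r > 0) {
    const cube dpred = (pred - target) / (r * (double)pred.n_elem);
    backward(net, cache, dpred, grad);
  }
  List out = net_to_list(grad);
  out["loss"] = r;
  return out;
}

// [[Rcpp::export]]
double cpp_unet_eval(Rcpp::List weights, Rcpp::List xs, Rcpp::List ys,
                     int n_levels) {
  const Net net = net_from_list(weights, n_levels);
  return eval_set(net, mats_from_list(xs), cubes_from_list(ys));
}

// [[Rcpp::export]]
Rcpp::List cpp_unet_train(Rcpp::List weights, Rcpp::List train_x,
                          Rcpp::List train_y, Rcpp::List val_x,
                          Rcpp::List val_y, int n_levels, double lr,
                          int batch_size, int max_epochs, int val_freq,
                          int patience, int seed) {
  Net net = net_from_list(weights, n_levels);
  const std::vector<mat> tx = mats_from_list(train_x);
  const std::vector<cube> ty = cubes_from_list(train_y);
  const std::vector<mat> vx = mats_from_list(val_x);
  const std::vector<cube> vy = cubes_from_list(val_y);
  const int N = tx.size();
  if (N == 0) Rcpp::stop("empty training set");

  Adam adam(net);
  std::mt19937 rng(seed);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  Net best = net;
  double best_val = datum::inf;
  int since_best = 0;
  long iter = 0;
  bool stop_now = false;
  std::vector<double> h_iter, h_train, h_val;

  for (int epoch = 0; epoch < max_epochs && !stop_now; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int start = 0; start < N && !stop_now; start += batch_size) {
      const int end = std::min(start + batch_size, N);
      Net grad = zeros_like(net);
      double batch_loss = 0;
      for (int k = start; k < end; ++k) {
        const int i = order[k];
        Cache cache;
        const cube pred = forward(net, tx[i], &cache);
        const double r = image_rmse(pred, ty[i]);
        batch_loss += r;
        if (r > 0) {
          const cube dpred = (pred - ty[i]) /
            (r * (double)pred.n_elem * (end - start));
          backward(net, cache, dpred, grad);
        }
      }
      batch_loss /= (end - start);
      adam.update(net, grad, lr);
      ++iter;

      double vloss = NA_REAL;
      if (!vx.empty() && (iter % val_freq == 0)) {
        vloss = eval_set(net, vx, vy);
        if (vloss < best_val) {
          best_val = vloss;
          best = net;
          since_best = 0;
        } else if (++since_best >= patience) {
          stop_now = true;
        }
      }
      h_iter.push_back((double)iter);
      h_train.push_back(batch_loss);
      h_val.push_back(vloss);
      Rcpp::checkUserInterrupt();
    }
  }
  // final validation so the best checkpoint reflects the last state too
  if (!vx.empty()) {
    const double vloss = eval_set(net, vx, vy);
    if (vloss < best_val) {
      best_val = vloss;
      best = net;
    }
  } else {
    best = net;
  }
  return List::create(
    Named("weights") = net_to_list(best),
    Named("final_weights") = net_to_list(net),
    Named("best_val") = best_val,
    Named("iterations") = (double)iter,
    Named("history") = Rcpp::DataFrame::create(
      Named("iteration") = h_iter,
      Named("train_rmse") = h_train,
      Named("val_rmse") = h_val));
}
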