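// Compiled CNN backend: forward/backward passes, SGD-with-momentum training.
//
// The network plan is a list of primitive layers produced by net_plan() on
// the R side:
//   conv : fs, stride, cin, cout (SAME padding, ReLU)
//   mb   : nb branches, cin, cout per branch; branch i uses kernel 2i-1,
//          stride 1, SAME padding, ReLU; outputs concatenated channel-wise
//   pool : pool ("max"/"avg"), fs, stride (VALID padding)
//   gap  : global average pooling to a 1x1xC vector
//   fc   : cin, cout, relu flag (final FC has relu = false)
// A softmax + cross-entropy head is implied after the last fc.
//
// Weights travel as a flat R list of matrices/vectors consumed in plan
// order: each conv/branch contributes (W: cout x fs^2*cin, b: cout), each
// fc contributes (W: cout x cin, b: cout). All arithmetic is single
// precision; determinism comes from the caller (weight init and batch
// order are generated from R's RNG).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::fmat;
using arma::fcube;
using arma::fvec;

namespace {

struct ConvDef { int fs, stride, cin, cout; int widx; };
struct Layer {
  int type;              // 0 conv, 1 mb, 2 pool, 3 gap, 4 fc
  std::vector<ConvDef> convs;  // conv: 1 entry; mb: nb entries
  int pool_type = 0;     // 0 max, 1 avg
  int fs = 0, stride = 1;
  int cin = 0, cout = 0; // fc dims
  int widx = -1;         // index into weights for fc
  bool relu = true;
};

struct Net {
  std::vector<Layer> layers;
  std::vector<fmat> W;
  std::vector<fvec> b;
};

Net build_net(const List& plan, const List& weights) {
  Net net;
  int widx = 0;
  for (int li = 0; li < plan.size(); ++li) {
    List pl = plan[li];
    std::string ty = as<std::string>(pl["type"]);
    Layer L;
    if (ty == "conv" || ty == "mb") {
      L.type = (ty == "conv") ? 0 : 1;
      int nb = (ty == "conv") ? 1 : as<int>(pl["nb"]);
      int cin = as<int>(pl["cin"]);
      int cout = as<int>(pl["cout"]);   // per-branch filters for mb
      int stride = (ty == "conv") ? as<int>(pl["stride"]) : 1;
      for (int bch = 0; bch < nb; ++bch) {
        ConvDef cd;
        cd.fs = (ty == "conv") ? as<int>(pl["fs"]) : (2 * (bch + 1) - 1);
        cd.stride = stride;
        cd.cin = cin;
        cd.cout = cout;
        cd.widx = widx;
        widx += 2;
        L.convs.push_back(cd);
      }
    } else if (ty == "pool") {
      L.type = 2;
      L.pool_type = (as<std::string>(pl["pool"]) == "avg") ? 1 : 0;
      L.fs = as<int>(pl["fs"]);
      L.stride = as<int>(pl["stride"]);
    } else if (ty == "gap") {
      L.type = 3;
    } else if (ty == "fc") {
      L.type = 4;
      L.cin = as<int>(pl["cin"]);
      L.cout = as<int>(pl["cout"]);
      L.relu = as<bool>(pl["relu"]);
      L.widx = widx;
      widx += 2;
    } else {
      stop("unknown plan layer type: %s", ty);
    }
    net.layers.push_back(L);
  }
  if (weights.size() != widx)
    stop("weight list length %d does not match plan (expected %d)",
         (int)weights.size(), widx);
  for (int i = 0; i < widx; i += 2) {
    net.W.push_back(as<fmat>(weights[i]));
    net.b.push_back(as<fvec>(weights[i + 1]));
  }
  return net;
}

inline int same_out(int in, int stride) { return (in + stride - 1) / stride; }

// im2col for SAME zero padding. cols: (fs^2*cin) x (Hout*Wout), row index
// r = c*fs*fs + kw*fs + kh, column index j = ow*Hout + oh.
void im2col_same(const fcube& x, int fs, int stride, fmat& cols,
                 int& Hout, int& Wout) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  Hout = same_out(H, stride);
  Wout = same_out(W, stride);
  const int pad_h = std::max((Hout - 1) * stride + fs - H, 0);
  const int pad_w = std::max((Wout - 1) * stride + fs - W, 0);
  const int pt = pad_h / 2, pl = pad_w / 2;
  cols.zeros(fs * fs * C, Hout * Wout);
  for (int c = 0; c < C; ++c) {
    const fmat& sl = x.slice(c);
    for (int ow = 0; ow < Wout; ++ow) {
      for (int oh = 0; oh < Hout; ++oh) {
        const int j = ow * Hout + oh;
        for (int kw = 0; kw < fs; ++kw) {
          const int iw = ow * stride - pl + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < fs; ++kh) {
            const int ih = oh * stride - pt + kh;
            if (ih < 0 || ih >= H) continue;
            cols(c * fs * fs + kw * fs + kh, j) = sl(ih, iw);
          }
        }
      }
    }
  }
}

void col2im_same(const fmat& dcols, int H, int W, int C, int fs, int stride,
                 fcube& dx) {
  const int Hout = same_out(H, stride), Wout = same_out(W, stride);
  const int pad_h = std::max((Hout - 1) * stride + fs - H, 0);
  const int pad_w = std::max((Wout - 1) * stride + fs - W, 0);
  const int pt = pad_h / 2, pl = pad_w / 2;
  dx.zeros(H, W, C);
  for (int c = 0; c < C; ++c) {
    fmat& sl = dx.slice(c);
    for (int ow = 0; ow < Wout; ++ow) {
      for (int oh = 0; oh < Hout; ++oh) {
        const int j = ow * Hout + oh;
        for (int kw = 0; kw < fs; ++kw) {
          const int iw = ow * stride - pl + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < fs; ++kh) {
            const int ih = oh * stride - pt + kh;
            if (ih < 0 || ih >= H) continue;
            sl(ih, iw) += dcols(c * fs * fs + kw * fs + kh, j);
          }
        }
      }
    }
  }
}

// Per-sample forward cache.
struct Cache {
  std::vector<fcube> in;           // input cube per layer
  std::vector<std::vector<fmat>> cols;   // im2col per conv/branch
  std::vector<std::vector<fmat>> pre;    // pre-ReLU conv output (cout x HW)
  std::vector<arma::umat> argmax;        // max-pool argmax (flat in-index per out cell x C)
  std::vector<fvec> fcin;          // fc input vectors
  std::vector<fvec> fcpre;         // fc pre-activation
  fvec vecact;                     // current vector activation
  bool isvec = false;
};

fvec forward_one(const Net& net, const fcube& x0, Cache* cache) {
  fcube cur = x0;
  fvec v;
  bool isvec = false;
  if (cache) {
    cache->in.resize(net.layers.size());
    cache->cols.resize(net.layers.size());
    cache->pre.resize(net.layers.size());
    cache->argmax.resize(net.layers.size());
    cache->fcin.resize(net.layers.size());
    cache->fcpre.resize(net.layers.size());
  }
  for (size_t li = 0; li < net.layers.size(); ++li) {
    const Layer& L = net.layers[li];
    if (L.type == 0 || L.type == 1) {
      if (cache) cache->in[li] = cur;
      int total_out = 0;
      for (const ConvDef& cd : L.convs) total_out += cd.cout;
      int Hout = 0, Wout = 0;
      fcube out;
      int coff = 0;
      std::vector<fmat> colsv, prev;
      for (const ConvDef& cd : L.convs) {
        fmat cols;
        im2col_same(cur, cd.fs, cd.stride, cols, Hout, Wout);
        fmat o = net.W[cd.widx / 2] * cols;
        o.each_col() += net.b[cd.widx / 2];
        if (coff == 0) out.set_size(Hout, Wout, total_out);
        fmat act = arma::clamp(o, 0.0f, std::numeric_limits<float>::max());
        for (int f = 0; f < cd.cout; ++f)
          out.slice(coff + f) = arma::reshape(act.row(f), Hout, Wout);
        if (cache) { colsv.push_back(std::move(cols)); prev.push_back(std::move(o)); }
        coff += cd.cout;
      }
      if (cache) { cache->cols[li] = std::move(colsv); cache->pre[li] = std::move(prev); }
      cur = std::move(out);
    } else if (L.type == 2) {
      if (cache) cache->in[li] = cur;
      const int H = cur.n_rows, W = cur.n_cols, C = cur.n_slices;
      const int Hout = (H - L.fs) / L.stride + 1;
      const int Wout = (W - L.fs) / L.stride + 1;
      fcube out(Hout, Wout, C);
      arma::umat amax;
      if (L.pool_type == 0) amax.set_size(Hout * Wout, C);
      for (int c = 0; c < C; ++c) {
        const fmat& sl = cur.slice(c);
        for (int ow = 0; ow < Wout; ++ow) {
          for (int oh = 0; oh < Hout; ++oh) {
            const int h0 = oh * L.stride, w0 = ow * L.stride;
            if (L.pool_type == 0) {
              float best = -std::numeric_limits<float>::max();
              int bh = h0, bw = w0;
              for (int kw = 0; kw < L.fs; ++kw)
                for (int kh = 0; kh < L.fs; ++kh) {
                  float val = sl(h0 + kh, w0 + kw);
                  if (val > best) { best = val; bh = h0 + kh; bw = w0 + kw; }
                }
              out(oh, ow, c) = best;
              amax(ow * Hout + oh, c) = (arma::uword)(bw * H + bh);
            } else {
              float s = 0.0f;
              for (int kw = 0; kw < L.fs; ++kw)
                for (int kh = 0; kh < L.fs; ++kh) s += sl(h0 + kh, w0 + kw);
              out(oh, ow, c) = s / (L.fs * L.fs);
            }
          }
        }
      }
      if (cache && L.pool_type == 0) cache->argmax[li] = std::move(amax);
      cur = std::move(out);
    } else if (L.type == 3) {
      if (cache) cache->in[li] = cur;
      v.set_size(cur.n_slices);
      for (arma::uword c = 0; c < cur.n_slices; ++c)
        v(c) = arma::accu(cur.slice(c)) / (cur.n_rows * cur.n_cols);
      isvec = true;
    } else {  // fc
      if (!isvec) stop("fc layer reached before global pooling");
      if (cache) cache->fcin[li] = v;
      fvec o = net.W[L.widx / 2] * v + net.b[L.widx / 2];
      if (cache) cache->fcpre[li] = o;
      if (L.relu) o = arma::clamp(o, 0.0f, std::numeric_limits<float>::max());
      v = std::move(o);
    }
  }
  if (!isvec) stop("network plan has no global pooling / fc head");
  return v;  // logits
}

fvec softmax_vec(const fvec& z) {
  fvec e = arma::exp(z - z.max());
  return e / arma::accu(e);
}

// Backward pass for one sample; accumulates gradients into gW/gb.
void backward_one(const Net& net, Cache& cache, const fvec& dlogits,
                  std::vector<fmat>& gW, std::vector<fvec>& gb) {
  fvec dv = dlogits;
  fcube dcur;
  bool isvec = true;
  for (int li = (int)net.layers.size() - 1; li >= 0; --li) {
    const Layer& L = net.layers[li];
    if (L.type == 4) {
      if (L.relu) dv = dv % arma::conv_to<fvec>::from(cache.fcpre[li] > 0);
      gW[L.widx / 2] += dv * cache.fcin[li].t();
      gb[L.widx / 2] += dv;
      dv = net.W[L.widx / 2].t() * dv;
    } else if (L.type == 3) {
      const fcube& in = cache.in[li];
      dcur.set_size(in.n_rows, in.n_cols, in.n_slices);
      const float inv = 1.0f / (in.n_rows * in.n_cols);
      for (arma::uword c = 0; c < in.n_slices; ++c)
        dcur.slice(c).fill(dv(c) * inv);
      isvec = false;
    } else if (L.type == 2) {
      const fcube& in = cache.in[li];
      const int H = in.n_rows, C = in.n_slices;
      const int Hout = dcur.n_rows, Wout = dcur.n_cols;
      fcube din(in.n_rows, in.n_cols, in.n_slices, arma::fill::zeros);
      for (int c = 0; c < C; ++c) {
        fmat& dsl = din.slice(c);
        for (int ow = 0; ow < Wout; ++ow)
          for (int oh = 0; oh < Hout; ++oh) {
            if (L.pool_type == 0) {
              arma::uword flat = cache.argmax[li](ow * Hout + oh, c);
              dsl(flat % H, flat / H) += dcur(oh, ow, c);
            } else {
              const int h0 = oh * L.stride, w0 = ow * L.stride;
              const float g = dcur(oh, ow, c) / (L.fs * L.fs);
              for (int kw = 0; kw < L.fs; ++kw)
                for (int kh = 0; kh < L.fs; ++kh) dsl(h0 + kh, w0 + kw) += g;
            }
          }
      }
      dcur = std::move(din);
    } else {  // conv / mb
      const fcube& in = cache.in[li];
      const int Hout = dcur.n_rows, Wout = dcur.n_cols;
      fcube din(in.n_rows, in.n_cols, in.n_slices, arma::fill::zeros);
      int coff = 0;
      for (size_t bi = 0; bi < L.convs.size(); ++bi) {
        const ConvDef& cd = L.convs[bi];
        fmat dout(cd.cout, Hout * Wout);
        for (int f = 0; f < cd.cout; ++f) {
          const fmat& dsl = dcur.slice(coff + f);
          dout.row(f) = arma::vectorise(dsl).t();
        }
        // ReLU gate on pre-activation
        dout = dout % arma::conv_to<fmat>::from(cache.pre[li][bi] > 0);
        gW[cd.widx / 2] += dout * cache.cols[li][bi].t();
        gb[cd.widx / 2] += arma::sum(dout, 1);
        fmat dcols = net.W[cd.widx / 2].t() * dout;
        fcube dxb;
        col2im_same(dcols, in.n_rows, in.n_cols, in.n_slices, cd.fs,
                    cd.stride, dxb);
        din += dxb;
        coff += cd.cout;
      }
      dcur = std::move(din);
    }
    (void)isvec;
  }
}

std::vector<fcube> to_cubes(const NumericVector& X) {
  IntegerVector dim = X.attr("dim");
  if (dim.size() != 4) stop("image array must have dim (H, W, C, N)");
  const int H = dim[0], W = dim[1], C = dim[2], N = dim[3];
  std::vector<fcube> out(N);
  const double* p = X.begin();
  const size_t per = (size_t)H * W * C;
  for (int n = 0; n < N; ++n) {
    fcube cb(H, W, C);
    const double* q = p + per * n;
    for (size_t i = 0; i < per; ++i) cb.memptr()[i] = (float)q[i];
    out[n] = std::move(cb);
  }
  return out;
}

void eval_set(const Net& net, const std::vector<fcube>& X,
              const IntegerVector& y, double& loss, double& acc) {
  double ls = 0.0; int correct = 0;
  for (size_t n = 0; n < X.size(); ++n) {
    fvec p = softmax_vec(forward_one(net, X[n], nullptr));
    int truth = y[n];
    ls += -std::log(std::max(p(truth), 1e-12f));
    if ((int)p.index_max() == truth) ++correct;
  }
  loss = ls / X.size();
  acc = (double)correct / X.size();
}

}  // namespace

// [[Rcpp::export]]
List cpp_train_net(List plan, List weights, NumericVector X, IntegerVector y,
                   NumericVector Xval, IntegerVector yval,
                   NumericVector lr_per_epoch, double momentum, double l2,
                   int batch_size, IntegerVector batch_order, int val_freq) {
  Net net = build_net(plan, weights);
  std::vector<fcube> Xtr = to_cubes(X);
  std::vector<fcube> Xv = to_cubes(Xval);
  const int N = Xtr.size();
  const int epochs = lr_per_epoch.size();
  if ((int)batch_order.size() != epochs * N)
    stop("batch_order must contain one permutation per epoch");

  std::vector<fmat> vW(net.W.size());
  std::vector<fvec> vb(net.b.size());
  for (size_t i = 0; i < net.W.size(); ++i) {
    vW[i].zeros(net.W[i].n_rows, net.W[i].n_cols);
    vb[i].zeros(net.b[i].n_elem);
  }
  std::vector<fmat> gW(net.W.size());
  std::vector<fvec> gb(net.b.size());

  std::vector<double> c_iter, c_epoch, c_lr, c_tloss, c_tacc, c_vloss, c_vacc;
  bool ok = true;
  long iter = 0;
  for (int e = 0; e < epochs && ok; ++e) {
    const float lr = (float)lr_per_epoch[e];
    for (int start = 0; start < N && ok; start += batch_size) {
      const int bs = std::min(batch_size, N - start);
      for (size_t i = 0; i < net.W.size(); ++i) {
        gW[i].zeros(net.W[i].n_rows, net.W[i].n_cols);
        gb[i].zeros(net.b[i].n_elem);
      }
      double bloss = 0.0; int bcorrect = 0;
      for (int k = 0; k < bs; ++k) {
        const int idx = batch_order[(size_t)e * N + start + k];
        Cache cache;
        fvec logits = forward_one(net, Xtr[idx], &cache);
        fvec p = softmax_vec(logits);
        const int truth = y[idx];
        bloss += -std::log(std::max(p(truth), 1e-12f));
        if ((int)p.index_max() == truth) ++bcorrect;
        fvec dlogits = p;
        dlogits(truth) -= 1.0f;
        dlogits /= (float)bs;
        backward_one(net, cache, dlogits, gW, gb);
      }
      bloss /= bs;
      if (!std::isfinite(bloss)) { ok = false; break; }
      // SGDM with L2 on weights only: v = m*v - lr*(g + l2*W); W += v
      for (size_t i = 0; i < net.W.size(); ++i) {
        vW[i] = (float)momentum * vW[i] - lr * (gW[i] + (float)l2 * net.W[i]);
        net.W[i] += vW[i];
        vb[i] = (float)momentum * vb[i] - lr * gb[i];
        net.b[i] += vb[i];
      }
      ++iter;
      if (val_freq > 0 && (iter % val_freq == 0)) {
        double vl, va;
        eval_set(net, Xv, yval, vl, va);
        c_iter.push_back((double)iter); c_epoch.push_back(e + 1);
        c_lr.push_back(lr);
        c_tloss.push_back(bloss); c_tacc.push_back((double)bcorrect / bs);
        c_vloss.push_back(vl); c_vacc.push_back(va);
      }
      if (iter % 64 == 0) Rcpp::checkUserInterrupt();
    }
  }
  double vl = NA_REAL, va = NA_REAL;
  if (ok && Xv.size() > 0) eval_set(net, Xv, yval, vl, va);

  List wout(weights.size());
  for (size_t i = 0; i < net.W.size(); ++i) {
    wout[2 * i] = wrap(arma::conv_to<arma::mat>::from(net.W[i]));
    wout[2 * i + 1] = wrap(arma::conv_to<arma::vec>::from(net.b[i]));
  }
  return List::create(
      _["ok"] = ok, _["weights"] = wout,
      _["val_loss"] = vl, _["val_accuracy"] = va,
      _["curves"] = List::create(
          _["iteration"] = c_iter, _["epoch"] = c_epoch, _["lr"] = c_lr,
          _["train_loss"] = c_tloss, _["train_accuracy"] = c_tacc,
          _["val_loss"] = c_vloss, _["val_accuracy"] = c_vacc));
}

// [[Rcpp::export]]
NumericMatrix cpp_predict_net(List plan, List weights, NumericVector X) {
  Net net = build_net(plan, weights);
  std::vector<fcube> Xs = to_cubes(X);
  const int N = Xs.size();
  int K = 0;
  NumericMatrix out;
  for (int n = 0; n < N; ++n) {
    fvec p = softmax_vec(forward_one(net, Xs[n], nullptr));
    if (n == 0) { K = p.n_elem; out = NumericMatrix(N, K); }
    for (int k = 0; k < K; ++k) out(n, k) = p(k);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_weight_sizes(List plan, List weights) {
  Net net = build_net(plan, weights);
  IntegerVector out(net.W.size() * 2);
  for (size_t i = 0; i < net.W.size(); ++i) {
    out[2 * i] = net.W[i].n_elem;
    out[2 * i + 1] = net.b[i].n_elem;
  }
  return out;
}
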