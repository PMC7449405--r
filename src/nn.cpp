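// Compact convolutional network engine backing the triage classifier and the
// adipocyte U-Net. Single precision, single threaded apart from BLAS; all
// randomness flows from one integer seed via a self-contained generator so
// that identical seeds give identical weights, shuffles and results.

#include <RcppArmadillo.h>
#include <vector>
#include <cmath>

using arma::fcube;
using arma::fmat;
using arma::frowvec;

// ---------------------------------------------------------------------------
// Deterministic RNG (mt19937 + hand-rolled Box-Muller and Fisher-Yates, so
// results do not depend on the standard library's distribution internals).
// ---------------------------------------------------------------------------
struct Rng {
  std::mt19937 g;
  bool has_spare = false;
  double spare = 0.0;
  explicit Rng(uint32_t s) : g(s) {}
  double unif() { return (static_cast<double>(g()) + 0.5) / 4294967296.0; }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), t = 2.0 * M_PI * u2;
    spare = r * std::sin(t);
    has_spare = true;
    return r * std::cos(t);
  }
  void shuffle(std::vector<int>& v) {
    for (int i = static_cast<int>(v.size()) - 1; i > 0; --i) {
      int j = static_cast<int>(unif() * (i + 1));
      if (j > i) j = i;
      std::swap(v[i], v[j]);
    }
  }
};

// ---------------------------------------------------------------------------
// Layers
// ---------------------------------------------------------------------------
struct Conv {
  fmat W;     // (k*k*Cin) x Cout
  frowvec b;  // Cout
  int k = 3, Cin = 0, Cout = 0;
  // caches for backward
  fmat Xcol;
  int H = 0, Wd = 0;

  void init(int k_, int cin, int cout, Rng& rng) {
    k = k_; Cin = cin; Cout = cout;
    double sd = std::sqrt(2.0 / (static_cast<double>(k) * k * cin));  // He
    W.set_size(k * k * cin, cout);
    for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = static_cast<float>(rng.norm() * sd);
    b.zeros(cout);
  }

  static void im2col3(const fcube& x, fmat& out) {
    const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
    out.set_size(H * Wd, 9 * C);
    fmat shifted(H, Wd);
    int col = 0;
    for (int c = 0; c < C; ++c)
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy) {
          shifted.zeros();
          const int r0 = std::max(0, -dy), r1 = std::min(H, H - dy);
          const int c0 = std::max(0, -dx), c1 = std::min(Wd, Wd - dx);
          if (r1 > r0 && c1 > c0)
            shifted.submat(r0, c0, r1 - 1, c1 - 1) =
                x.slice(c).submat(r0 + dy, c0 + dx, r1 - 1 + dy, c1 - 1 + dx);
          out.col(col++) = arma::vectorise(shifted);
        }
  }

  fcube forward(const fcube& x, bool cache) {
    H = x.n_rows; Wd = x.n_cols;
    fmat xc;
    if (k == 3) {
      im2col3(x, xc);
    } else {  // 1x1
      xc.set_size(H * Wd, Cin);
      for (int c = 0; c < Cin; ++c) xc.col(c) = arma::vectorise(x.slice(c));
    }
    fmat y = xc * W;
    y.each_row() += b;
    if (cache) Xcol = std::move(xc);
    fcube out(H, Wd, Cout);
    for (int c = 0; c < Cout; ++c) out.slice(c) = arma::reshape(y.col(c), H, Wd);
    return out;
  }

  // accumulates dW/db, returns gradient w.r.t. the input
  fcube backward(const fcube& dy, fmat& dW, frowvec& db) {
    fmat dym(H * Wd, Cout);
    for (int c = 0; c < Cout; ++c) dym.col(c) = arma::vectorise(dy.slice(c));
    dW += Xcol.t() * dym;
    db += arma::sum(dym, 0);
    fmat dxc = dym * W.t();
    fcube dx(H, Wd, Cin, arma::fill::zeros);
    if (k == 3) {
      int col = 0;
      for (int c = 0; c < Cin; ++c)
        for (int ox = -1; ox <= 1; ++ox)
          for (int oy = -1; oy <= 1; ++oy) {
            const int r0 = std::max(0, -oy), r1 = std::min(H, H - oy);
            const int c0 = std::max(0, -ox), c1 = std::min(Wd, Wd - ox);
            if (r1 > r0 && c1 > c0) {
              fmat g = arma::reshape(dxc.col(col), H, Wd);
              dx.slice(c).submat(r0 + oy, c0 + ox, r1 - 1 + oy, c1 - 1 + ox) +=
                  g.submat(r0, c0, r1 - 1, c1 - 1);
            }
            ++col;
          }
    } else {
      for (int c = 0; c < Cin; ++c) dx.slice(c) = arma::reshape(dxc.col(c), H, Wd);
    }
    return dx;
  }
};

static void relu_inplace(fcube& x) {
  for (arma::uword i = 0; i < x.n_elem; ++i)
    if (x(i) < 0.0f) x(i) = 0.0f;
}

// dy masked by the cached *output* of the relu (y > 0 <=> pre-activation > 0)
static void relu_backward_inplace(fcube& dy, const fcube& y) {
  for (arma::uword i = 0; i < dy.n_elem; ++i)
    if (y(i) <= 0.0f) dy(i) = 0.0f;
}

struct Pool {  // 2x2 max pooling, stride 2
  arma::ucube idx;  // winner position 0..3 = (dr, dc) = (idx%2, idx/2)
  fcube forward(const fcube& x) {
    const int Ho = x.n_rows / 2, Wo = x.n_cols / 2, C = x.n_slices;
    fcube out(Ho, Wo, C);
    idx.set_size(Ho, Wo, C);
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          float best = -std::numeric_limits<float>::infinity();
          unsigned bi = 0;
          for (int dc = 0; dc < 2; ++dc)
            for (int dr = 0; dr < 2; ++dr) {
              float v = x(2 * i + dr, 2 * j + dc, c);
              if (v > best) { best = v; bi = dr + 2 * dc; }
            }
          out(i, j, c) = best;
          idx(i, j, c) = bi;
        }
    return out;
  }
  fcube backward(const fcube& dy, int H, int Wd) {
    const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
    fcube dx(H, Wd, C, arma::fill::zeros);
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          unsigned bi = idx(i, j, c);
          dx(2 * i + (bi % 2), 2 * j + (bi / 2), c) = dy(i, j, c);
        }
    return dx;
  }
};

static fcube upsample2(const fcube& x) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  fcube out(2 * H, 2 * Wd, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wd; ++j)
      for (int i = 0; i < H; ++i) {
        const float v = x(i, j, c);
        out(2 * i, 2 * j, c) = v;
        out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v;
        out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return out;
}

static fcube upsample2_backward(const fcube& dy) {
  const int Ho = dy.n_rows / 2, Wo = dy.n_cols / 2, C = dy.n_slices;
  fcube dx(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}

// ---------------------------------------------------------------------------
// R <-> arma conversion
// ---------------------------------------------------------------------------
static fcube cube_from_r(const Rcpp::NumericVector& arr) {
  Rcpp::IntegerVector d = arr.attr("dim");
  const int H = d[0], Wd = d[1], C = (d.size() > 2) ? d[2] : 1;
  fcube x(H, Wd, C);
  for (int i = 0; i < H * Wd * C; ++i) x(i) = static_cast<float>(arr[i]);
  return x;
}

static Rcpp::NumericMatrix mat_to_r(const fmat& m) {
  Rcpp::NumericMatrix out(m.n_rows, m.n_cols);
  for (arma::uword i = 0; i < m.n_elem; ++i) out[i] = m(i);
  return out;
}

static fmat mat_from_r(const Rcpp::NumericMatrix& m) {
  fmat out(m.nrow(), m.ncol());
  for (int i = 0; i < m.nrow() * m.ncol(); ++i) out(i) = static_cast<float>(m[i]);
  return out;
}

// ===========================================================================
// Triage classifier: [conv3 -> relu -> maxpool2] * nblocks -> global average
// pooling -> dense 3-way softmax. Input is raw 0-255 pixel scale centred at
// 128 (the R wrapper passes [0,1] arrays; scaling happens here). Biases are
// stored as 1 x C matrices so one optimizer path covers all parameters.
// ===========================================================================
static frowvec row_from(const fmat& m) { return m.row(0); }

// Triage forward pass over `net` given weight matrices W[i], B[i] (1 x C).
struct TriageModel {
  std::vector<Conv> convs;
  fmat fcW, fcB;  // fcB is 1 x 3
};

static void triage_init(TriageModel& M, const std::vector<int>& channels, Rng& rng) {
  M.convs.resize(channels.size());
  int cin = 3;
  for (size_t i = 0; i < channels.size(); ++i) {
    M.convs[i].init(3, cin, channels[i], rng);
    cin = channels[i];
  }
  M.fcW.zeros(cin, 3);
  M.fcB.zeros(1, 3);
}

struct TriageTape {
  std::vector<fcube> relu_out;
  std::vector<Pool> pools;
  frowvec feat;
  int featH = 0, featW = 0;
};

static frowvec triage_forward(TriageModel& M, const fcube& img01, TriageTape* tape) {
  fcube x = img01 * 255.0f - 128.0f;
  if (tape) { tape->relu_out.resize(M.convs.size()); tape->pools.resize(M.convs.size()); }
  for (size_t i = 0; i < M.convs.size(); ++i) {
    fcube y = M.convs[i].forward(x, tape != nullptr);
    relu_inplace(y);
    Pool pl;
    x = pl.forward(y);
    if (tape) { tape->relu_out[i] = std::move(y); tape->pools[i] = std::move(pl); }
  }
  const int fh = x.n_rows, fw = x.n_cols;
  frowvec f(x.n_slices);
  for (arma::uword c = 0; c < x.n_slices; ++c) f(c) = arma::accu(x.slice(c)) / (fh * fw);
  if (tape) { tape->feat = f; tape->featH = fh; tape->featW = fw; }
  frowvec logits = f * M.fcW + row_from(M.fcB);
  const float mx = logits.max();
  frowvec p = arma::exp(logits - mx);
  return p / arma::accu(p);
}

// grads layout: [conv0.W, conv0.b(1xC), conv1.W, ... , fcW, fcB]
static void triage_backward(TriageModel& M, TriageTape& tape, const frowvec& dlogits,
                            std::vector<fmat>& g) {
  const size_t nb = M.convs.size();
  g[2 * nb] += tape.feat.t() * dlogits;
  g[2 * nb + 1] += fmat(dlogits);
  frowvec dfeat = dlogits * M.fcW.t();
  const int Cl = M.convs.back().Cout;
  fcube dx(tape.featH, tape.featW, Cl);
  for (int c = 0; c < Cl; ++c) dx.slice(c).fill(dfeat(c) / (tape.featH * tape.featW));
  for (int i = static_cast<int>(nb) - 1; i >= 0; --i) {
    fcube d = tape.pools[i].backward(dx, tape.relu_out[i].n_rows, tape.relu_out[i].n_cols);
    relu_backward_inplace(d, tape.relu_out[i]);
    frowvec db(M.convs[i].b.n_elem, arma::fill::zeros);
    dx = M.convs[i].backward(d, g[2 * i], db);
    g[2 * i + 1] += fmat(db);
  }
}

static Rcpp::List triage_weights_out(const TriageModel& M) {
  Rcpp::List Ws, Bs;
  for (const auto& cv : M.convs) {
    Ws.push_back(mat_to_r(cv.W));
    Bs.push_back(mat_to_r(fmat(cv.b)));
  }
  return Rcpp::List::create(Rcpp::Named("conv_W") = Ws, Rcpp::Named("conv_b") = Bs,
                            Rcpp::Named("fc_W") = mat_to_r(M.fcW),
                            Rcpp::Named("fc_b") = mat_to_r(M.fcB));
}

static TriageModel triage_weights_in(const Rcpp::List& wts) {
  TriageModel M;
  Rcpp::List Ws = wts["conv_W"], Bs = wts["conv_b"];
  M.convs.resize(Ws.size());
  int cin = 3;
  for (int i = 0; i < Ws.size(); ++i) {
    fmat W = mat_from_r(Ws[i]);
    M.convs[i].k = 3;
    M.convs[i].Cin = cin;
    M.convs[i].Cout = W.n_cols;
    M.convs[i].W = W;
    M.convs[i].b = row_from(mat_from_r(Bs[i]));
    cin = W.n_cols;
  }
  M.fcW = mat_from_r(wts["fc_W"]);
  M.fcB = mat_from_r(wts["fc_b"]);
  return M;
}

// [[Rcpp::export]]
Rcpp::List cpp_triage_init(Rcpp::IntegerVector channels, int seed) {
  Rng rng(static_cast<uint32_t>(seed));
  std::vector<int> ch(channels.begin(), channels.end());
  TriageModel M;
  triage_init(M, ch, rng);
  return triage_weights_out(M);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_triage_predict(Rcpp::List weights, Rcpp::List images) {
  TriageModel M = triage_weights_in(weights);
  const int n = images.size();
  Rcpp::NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    fcube img = cube_from_r(images[i]);
    frowvec p = triage_forward(M, img, nullptr);
    for (int c = 0; c < 3; ++c) out(i, c) = p(c);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_triage_train(Rcpp::List weights, Rcpp::List images, Rcpp::IntegerVector labels,
                            Rcpp::IntegerVector train_idx, Rcpp::IntegerVector val_idx,
                            double lr, double momentum, int epochs, int batch_size,
                            double clip_norm, int seed) {
  TriageModel M = triage_weights_in(weights);
  Rng rng(static_cast<uint32_t>(seed));
  const int n = images.size();
  std::vector<fcube> imgs(n);
  for (int i = 0; i < n; ++i) imgs[i] = cube_from_r(images[i]);

  // parameter/grad bookkeeping
  std::vector<fmat*> params;
  std::vector<fmat> bias_as_mat(M.convs.size());
  for (size_t i = 0; i < M.convs.size(); ++i) {
    params.push_back(&M.convs[i].W);
    bias_as_mat[i] = fmat(M.convs[i].b);
    params.push_back(&bias_as_mat[i]);
  }
  params.push_back(&M.fcW);
  params.push_back(&M.fcB);
  std::vector<fmat> g(params.size()), vel(params.size());
  for (size_t i = 0; i < params.size(); ++i) {
    g[i].zeros(arma::size(*params[i]));
    vel[i].zeros(arma::size(*params[i]));
  }

  std::vector<int> tr(train_idx.begin(), train_idx.end());  // 0-based
  Rcpp::NumericVector loss_hist(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    rng.shuffle(tr);
    double ep_loss = 0.0;
    int nb = 0;
    for (size_t start = 0; start < tr.size(); start += batch_size) {
      const size_t stop = std::min(tr.size(), start + batch_size);
      const double bs = static_cast<double>(stop - start);
      for (auto& x : g) x.zeros();
      // keep conv biases in sync with the matrices the optimizer updates
      for (size_t i = 0; i < M.convs.size(); ++i) M.convs[i].b = row_from(bias_as_mat[i]);
      for (size_t s = start; s < stop; ++s) {
        const int ix = tr[s];
        TriageTape tape;
        frowvec p = triage_forward(M, imgs[ix], &tape);
        const int y = labels[ix];
        ep_loss += -std::log(std::max(1e-12, static_cast<double>(p(y))));
        frowvec dlogits = p;
        dlogits(y) -= 1.0f;
        dlogits /= static_cast<float>(bs);
        triage_backward(M, tape, dlogits, g);
      }
      // clip (NaN/blow-up guard) then Nesterov update
      double nrm = 0.0;
      for (const auto& x : g) nrm += arma::accu(arma::square(arma::conv_to<arma::mat>::from(x)));
      nrm = std::sqrt(nrm);
      if (std::isfinite(nrm) && nrm > clip_norm) {
        const float sc = static_cast<float>(clip_norm / nrm);
        for (auto& x : g) x *= sc;
      }
      for (size_t i = 0; i < params.size(); ++i) {
        vel[i] = static_cast<float>(momentum) * vel[i] - static_cast<float>(lr) * g[i];
        *params[i] += static_cast<float>(momentum) * vel[i] - static_cast<float>(lr) * g[i];
      }
      ++nb;
    }
    for (size_t i = 0; i < M.convs.size(); ++i) M.convs[i].b = row_from(bias_as_mat[i]);
    loss_hist[ep] = ep_loss / std::max<size_t>(1, tr.size());
    (void)nb;
    Rcpp::checkUserInterrupt();
  }

  auto accuracy = [&](const Rcpp::IntegerVector& idx) {
    if (idx.size() == 0) return NA_REAL;
    int ok = 0;
    for (int i = 0; i < idx.size(); ++i) {
      frowvec p = triage_forward(M, imgs[idx[i]], nullptr);
      if (static_cast<int>(p.index_max()) == labels[idx[i]]) ++ok;
    }
    return static_cast<double>(ok) / idx.size();
  };

  return Rcpp::List::create(Rcpp::Named("weights") = triage_weights_out(M),
                            Rcpp::Named("train_accuracy") = accuracy(train_idx),
                            Rcpp::Named("validation_accuracy") = accuracy(val_idx),
                            Rcpp::Named("loss") = loss_hist);
}

// ===========================================================================
// U-Net: encoder [conv3+relu, maxpool2] x depth, bottleneck conv3+relu,
// decoder [upsample2, concat skip, conv3+relu] x depth, 1x1 conv + sigmoid.
// Channels double per level, capped at cap_mult * base.
// Loss: (1 - soft dice) + pixelwise BCE, equal weights.
// ===========================================================================
struct UNetModel {
  int depth = 4, base = 16, cap = 64;
  std::vector<Conv> enc;   // depth
  Conv bott;
  std::vector<Conv> dec;   // depth (dec[d] consumes concat(skip_d, up))
  Conv final1;             // 1x1 -> 1 channel
  std::vector<int> ch;     // encoder output channels per level
  int chb = 0;
};

static void unet_init(UNetModel& M, int depth, int base, int cap_mult, Rng& rng) {
  M.depth = depth; M.base = base; M.cap = base * cap_mult;
  M.ch.resize(depth);
  M.enc.resize(depth);
  M.dec.resize(depth);
  int cin = 3;
  for (int d = 0; d < depth; ++d) {
    M.ch[d] = std::min(base << d, M.cap);
    M.enc[d].init(3, cin, M.ch[d], rng);
    cin = M.ch[d];
  }
  M.chb = std::min(base << depth, M.cap);
  M.bott.init(3, cin, M.chb, rng);
  int up = M.chb;
  for (int d = depth - 1; d >= 0; --d) {
    M.dec[d].init(3, M.ch[d] + up, M.ch[d], rng);
    up = M.ch[d];
  }
  M.final1.init(1, M.ch[0], 1, rng);
}

struct UNetTape {
  std::vector<fcube> enc_relu;   // skip activations
  std::vector<Pool> pools;
  fcube bott_relu;
  std::vector<fcube> dec_relu;
  std::vector<fcube> concat_in;  // kept implicitly via conv caches; store dims
};

static fcube concat_slices(const fcube& a, const fcube& b) {
  fcube out(a.n_rows, a.n_cols, a.n_slices + b.n_slices);
  for (arma::uword c = 0; c < a.n_slices; ++c) out.slice(c) = a.slice(c);
  for (arma::uword c = 0; c < b.n_slices; ++c) out.slice(a.n_slices + c) = b.slice(c);
  return out;
}

// forward to the sigmoid probability map
static fmat unet_forward(UNetModel& M, const fcube& img, UNetTape* tape) {
  fcube x = img;
  if (tape) {
    tape->enc_relu.resize(M.depth);
    tape->pools.resize(M.depth);
    tape->dec_relu.resize(M.depth);
  }
  std::vector<fcube> skips(M.depth);
  for (int d = 0; d < M.depth; ++d) {
    fcube y = M.enc[d].forward(x, tape != nullptr);
    relu_inplace(y);
    skips[d] = y;
    Pool pl;
    x = pl.forward(y);
    if (tape) { tape->enc_relu[d] = std::move(y); tape->pools[d] = std::move(pl); }
  }
  x = M.bott.forward(x, tape != nullptr);
  relu_inplace(x);
  if (tape) tape->bott_relu = x;
  for (int d = M.depth - 1; d >= 0; --d) {
    fcube up = upsample2(x);
    fcube cat = concat_slices(skips[d], up);
    x = M.dec[d].forward(cat, tape != nullptr);
    relu_inplace(x);
    if (tape) tape->dec_relu[d] = x;
  }
  fcube z = M.final1.forward(x, tape != nullptr);
  fmat p = 1.0f / (1.0f + arma::exp(-z.slice(0)));
  return p;
}

// backward from d(loss)/d(logit z); grads layout:
// [enc0.W, enc0.b, ..., bott.W, bott.b, dec(depth-1).W, dec(depth-1).b, ...,
//  dec0.W, dec0.b, final.W, final.b]
static void unet_backward(UNetModel& M, UNetTape& tape, const fmat& dz,
                          std::vector<fmat>& g) {
  const int D = M.depth;
  auto gi_enc = [&](int d) { return 2 * d; };
  const int gi_bott = 2 * D;
  auto gi_dec = [&](int d) { return 2 * D + 2 + 2 * (D - 1 - d); };
  const int gi_fin = 4 * D + 2;

  fcube dzc(dz.n_rows, dz.n_cols, 1);
  dzc.slice(0) = dz;
  frowvec db_f(1, arma::fill::zeros);
  fcube dx = M.final1.backward(dzc, g[gi_fin], db_f);
  g[gi_fin + 1] += fmat(db_f);

  std::vector<fcube> dskip(D);
  for (int d = 0; d <= D - 1; ++d) {
    // decoder blocks were applied from d = D-1 down to 0; reverse order: 0..D-1
    relu_backward_inplace(dx, tape.dec_relu[d]);
    frowvec db(M.dec[d].b.n_elem, arma::fill::zeros);
    fcube dcat = M.dec[d].backward(dx, g[gi_dec(d)], db);
    g[gi_dec(d) + 1] += fmat(db);
    const int cs = M.ch[d];
    fcube ds(dcat.n_rows, dcat.n_cols, cs);
    fcube dup(dcat.n_rows, dcat.n_cols, dcat.n_slices - cs);
    for (int c = 0; c < cs; ++c) ds.slice(c) = dcat.slice(c);
    for (arma::uword c = cs; c < dcat.n_slices; ++c) dup.slice(c - cs) = dcat.slice(c);
    dskip[d] = std::move(ds);
    dx = upsample2_backward(dup);
  }
  relu_backward_inplace(dx, tape.bott_relu);
  {
    frowvec db(M.bott.b.n_elem, arma::fill::zeros);
    dx = M.bott.backward(dx, g[gi_bott], db);
    g[gi_bott + 1] += fmat(db);
  }
  for (int d = D - 1; d >= 0; --d) {
    fcube dpooled = tape.pools[d].backward(dx, tape.enc_relu[d].n_rows, tape.enc_relu[d].n_cols);
    dpooled += dskip[d];
    relu_backward_inplace(dpooled, tape.enc_relu[d]);
    frowvec db(M.enc[d].b.n_elem, arma::fill::zeros);
    dx = M.enc[d].backward(dpooled, g[gi_enc(d)], db);
    g[gi_enc(d) + 1] += fmat(db);
  }
}

static Rcpp::List unet_weights_out(const UNetModel& M) {
  Rcpp::List Ws, Bs;
  auto push = [&](const Conv& cv) {
    Ws.push_back(mat_to_r(cv.W));
    Bs.push_back(mat_to_r(fmat(cv.b)));
  };
  for (int d = 0; d < M.depth; ++d) push(M.enc[d]);
  push(M.bott);
  for (int d = M.depth - 1; d >= 0; --d) push(M.dec[d]);
  push(M.final1);
  return Rcpp::List::create(Rcpp::Named("W") = Ws, Rcpp::Named("b") = Bs,
                            Rcpp::Named("depth") = M.depth, Rcpp::Named("base") = M.base,
                            Rcpp::Named("cap_mult") = M.cap / M.base);
}

static UNetModel unet_weights_in(const Rcpp::List& wts) {
  UNetModel M;
  M.depth = Rcpp::as<int>(wts["depth"]);
  M.base = Rcpp::as<int>(wts["base"]);
  M.cap = M.base * Rcpp::as<int>(wts["cap_mult"]);
  Rcpp::List Ws = wts["W"], Bs = wts["b"];
  M.ch.resize(M.depth);
  M.enc.resize(M.depth);
  M.dec.resize(M.depth);
  int k = 0, cin = 3;
  auto load = [&](Conv& cv, int kk, int cin_) {
    cv.W = mat_from_r(Ws[k]);
    cv.b = row_from(mat_from_r(Bs[k]));
    cv.k = kk; cv.Cin = cin_; cv.Cout = cv.W.n_cols;
    ++k;
  };
  for (int d = 0; d < M.depth; ++d) {
    M.ch[d] = std::min(M.base << d, M.cap);
    load(M.enc[d], 3, cin);
    cin = M.ch[d];
  }
  M.chb = std::min(M.base << M.depth, M.cap);
  load(M.bott, 3, cin);
  int up = M.chb;
  for (int d = M.depth - 1; d >= 0; --d) {
    load(M.dec[d], 3, M.ch[d] + up);
    up = M.ch[d];
  }
  load(M.final1, 1, M.ch[0]);
  return M;
}

// [[Rcpp::export]]
Rcpp::List cpp_unet_init(int depth, int base, int cap_mult, int seed) {
  Rng rng(static_cast<uint32_t>(seed));
  UNetModel M;
  unet_init(M, depth, base, cap_mult, rng);
  return unet_weights_out(M);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_unet_predict(Rcpp::List weights, Rcpp::NumericVector image) {
  UNetModel M = unet_weights_in(weights);
  fcube img = cube_from_r(image);
  fmat p = unet_forward(M, img, nullptr);
  return mat_to_r(p);
}

// [[Rcpp::export]]
Rcpp::List cpp_unet_train(Rcpp::List weights, Rcpp::List images, Rcpp::List masks,
                          Rcpp::IntegerVector train_idx, Rcpp::IntegerVector val_idx,
                          double lr, double beta1, double beta2, double adam_eps,
                          int epochs, int batch_size, double dice_smooth,
                          double dice_weight, double bce_weight, int seed) {
  UNetModel M = unet_weights_in(weights);
  Rng rng(static_cast<uint32_t>(seed));
  const int n = images.size();
  std::vector<fcube> imgs(n);
  std::vector<fmat> tgts(n);
  for (int i = 0; i < n; ++i) {
    imgs[i] = cube_from_r(images[i]);
    fcube m = cube_from_r(masks[i]);
    tgts[i] = m.slice(0);
  }

  std::vector<fmat*> params;
  std::vector<fmat> bias_as_mat;
  std::vector<Conv*> all_convs;
  for (int d = 0; d < M.depth; ++d) all_convs.push_back(&M.enc[d]);
  all_convs.push_back(&M.bott);
  for (int d = M.depth - 1; d >= 0; --d) all_convs.push_back(&M.dec[d]);
  all_convs.push_back(&M.final1);
  bias_as_mat.resize(all_convs.size());
  for (size_t i = 0; i < all_convs.size(); ++i) {
    params.push_back(&all_convs[i]->W);
    bias_as_mat[i] = fmat(all_convs[i]->b);
    params.push_back(&bias_as_mat[i]);
  }
  std::vector<fmat> g(params.size()), am(params.size()), av(params.size());
  for (size_t i = 0; i < params.size(); ++i) {
    g[i].zeros(arma::size(*params[i]));
    am[i].zeros(arma::size(*params[i]));
    av[i].zeros(arma::size(*params[i]));
  }

  std::vector<int> tr(train_idx.begin(), train_idx.end());
  Rcpp::NumericVector loss_hist(epochs);
  int t_adam = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    rng.shuffle(tr);
    double ep_loss = 0.0;
    for (size_t start = 0; start < tr.size(); start += batch_size) {
      const size_t stop = std::min(tr.size(), start + batch_size);
      const double bs = static_cast<double>(stop - start);
      for (auto& x : g) x.zeros();
      for (size_t i = 0; i < all_convs.size(); ++i) all_convs[i]->b = row_from(bias_as_mat[i]);
      for (size_t s = start; s < stop; ++s) {
        const int ix = tr[s];
        UNetTape tape;
        fmat p = unet_forward(M, imgs[ix], &tape);
        const fmat& tgt = tgts[ix];
        const double npx = static_cast<double>(p.n_elem);
        // losses
        double bce = 0.0;
        for (arma::uword e = 0; e < p.n_elem; ++e) {
          const double pe = std::min(1.0 - 1e-7, std::max(1e-7, static_cast<double>(p(e))));
          bce += tgt(e) > 0.5f ? -std::log(pe) : -std::log(1.0 - pe);
        }
        bce /= npx;
        const double sd_num = 2.0 * arma::accu(arma::conv_to<arma::mat>::from(p % tgt)) + dice_smooth;
        const double sd_den = arma::accu(arma::conv_to<arma::mat>::from(p)) +
                              arma::accu(arma::conv_to<arma::mat>::from(tgt)) + dice_smooth;
        ep_loss += bce_weight * bce + dice_weight * (1.0 - sd_num / sd_den);
        // gradient wrt logit z
        fmat dz(p.n_rows, p.n_cols);
        const float c_bce = static_cast<float>(bce_weight / (npx * bs));
        const float inv_den = static_cast<float>(1.0 / sd_den);
        const float num_over_den2 = static_cast<float>(sd_num / (sd_den * sd_den));
        const float c_dice = static_cast<float>(dice_weight / bs);
        for (arma::uword e = 0; e < p.n_elem; ++e) {
          const float pe = p(e), ge = tgt(e);
          const float dbce_dz = c_bce * (pe - ge);
          // d(1 - SD)/dp = -(2 g / den - num/den^2)
          const float ddice_dp = -(2.0f * ge * inv_den - num_over_den2);
          const float ddice_dz = c_dice * ddice_dp * pe * (1.0f - pe);
          dz(e) = dbce_dz + ddice_dz;
        }
        unet_backward(M, tape, dz, g);
      }
      // Adam step
      ++t_adam;
      const double c1 = 1.0 - std::pow(beta1, t_adam), c2 = 1.0 - std::pow(beta2, t_adam);
      for (size_t i = 0; i < params.size(); ++i) {
        am[i] = static_cast<float>(beta1) * am[i] + static_cast<float>(1.0 - beta1) * g[i];
        av[i] = static_cast<float>(beta2) * av[i] + static_cast<float>(1.0 - beta2) * arma::square(g[i]);
        *params[i] -= static_cast<float>(lr) * (am[i] / static_cast<float>(c1)) /
                      (arma::sqrt(av[i] / static_cast<float>(c2)) + static_cast<float>(adam_eps));
      }
      Rcpp::checkUserInterrupt();
    }
    for (size_t i = 0; i < all_convs.size(); ++i) all_convs[i]->b = row_from(bias_as_mat[i]);
    loss_hist[ep] = ep_loss / std::max<size_t>(1, tr.size());
  }

  // pooled (micro) hard dice over a set of crops at threshold 0.5
  auto pooled_dice = [&](const Rcpp::IntegerVector& idx) {
    if (idx.size() == 0) return NA_REAL;
    double inter = 0.0, tot = 0.0;
    for (int i = 0; i < idx.size(); ++i) {
      fmat p = unet_forward(M, imgs[idx[i]], nullptr);
      const fmat& tgt = tgts[idx[i]];
      for (arma::uword e = 0; e < p.n_elem; ++e) {
        const int a = p(e) > 0.5f ? 1 : 0, b = tgt(e) > 0.5f ? 1 : 0;
        inter += a * b;
        tot += a + b;
      }
    }
    return tot == 0.0 ? 1.0 : 2.0 * inter / tot;
  };

  return Rcpp::List::create(Rcpp::Named("weights") = unet_weights_out(M),
                            Rcpp::Named("train_dice") = pooled_dice(train_idx),
                            Rcpp::Named("validation_dice") = pooled_dice(val_idx),
                            Rcpp::Named("loss") = loss_hist);
}
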