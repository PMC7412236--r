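// Minimal 2D conv-net engine for recurrence-image classification.
//
// Activations are stored as (B*H*W) x C float matrices, one row per
// pixel (column-major within an image, images stacked), one column per
// channel. Convolutions are im2col + BLAS sgemm; training is plain
// backprop with Adam. Everything is seeded through one mt19937 so a
// given (architecture, seed, data) triple reproduces bit-identically on
// a fixed build.

#include <RcppArmadillo.h>
#include <random>
#include <memory>

using namespace arma;

// ---------------------------------------------------------------- im2col

// X: (B*H*W) x Cin -> out: (B*H*W) x (k*k*Cin), zero-padded "same",
// stride 1, odd k. Offset block o = (dx+r)*k + (dy+r) holds the input
// pixel (y+dy, x+dx) for output pixel (y, x).
//
// The padding zeros sit at fixed positions for fixed (B, H, W), so a
// reused buffer only needs zeroing when its geometry changes; the valid
// regions are overwritten every call. This matters: the buffer is by
// far the largest allocation in the engine.
static void im2col(const fmat& X, int B, int H, int W, int k, fmat& out) {
  const int cin = X.n_cols, r = k / 2;
  const uword nr = (uword)B * H * W, nc = (uword)k * k * cin;
  if (out.n_rows != nr || out.n_cols != nc) out.zeros(nr, nc);
  for (int b = 0; b < B; ++b) {
    const uword base = (uword)b * H * W;
    for (int dx = -r; dx <= r; ++dx) {
      for (int dy = -r; dy <= r; ++dy) {
        const int o = (dx + r) * k + (dy + r);
        const uword c0 = (uword)o * cin, c1 = c0 + cin - 1;
        for (int x = 0; x < W; ++x) {
          const int sx = x + dx;
          if (sx < 0 || sx >= W) continue;
          const int y0 = std::max(0, -dy), y1 = std::min(H - 1, H - 1 - dy);
          if (y0 > y1) continue;
          out.submat(base + (uword)x * H + y0, c0,
                     base + (uword)x * H + y1, c1) =
            X.submat(base + (uword)sx * H + y0 + dy, 0,
                     base + (uword)sx * H + y1 + dy, cin - 1);
        }
      }
    }
  }
}

// Transpose of im2col: accumulate column gradients back onto pixels.
static void col2im(const fmat& dCol, int B, int H, int W, int k, fmat& dX,
                   int cin) {
  const int r = k / 2;
  dX.zeros((uword)B * H * W, cin);
  for (int b = 0; b < B; ++b) {
    const uword base = (uword)b * H * W;
    for (int dx = -r; dx <= r; ++dx) {
      for (int dy = -r; dy <= r; ++dy) {
        const int o = (dx + r) * k + (dy + r);
        const uword c0 = (uword)o * cin, c1 = c0 + cin - 1;
        for (int x = 0; x < W; ++x) {
          const int sx = x + dx;
          if (sx < 0 || sx >= W) continue;
          const int y0 = std::max(0, -dy), y1 = std::min(H - 1, H - 1 - dy);
          if (y0 > y1) continue;
          dX.submat(base + (uword)sx * H + y0 + dy, 0,
                    base + (uword)sx * H + y1 + dy, cin - 1) +=
            dCol.submat(base + (uword)x * H + y0, c0,
                        base + (uword)x * H + y1, c1);
        }
      }
    }
  }
}

// ---------------------------------------------------------------- layers

struct Layer {
  virtual ~Layer() {}
  // H, W updated in place by pooling / pooling-like layers
  virtual fmat forward(const fmat& X, int B, int& H, int& W, bool train) = 0;
  virtual fmat backward(const fmat& dY) = 0;
  // trainable parameter / gradient pairs, then non-trained state tensors
  virtual void collect(const std::string& tag,
                       std::vector<std::string>& names,
                       std::vector<fmat*>& par, std::vector<fmat*>& grad,
                       std::vector<std::string>& snames,
                       std::vector<fmat*>& state) = 0;
  virtual void init(std::mt19937& rng) = 0;
};

static fmat he_normal(uword nr, uword nc, double fan_in, std::mt19937& rng) {
  std::normal_distribution<float> d(0.0f, (float)std::sqrt(2.0 / fan_in));
  fmat W(nr, nc);
  for (uword j = 0; j < nc; ++j)
    for (uword i = 0; i < nr; ++i) W(i, j) = d(rng);
  return W;
}

struct Conv : Layer {
  int k, cin, cout;
  fmat W, b, dW, db;  // W: (k*k*cin) x cout, b: 1 x cout
  fmat col;           // cached im2col of the last forward input
  fmat dCol, dX_buf;  // reused backward buffers
  int B_, H_, W_;
  Conv(int k_, int ci, int co) : k(k_), cin(ci), cout(co) {}
  void init(std::mt19937& rng) override {
    W = he_normal((uword)k * k * cin, cout, (double)k * k * cin, rng);
    b.zeros(1, cout);
  }
  fmat forward(const fmat& X, int B, int& H, int& Wd, bool) override {
    B_ = B; H_ = H; W_ = Wd;
    im2col(X, B, H, Wd, k, col);
    fmat Y = col * W;
    Y.each_row() += b;
    return Y;
  }
  fmat backward(const fmat& dY) override {
    dW = col.t() * dY;
    db = sum(dY, 0);
    dCol = dY * W.t();
    col2im(dCol, B_, H_, W_, k, dX_buf, cin);
    return dX_buf;
  }
  void collect(const std::string& tag, std::vector<std::string>& names,
               std::vector<fmat*>& par, std::vector<fmat*>& grad,
               std::vector<std::string>&, std::vector<fmat*>&) override {
    names.push_back(tag + ".W"); par.push_back(&W); grad.push_back(&dW);
    names.push_back(tag + ".b"); par.push_back(&b); grad.push_back(&db);
    dW.zeros(W.n_rows, W.n_cols); db.zeros(1, cout);
  }
};

struct BatchNorm : Layer {
  int c;
  fmat gamma, beta, dgamma, dbeta, rmean, rvar;
  fmat xhat;
  frowvec invstd;
  static constexpr float eps = 1e-5f, momentum = 0.9f;
  explicit BatchNorm(int c_) : c(c_) {}
  void init(std::mt19937&) override {
    gamma.ones(1, c); beta.zeros(1, c); rmean.zeros(1, c); rvar.ones(1, c);
  }
  fmat forward(const fmat& X, int, int&, int&, bool train) override {
    const uword n = X.n_rows;
    if (train) {
      frowvec mu = mean(X, 0);
      fmat Xc = X; Xc.each_row() -= mu;
      frowvec var = mean(square(Xc), 0);  // biased, as used for the step
      invstd = 1.0f / sqrt(var + eps);
      xhat = Xc; xhat.each_row() %= invstd;
      rmean = momentum * rmean + (1.0f - momentum) * conv_to<fmat>::from(mu);
      rvar = momentum * rvar + (1.0f - momentum) * conv_to<fmat>::from(var);
      fmat Y = xhat;
      Y.each_row() %= conv_to<frowvec>::from(gamma);
      Y.each_row() += conv_to<frowvec>::from(beta);
      return Y;
    }
    frowvec is = 1.0f / sqrt(conv_to<frowvec>::from(rvar) + eps);
    fmat Y = X; Y.each_row() -= conv_to<frowvec>::from(rmean);
    Y.each_row() %= is;
    Y.each_row() %= conv_to<frowvec>::from(gamma);
    Y.each_row() += conv_to<frowvec>::from(beta);
    (void)n;
    return Y;
  }
  fmat backward(const fmat& dY) override {
    const float n = (float)dY.n_rows;
    dgamma = sum(dY % xhat, 0);
    dbeta = sum(dY, 0);
    fmat dxhat = dY;
    dxhat.each_row() %= conv_to<frowvec>::from(gamma);
    frowvec s1 = sum(dxhat, 0), s2 = sum(dxhat % xhat, 0);
    fmat dX = n * dxhat;
    dX.each_row() -= s1;
    fmat t = xhat;
    t.each_row() %= s2;
    dX -= t;
    dX.each_row() %= (invstd / n);
    return dX;
  }
  void collect(const std::string& tag, std::vector<std::string>& names,
               std::vector<fmat*>& par, std::vector<fmat*>& grad,
               std::vector<std::string>& snames,
               std::vector<fmat*>& state) override {
    names.push_back(tag + ".gamma"); par.push_back(&gamma); grad.push_back(&dgamma);
    names.push_back(tag + ".beta"); par.push_back(&beta); grad.push_back(&dbeta);
    snames.push_back(tag + ".rmean"); state.push_back(&rmean);
    snames.push_back(tag + ".rvar"); state.push_back(&rvar);
    dgamma.zeros(1, c); dbeta.zeros(1, c);
  }
};

struct ReLU : Layer {
  fmat mask;
  void init(std::mt19937&) override {}
  fmat forward(const fmat& X, int, int&, int&, bool) override {
    mask = conv_to<fmat>::from(X > 0.0f);
    return X % mask;
  }
  fmat backward(const fmat& dY) override { return dY % mask; }
  void collect(const std::string&, std::vector<std::string>&,
               std::vector<fmat*>&, std::vector<fmat*>&,
               std::vector<std::string>&, std::vector<fmat*>&) override {}
};

struct MaxPool2 : Layer {
  int B_, H_, W_, Ho, Wo;
  Mat<uword> amax;  // winning input row per (output row, channel)
  void init(std::mt19937&) override {}
  fmat forward(const fmat& X, int B, int& H, int& W, bool) override {
    B_ = B; H_ = H; W_ = W; Ho = H / 2; Wo = W / 2;
    const int C = X.n_cols;
    fmat Y(((uword)B) * Ho * Wo, C);
    Y.fill(-std::numeric_limits<float>::infinity());
    amax.set_size(Y.n_rows, C);
    for (int b = 0; b < B; ++b)
      for (int x = 0; x < Wo; ++x)
        for (int y = 0; y < Ho; ++y) {
          const uword orow = (uword)b * Ho * Wo + (uword)x * Ho + y;
          for (int dx = 0; dx < 2; ++dx)
            for (int dy = 0; dy < 2; ++dy) {
              const uword irow = (uword)b * H_ * W_ +
                (uword)(2 * x + dx) * H_ + (2 * y + dy);
              for (int c = 0; c < C; ++c)
                if (X(irow, c) > Y(orow, c)) {
                  Y(orow, c) = X(irow, c);
                  amax(orow, c) = irow;
                }
            }
        }
    H = Ho; W = Wo;
    return Y;
  }
  fmat backward(const fmat& dY) override {
    fmat dX((uword)B_ * H_ * W_, dY.n_cols, fill::zeros);
    for (uword r = 0; r < dY.n_rows; ++r)
      for (uword c = 0; c < dY.n_cols; ++c)
        dX(amax(r, c), c) += dY(r, c);
    return dX;
  }
  void collect(const std::string&, std::vector<std::string>&,
               std::vector<fmat*>&, std::vector<fmat*>&,
               std::vector<std::string>&, std::vector<fmat*>&) override {}
};

// Global average pooling: (B*H*W) x C -> B x C; ends the spatial phase.
struct GAP : Layer {
  int B_, HW_;
  void init(std::mt19937&) override {}
  fmat forward(const fmat& X, int B, int& H, int& W, bool) override {
    B_ = B; HW_ = H * W;
    fmat Y(B, X.n_cols);
    for (int b = 0; b < B; ++b)
      Y.row(b) = mean(X.rows((uword)b * HW_, (uword)(b + 1) * HW_ - 1), 0);
    H = 1; W = 1;
    return Y;
  }
  fmat backward(const fmat& dY) override {
    fmat dX((uword)B_ * HW_, dY.n_cols);
    for (int b = 0; b < B_; ++b)
      dX.rows((uword)b * HW_, (uword)(b + 1) * HW_ - 1) =
        repmat(dY.row(b) / (float)HW_, HW_, 1);
    return dX;
  }
  void collect(const std::string&, std::vector<std::string>&,
               std::vector<fmat*>&, std::vector<fmat*>&,
               std::vector<std::string>&, std::vector<fmat*>&) override {}
};

// (B*H*W) x C -> B x (H*W*C), channel blocks concatenated.
struct Flatten : Layer {
  int B_, HW_, C_;
  void init(std::mt19937&) override {}
  fmat forward(const fmat& X, int B, int& H, int& W, bool) override {
    B_ = B; HW_ = H * W; C_ = X.n_cols;
    fmat Y(B, (uword)HW_ * C_);
    for (int b = 0; b < B; ++b) {
      fmat sub = X.rows((uword)b * HW_, (uword)(b + 1) * HW_ - 1);
      Y.row(b) = vectorise(sub, 0).t();
    }
    H = 1; W = 1;
    return Y;
  }
  fmat backward(const fmat& dY) override {
    fmat dX((uword)B_ * HW_, C_);
    for (int b = 0; b < B_; ++b)
      dX.rows((uword)b * HW_, (uword)(b + 1) * HW_ - 1) =
        reshape(dY.row(b).t(), HW_, C_);
    return dX;
  }
  void collect(const std::string&, std::vector<std::string>&,
               std::vector<fmat*>&, std::vector<fmat*>&,
               std::vector<std::string>&, std::vector<fmat*>&) override {}
};

struct Dense : Layer {
  int fin, fout;
  fmat W, b, dW, db, Xc;
  Dense(int fi, int fo) : fin(fi), fout(fo) {}
  void init(std::mt19937& rng) override {
    W = he_normal(fin, fout, fin, rng);
    b.zeros(1, fout);
  }
  fmat forward(const fmat& X, int, int&, int&, bool) override {
    Xc = X;
    fmat Y = X * W;
    Y.each_row() += b;
    return Y;
  }
  fmat backward(const fmat& dY) override {
    dW = Xc.t() * dY;
    db = sum(dY, 0);
    return dY * W.t();
  }
  void collect(const std::string& tag, std::vector<std::string>& names,
               std::vector<fmat*>& par, std::vector<fmat*>& grad,
               std::vector<std::string>&, std::vector<fmat*>&) override {
    names.push_back(tag + ".W"); par.push_back(&W); grad.push_back(&dW);
    names.push_back(tag + ".b"); par.push_back(&b); grad.push_back(&db);
    dW.zeros(fin, fout); db.zeros(1, fout);
  }
};

// Residual block: three conv-BN-ReLU stages (the last ReLU applied after
// the shortcut addition), identity shortcut when channels match, else
// 1x1 conv + BN projection.
struct ResBlock : Layer {
  Conv c1, c2, c3;
  BatchNorm b1, b2, b3;
  ReLU r1, r2, r3;
  bool project;
  std::unique_ptr<Conv> cs;
  std::unique_ptr<BatchNorm> bs;
  ResBlock(int cin, int c_mid1, int c_mid2, int cout, int k)
    : c1(k, cin, c_mid1), c2(k, c_mid1, c_mid2), c3(k, c_mid2, cout),
      b1(c_mid1), b2(c_mid2), b3(cout), project(cin != cout) {
    if (project) {
      cs.reset(new Conv(1, cin, cout));
      bs.reset(new BatchNorm(cout));
    }
  }
  void init(std::mt19937& rng) override {
    c1.init(rng); b1.init(rng); c2.init(rng); b2.init(rng);
    c3.init(rng); b3.init(rng);
    if (project) { cs->init(rng); bs->init(rng); }
  }
  fmat forward(const fmat& X, int B, int& H, int& W, bool train) override {
    fmat y = c1.forward(X, B, H, W, train);
    y = b1.forward(y, B, H, W, train);
    y = r1.forward(y, B, H, W, train);
    y = c2.forward(y, B, H, W, train);
    y = b2.forward(y, B, H, W, train);
    y = r2.forward(y, B, H, W, train);
    y = c3.forward(y, B, H, W, train);
    y = b3.forward(y, B, H, W, train);
    fmat s = X;
    if (project) {
      s = cs->forward(X, B, H, W, train);
      s = bs->forward(s, B, H, W, train);
    }
    y += s;
    return r3.forward(y, B, H, W, train);
  }
  fmat backward(const fmat& dY) override {
    fmat d = r3.backward(dY);
    fmat dshort = d;
    if (project) dshort = cs->backward(bs->backward(dshort));
    fmat dmain = b3.backward(d);
    dmain = c3.backward(dmain);
    dmain = r2.backward(dmain);
    dmain = b2.backward(dmain);
    dmain = c2.backward(dmain);
    dmain = r1.backward(dmain);
    dmain = b1.backward(dmain);
    dmain = c1.backward(dmain);
    return dmain + dshort;
  }
  void collect(const std::string& tag, std::vector<std::string>& names,
               std::vector<fmat*>& par, std::vector<fmat*>& grad,
               std::vector<std::string>& snames,
               std::vector<fmat*>& state) override {
    c1.collect(tag + ".conv1", names, par, grad, snames, state);
    b1.collect(tag + ".bn1", names, par, grad, snames, state);
    c2.collect(tag + ".conv2", names, par, grad, snames, state);
    b2.collect(tag + ".bn2", names, par, grad, snames, state);
    c3.collect(tag + ".conv3", names, par, grad, snames, state);
    b3.collect(tag + ".bn3", names, par, grad, snames, state);
    if (project) {
      cs->collect(tag + ".convs", names, par, grad, snames, state);
      bs->collect(tag + ".bns", names, par, grad, snames, state);
    }
  }
};

// ------------------------------------------------------------------ net

struct Net {
  std::vector<std::unique_ptr<Layer>> layers;
  std::vector<std::string> tags;
  std::vector<std::string> pnames, snames;
  std::vector<fmat*> par, grad, state;
  int input_size, n_classes;

  void add(Layer* l, const std::string& tag) {
    layers.emplace_back(l);
    tags.push_back(tag);
  }
  void finalize() {
    pnames.clear(); snames.clear(); par.clear(); grad.clear(); state.clear();
    for (size_t i = 0; i < layers.size(); ++i)
      layers[i]->collect(tags[i], pnames, par, grad, snames, state);
  }
  void init(int seed) {
    std::mt19937 rng((unsigned)seed);
    for (auto& l : layers) l->init(rng);
    finalize();
  }
  fmat forward(const fmat& X0, int B, bool train) {
    int H = input_size, W = input_size;
    fmat X = X0;
    for (auto& l : layers) X = l->forward(X, B, H, W, train);
    return X;  // logits, B x K
  }
  fmat backward(const fmat& dlogits) {
    fmat d = dlogits;
    for (size_t i = layers.size(); i-- > 0;) d = layers[i]->backward(d);
    return d;
  }
};

static Net* build_net(const std::string& kind, int input_size, int K) {
  Net* net = new Net();
  net->input_size = input_size;
  net->n_classes = K;
  if (kind == "fcn") {
    net->add(new Conv(5, 1, 128), "conv1");
    net->add(new BatchNorm(128), "bn1");
    net->add(new ReLU(), "relu1");
    net->add(new Conv(5, 128, 256), "conv2");
    net->add(new BatchNorm(256), "bn2");
    net->add(new ReLU(), "relu2");
    net->add(new Conv(5, 256, 128), "conv3");
    net->add(new BatchNorm(128), "bn3");
    net->add(new ReLU(), "relu3");
    net->add(new GAP(), "gap");
    net->add(new Dense(128, K), "head");
  } else if (kind == "resnet") {
    net->add(new ResBlock(1, 128, 256, 128, 5), "block1");
    net->add(new ResBlock(128, 128, 256, 128, 5), "block2");
    net->add(new ResBlock(128, 128, 256, 128, 5), "block3");
    net->add(new GAP(), "gap");
    net->add(new Dense(128, K), "head");
  } else if (kind == "cnn") {
    if (input_size < 4)
      Rcpp::stop("cnn baseline needs input size >= 4 for its two 2x2 "
                 "pooling stages, got %d", input_size);
    const int s1 = input_size / 2, s2 = s1 / 2;
    net->add(new Conv(3, 1, 32), "conv1");
    net->add(new ReLU(), "relu1");
    net->add(new MaxPool2(), "pool1");
    net->add(new Conv(3, 32, 32), "conv2");
    net->add(new ReLU(), "relu2");
    net->add(new MaxPool2(), "pool2");
    net->add(new Flatten(), "flatten");
    net->add(new Dense(s2 * s2 * 32, 125), "fc1");
    net->add(new ReLU(), "relu3");
    net->add(new Dense(125, 125), "fc2");
    net->add(new ReLU(), "relu4");
    net->add(new Dense(125, K), "head");
  } else {
    Rcpp::stop("unknown network kind: %s", kind.c_str());
  }
  return net;
}

// ------------------------------------------------- parameter marshalling

static Rcpp::List export_params(Net& net) {
  const size_t np = net.par.size(), ns = net.state.size();
  Rcpp::List out(np + ns);
  Rcpp::CharacterVector nm(np + ns);
  for (size_t i = 0; i < np; ++i) {
    out[i] = Rcpp::wrap(conv_to<mat>::from(*net.par[i]));
    nm[i] = net.pnames[i];
  }
  for (size_t i = 0; i < ns; ++i) {
    out[np + i] = Rcpp::wrap(conv_to<mat>::from(*net.state[i]));
    nm[np + i] = net.snames[i];
  }
  out.attr("names") = nm;
  return out;
}

static void import_params(Net& net, const Rcpp::List& params) {
  for (size_t i = 0; i < net.par.size(); ++i) {
    if (!params.containsElementNamed(net.pnames[i].c_str()))
      Rcpp::stop("missing parameter: %s", net.pnames[i].c_str());
    mat M = Rcpp::as<mat>(params[net.pnames[i]]);
    if (M.n_rows != net.par[i]->n_rows || M.n_cols != net.par[i]->n_cols)
      Rcpp::stop("parameter %s has wrong shape", net.pnames[i].c_str());
    *net.par[i] = conv_to<fmat>::from(M);
  }
  for (size_t i = 0; i < net.state.size(); ++i) {
    if (!params.containsElementNamed(net.snames[i].c_str()))
      Rcpp::stop("missing state tensor: %s", net.snames[i].c_str());
    *net.state[i] = conv_to<fmat>::from(Rcpp::as<mat>(params[net.snames[i]]));
  }
}

// Copy images (H x W x N cube, double) for the given indices into one
// activation matrix (B*H*W) x 1.
static fmat gather_batch(const cube& images, const std::vector<int>& idx) {
  const uword HW = images.n_rows * images.n_cols;
  fmat X(HW * idx.size(), 1);
  for (size_t b = 0; b < idx.size(); ++b) {
    const mat& sl = images.slice(idx[b]);
    X.submat(b * HW, 0, (b + 1) * HW - 1, 0) =
      conv_to<fmat>::from(vectorise(sl));
  }
  return X;
}

static fmat softmax_rows(const fmat& logits) {
  fmat P = logits;
  P.each_col() -= max(P, 1);
  P = exp(P);
  P.each_col() /= sum(P, 1);
  return P;
}

// ------------------------------------------------------------- R bridge

// [[Rcpp::export]]
Rcpp::List nn_init_cpp(std::string kind, int input_size, int n_classes,
                       int seed) {
  std::unique_ptr<Net> net(build_net(kind, input_size, n_classes));
  net->init(seed);
  return export_params(*net);
}

// [[Rcpp::export]]
Rcpp::List nn_train_cpp(std::string kind, int input_size, int n_classes,
                        Rcpp::List params, arma::cube images,
                        arma::ivec labels0, int epochs, double lr,
                        int batch_size, int seed) {
  const int N = images.n_slices;
  if ((int)labels0.n_elem != N)
    Rcpp::stop("got %d images but %d labels", N, (int)labels0.n_elem);
  if ((int)images.n_rows != input_size || (int)images.n_cols != input_size)
    Rcpp::stop("images are %dx%d but the network was built for %dx%d",
               (int)images.n_rows, (int)images.n_cols, input_size, input_size);
  std::unique_ptr<Net> net(build_net(kind, input_size, n_classes));
  net->init(seed);  // sizes all parameter tensors
  import_params(*net, params);

  // Adam state
  std::vector<fmat> am(net->par.size()), av(net->par.size());
  for (size_t i = 0; i < net->par.size(); ++i) {
    am[i].zeros(net->par[i]->n_rows, net->par[i]->n_cols);
    av[i].zeros(net->par[i]->n_rows, net->par[i]->n_cols);
  }
  const float b1 = 0.9f, b2 = 0.999f, aeps = 1e-8f;
  long tstep = 0;

  std::mt19937 rng((unsigned)seed + 0x9e3779b9u);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  std::vector<double> hist_loss(epochs), hist_acc(epochs);
  for (int e = 0; e < epochs; ++e) {
    std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0.0;
    int correct = 0;
    for (int start = 0; start < N; start += batch_size) {
      const int stop = std::min(N, start + batch_size);
      std::vector<int> idx(order.begin() + start, order.begin() + stop);
      const int B = (int)idx.size();
      fmat X = gather_batch(images, idx);
      fmat logits = net->forward(X, B, true);
      fmat P = softmax_rows(logits);
      fmat dlogits = P;
      for (int b = 0; b < B; ++b) {
        const int y = labels0[idx[b]];
        const float p = std::max(P(b, y), 1e-12f);
        loss_sum += -std::log((double)p);
        if ((int)index_max(P.row(b)) == y) ++correct;
        dlogits(b, y) -= 1.0f;
      }
      dlogits /= (float)B;
      net->backward(dlogits);
      ++tstep;
      const float corr =
        (float)(std::sqrt(1.0 - std::pow((double)b2, (double)tstep)) /
                (1.0 - std::pow((double)b1, (double)tstep)));
      for (size_t i = 0; i < net->par.size(); ++i) {
        am[i] = b1 * am[i] + (1.0f - b1) * (*net->grad[i]);
        av[i] = b2 * av[i] + (1.0f - b2) * square(*net->grad[i]);
        *net->par[i] -= (float)lr * corr * (am[i] / (sqrt(av[i]) + aeps));
      }
    }
    hist_loss[e] = loss_sum / N;
    hist_acc[e] = (double)correct / N;
    if (!std::isfinite(hist_loss[e]))
      Rcpp::stop("training diverged: non-finite loss at epoch %d "
                 "(learning rate too high?)", e + 1);
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("params") = export_params(*net),
    Rcpp::Named("loss") = hist_loss,
    Rcpp::Named("accuracy") = hist_acc);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix nn_predict_cpp(std::string kind, int input_size,
                                   int n_classes, Rcpp::List params,
                                   arma::cube images, int batch_size = 8) {
  const int N = images.n_slices;
  if ((int)images.n_rows != input_size || (int)images.n_cols != input_size)
    Rcpp::stop("images are %dx%d but the network was built for %dx%d",
               (int)images.n_rows, (int)images.n_cols, input_size, input_size);
  std::unique_ptr<Net> net(build_net(kind, input_size, n_classes));
  net->init(1);
  import_params(*net, params);
  mat out(N, n_classes);
  for (int start = 0; start < N; start += batch_size) {
    const int stop = std::min(N, start + batch_size);
    std::vector<int> idx;
    for (int i = start; i < stop; ++i) idx.push_back(i);
    fmat X = gather_batch(images, idx);
    fmat P = softmax_rows(net->forward(X, (int)idx.size(), false));
    out.rows(start, stop - 1) = conv_to<mat>::from(P);
  }
  return Rcpp::wrap(out);
}
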