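// Minimal CNN engine for 6D plane-pose regression: conv / batchnorm /
// pooling / linear layers with analytic backprop, two backbones (smallconv
// for CPU-scale training, resnet18 matching the standard 18-layer residual
// topology), and the pose loss head (Gram-Schmidt reconstruction of the
// rotation from the 6 head outputs, mean-norm translation + rotation losses
// with lambda weighting) differentiated end to end.
//
// Activations are arma::cube (H, W, C); a batch is std::vector<cube>.
// Parameters/gradients are packed into flat vectors in layer order so the R
// side owns initialization, Adam updates and checkpoint serialization.

#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

struct ParamInfo {
  std::string name;
  int size;
  int fan_in;
  std::string kind; // "weight" (He init) or "bias"/"bn_gamma"/"bn_beta"
};

struct Layer {
  virtual ~Layer() = default;
  virtual int nparams() const { return 0; }
  virtual void set_params(const double*& p) {}
  virtual void get_params(double*& p) const {}
  virtual void get_grads(double*& g) const {}
  virtual void zero_grad() {}
  virtual int nbuffers() const { return 0; }
  virtual void set_buffers(const double*& p) {}
  virtual void get_buffers(double*& p) const {}
  virtual void param_info(std::vector<ParamInfo>& out, const std::string& prefix) const {}
  virtual std::vector<cube> forward(const std::vector<cube>& x, bool train) = 0;
  virtual std::vector<cube> backward(const std::vector<cube>& dy) = 0;
};

// ---------------------------------------------------------------- Conv2d --
struct Conv2d : Layer {
  int in_c, out_c, k, stride, pad;
  mat W;  // (out_c, in_c*k*k)
  vec b;
  mat dW;
  vec db;
  std::vector<mat> cols_cache;
  int in_h = 0, in_w = 0;

  Conv2d(int ic, int oc, int kk, int s, int p)
    : in_c(ic), out_c(oc), k(kk), stride(s), pad(p),
      W(oc, ic * kk * kk, arma::fill::zeros), b(oc, arma::fill::zeros),
      dW(arma::size(W), arma::fill::zeros), db(oc, arma::fill::zeros) {}

  int out_dim(int n) const { return (n + 2 * pad - k) / stride + 1; }
  int nparams() const override { return W.n_elem + b.n_elem; }
  void set_params(const double*& p) override {
    std::copy(p, p + W.n_elem, W.memptr()); p += W.n_elem;
    std::copy(p, p + b.n_elem, b.memptr()); p += b.n_elem;
  }
  void get_params(double*& p) const override {
    std::copy(W.memptr(), W.memptr() + W.n_elem, p); p += W.n_elem;
    std::copy(b.memptr(), b.memptr() + b.n_elem, p); p += b.n_elem;
  }
  void get_grads(double*& g) const override {
    std::copy(dW.memptr(), dW.memptr() + dW.n_elem, g); g += dW.n_elem;
    std::copy(db.memptr(), db.memptr() + db.n_elem, g); g += db.n_elem;
  }
  void zero_grad() override { dW.zeros(); db.zeros(); }
  void param_info(std::vector<ParamInfo>& out, const std::string& prefix) const override {
    out.push_back({prefix + ".W", (int)W.n_elem, in_c * k * k, "weight"});
    out.push_back({prefix + ".b", (int)b.n_elem, in_c * k * k, "bias"});
  }

  mat im2col(const cube& x, int oh, int ow) const {
    mat cols(in_c * k * k, oh * ow, arma::fill::zeros);
    for (int c = 0; c < in_c; ++c) {
      const mat& xc = x.slice(c);
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          int r = (c * k + kj) * k + ki;
          for (int oj = 0; oj < ow; ++oj) {
            int jj = oj * stride - pad + kj;
            if (jj < 0 || jj >= in_w) continue;
            for (int oi = 0; oi < oh; ++oi) {
              int ii = oi * stride - pad + ki;
              if (ii < 0 || ii >= in_h) continue;
              cols(r, oi + oh * oj) = xc(ii, jj);
            }
          }
        }
      }
    }
    return cols;
  }

  void col2im(const mat& dcols, cube& dx, int oh, int ow) const {
    for (int c = 0; c < in_c; ++c) {
      mat& xc = dx.slice(c);
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          int r = (c * k + kj) * k + ki;
          for (int oj = 0; oj < ow; ++oj) {
            int jj = oj * stride - pad + kj;
            if (jj < 0 || jj >= in_w) continue;
            for (int oi = 0; oi < oh; ++oi) {
              int ii = oi * stride - pad + ki;
              if (ii < 0 || ii >= in_h) continue;
              xc(ii, jj) += dcols(r, oi + oh * oj);
            }
          }
        }
      }
    }
  }

  std::vector<cube> forward(const std::vector<cube>& x, bool train) override {
    int n = x.size();
    in_h = x[0].n_rows; in_w = x[0].n_cols;
    int oh = out_dim(in_h), ow = out_dim(in_w);
    cols_cache.assign(n, mat());
    std::vector<cube> y(n);
    for (int s = 0; s < n; ++s) {
      mat cols = im2col(x[s], oh, ow);
      mat Y = W * cols;
      Y.each_col() += b;
      y[s] = cube(oh, ow, out_c);
      for (int c = 0; c < out_c; ++c)
        y[s].slice(c) = arma::reshape(Y.row(c), oh, ow);
      cols_cache[s] = std::move(cols);
    }
    return y;
  }

  std::vector<cube> backward(const std::vector<cube>& dy) override {
    int n = dy.size();
    int oh = dy[0].n_rows, ow = dy[0].n_cols;
    std::vector<cube> dx(n);
    for (int s = 0; s < n; ++s) {
      mat dY(out_c, oh * ow);
      for (int c = 0; c < out_c; ++c)
        dY.row(c) = arma::vectorise(dy[s].slice(c)).t();
      dW += dY * cols_cache[s].t();
      db += arma::sum(dY, 1);
      mat dcols = W.t() * dY;
      dx[s] = cube(in_h, in_w, in_c, arma::fill::zeros);
      col2im(dcols, dx[s], oh, ow);
    }
    return dx;
  }
};

// ------------------------------------------------------------------ ReLU --
struct ReLU : Layer {
  std::vector<cube> out_cache;
  std::vector<cube> forward(const std::vector<cube>& x, bool train) override {
    int n = x.size();
    std::vector<cube> y(n);
    for (int s = 0; s < n; ++s) y[s] = arma::clamp(x[s], 0.0, arma::datum::inf);
    out_cache = y;
    return y;
  }
  std::vector<cube> backward(const std::vector<cube>& dy) override {
    int n = dy.size();
    std::vector<cube> dx(n);
    for (int s = 0; s < n; ++s)
      dx[s] = dy[s] % arma::conv_to<cube>::from(out_cache[s] > 0);
    return dx;
  }
};

// ----------------------------------------------------------- BatchNorm2d --
struct BatchNorm2d : Layer {
  int C;
  double eps = 1e-5, momentum = 0.1;
  vec gamma, beta, dgamma, dbeta, run_mean, run_var;
  std::vector<cube> xhat_cache;
  vec invstd;
  double count = 0;

  explicit BatchNorm2d(int c)
    : C(c), gamma(c, arma::fill::ones), beta(c, arma::fill::zeros),
      dgamma(c, arma::fill::zeros), dbeta(c, arma::fill::zeros),
      run_mean(c, arma::fill::zeros), run_var(c, arma::fill::ones) {}

  int nparams() const override { return 2 * C; }
  void set_params(const double*& p) override {
    std::copy(p, p + C, gamma.memptr()); p += C;
    std::copy(p, p + C, beta.memptr()); p += C;
  }
  void get_params(double*& p) const override {
    std::copy(gamma.memptr(), gamma.memptr() + C, p); p += C;
    std::copy(beta.memptr(), beta.memptr() + C, p); p += C;
  }
  void get_grads(double*& g) const override {
    std::copy(dgamma.memptr(), dgamma.memptr() + C, g); g += C;
    std::copy(dbeta.memptr(), dbeta.memptr() + C, g); g += C;
  }
  void zero_grad() override { dgamma.zeros(); dbeta.zeros(); }
  int nbuffers() const override { return 2 * C; }
  void set_buffers(const double*& p) override {
    std::copy(p, p + C, run_mean.memptr()); p += C;
    std::copy(p, p + C, run_var.memptr()); p += C;
  }
  void get_buffers(double*& p) const override {
    std::copy(run_mean.memptr(), run_mean.memptr() + C, p); p += C;
    std::copy(run_var.memptr(), run_var.memptr() + C, p); p += C;
  }
  void param_info(std::vector<ParamInfo>& out, const std::string& prefix) const override {
    out.push_back({prefix + ".gamma", C, C, "bn_gamma"});
    out.push_back({prefix + ".beta", C, C, "bn_beta"});
  }

  std::vector<cube> forward(const std::vector<cube>& x, bool train) override {
    int n = x.size();
    std::vector<cube> y(n);
    if (train) {
      count = (double)n * x[0].n_rows * x[0].n_cols;
      vec mean_(C, arma::fill::zeros), var_(C, arma::fill::zeros);
      for (int s = 0; s < n; ++s)
        for (int c = 0; c < C; ++c) mean_(c) += arma::accu(x[s].slice(c));
      mean_ /= count;
      for (int s = 0; s < n; ++s)
        for (int c = 0; c < C; ++c)
          var_(c) += arma::accu(arma::square(x[s].slice(c) - mean_(c)));
      var_ /= count;
      invstd = 1.0 / arma::sqrt(var_ + eps);
      run_mean = (1 - momentum) * run_mean + momentum * mean_;
      run_var = (1 - momentum) * run_var + momentum * var_;
      xhat_cache.assign(n, cube());
      for (int s = 0; s < n; ++s) {
        cube xh(arma::size(x[s]));
        for (int c = 0; c < C; ++c)
          xh.slice(c) = (x[s].slice(c) - mean_(c)) * invstd(c);
        y[s] = cube(arma::size(xh));
        for (int c = 0; c < C; ++c)
          y[s].slice(c) = gamma(c) * xh.slice(c) + beta(c);
        xhat_cache[s] = std::move(xh);
      }
    } else {
      vec is = 1.0 / arma::sqrt(run_var + eps);
      for (int s = 0; s < n; ++s) {
        y[s] = cube(arma::size(x[s]));
        for (int c = 0; c < C; ++c)
          y[s].slice(c) = gamma(c) * (x[s].slice(c) - run_mean(c)) * is(c) + beta(c);
      }
    }
    return y;
  }

  std::vector<cube> backward(const std::vector<cube>& dy) override {
    int n = dy.size();
    vec sum_dy(C, arma::fill::zeros), sum_dy_xhat(C, arma::fill::zeros);
    for (int s = 0; s < n; ++s)
      for (int c = 0; c < C; ++c) {
        sum_dy(c) += arma::accu(dy[s].slice(c));
        sum_dy_xhat(c) += arma::accu(dy[s].slice(c) % xhat_cache[s].slice(c));
      }
    dbeta += sum_dy;
    dgamma += sum_dy_xhat;
    std::vector<cube> dx(n);
    for (int s = 0; s < n; ++s) {
      dx[s] = cube(arma::size(dy[s]));
      for (int c = 0; c < C; ++c)
        dx[s].slice(c) = (gamma(c) * invstd(c)) *
          (dy[s].slice(c) - sum_dy(c) / count -
           xhat_cache[s].slice(c) * (sum_dy_xhat(c) / count));
    }
    return dx;
  }
};

// --------------------------------------------------------------- MaxPool --
struct MaxPool : Layer {
  int k, stride, pad;
  int in_h = 0, in_w = 0, C = 0;
  std::vector<arma::umat> argmax; // per sample: (oh*ow, C) flat input index
  MaxPool(int kk, int s, int p) : k(kk), stride(s), pad(p) {}
  int out_dim(int n) const { return (n + 2 * pad - k) / stride + 1; }

  std::vector<cube> forward(const std::vector<cube>& x, bool train) override {
    int n = x.size();
    in_h = x[0].n_rows; in_w = x[0].n_cols; C = x[0].n_slices;
    int oh = out_dim(in_h), ow = out_dim(in_w);
    argmax.assign(n, arma::umat(oh * ow, C));
    std::vector<cube> y(n);
    for (int s = 0; s < n; ++s) {
      y[s] = cube(oh, ow, C);
      for (int c = 0; c < C; ++c) {
        const mat& xc = x[s].slice(c);
        for (int oj = 0; oj < ow; ++oj)
          for (int oi = 0; oi < oh; ++oi) {
            double best = -arma::datum::inf;
            arma::uword besti = 0;
            for (int kj = 0; kj < k; ++kj) {
              int jj = oj * stride - pad + kj;
              if (jj < 0 || jj >= in_w) continue;
              for (int ki = 0; ki < k; ++ki) {
                int ii = oi * stride - pad + ki;
                if (ii < 0 || ii >= in_h) continue;
                if (xc(ii, jj) > best) { best = xc(ii, jj); besti = ii + in_h * jj; }
              }
            }
            y[s](oi, oj, c) = best;
            argmax[s](oi + oh * oj, c) = besti;
          }
      }
    }
    return y;
  }

  std::vector<cube> backward(const std::vector<cube>& dy) override {
    int n = dy.size();
    int oh = dy[0].n_rows, ow = dy[0].n_cols;
    std::vector<cube> dx(n);
    for (int s = 0; s < n; ++s) {
      dx[s] = cube(in_h, in_w, C, arma::fill::zeros);
      for (int c = 0; c < C; ++c) {
        mat& dc = dx[s].slice(c);
        for (int q = 0; q < oh * ow; ++q)
          dc(argmax[s](q, c)) += dy[s](q % oh, q / oh, c);
      }
    }
    return dx;
  }
};

// --------------------------------------------------------- GlobalAvgPool --
struct GlobalAvgPool : Layer {
  int in_h = 0, in_w = 0;
  std::vector<cube> forward(const std::vector<cube>& x, bool train) override {
    int n = x.size();
    in_h = x[0].n_rows; in_w = x[0].n_cols;
    std::vector<cube> y(n);
    for (int s = 0; s < n; ++s) {
      int C = x[s].n_slices;
      y[s] = cube(1, 1, C);
      for (int c = 0; c < C; ++c) y[s](0, 0, c) = arma::accu(x[s].slice(c)) / (in_h * in_w);
    }
    return y;
  }
  std::vector<cube> backward(const std::vector<cube>& dy) override {
    int n = dy.size();
    std::vector<cube> dx(n);
    for (int s = 0; s < n; ++s) {
      int C = dy[s].n_slices;
      dx[s] = cube(in_h, in_w, C);
      for (int c = 0; c < C; ++c)
        dx[s].slice(c).fill(dy[s](0, 0, c) / (in_h * in_w));
    }
    return dx;
  }
};

// --------------------------------------------------------------- Flatten --
struct Flatten : Layer {
  int in_h = 0, in_w = 0, in_c = 0;
  std::vector<cube> forward(const std::vector<cube>& x, bool train) override {
    int n = x.size();
    in_h = x[0].n_rows; in_w = x[0].n_cols; in_c = x[0].n_slices;
    std::vector<cube> y(n);
    for (int s = 0; s < n; ++s) {
      cube f(1, 1, in_h * in_w * in_c);
      std::copy(x[s].memptr(), x[s].memptr() + x[s].n_elem, f.memptr());
      y[s] = std::move(f);
    }
    return y;
  }
  std::vector<cube> backward(const std::vector<cube>& dy) override {
    int n = dy.size();
    std::vector<cube> dx(n);
    for (int s = 0; s < n; ++s) {
      cube g(in_h, in_w, in_c);
      std::copy(dy[s].memptr(), dy[s].memptr() + dy[s].n_elem, g.memptr());
      dx[s] = std::move(g);
    }
    return dx;
  }
};

// ---------------------------------------------------------------- Linear --
struct Linear : Layer {
  int in_n, out_n;
  mat W; vec b; mat dW; vec db;
  std::vector<vec> x_cache;
  Linear(int i, int o)
    : in_n(i), out_n(o), W(o, i, arma::fill::zeros), b(o, arma::fill::zeros),
      dW(o, i, arma::fill::zeros), db(o, arma::fill::zeros) {}
  int nparams() const override { return W.n_elem + b.n_elem; }
  void set_params(const double*& p) override {
    std::copy(p, p + W.n_elem, W.memptr()); p += W.n_elem;
    std::copy(p, p + b.n_elem, b.memptr()); p += b.n_elem;
  }
  void get_params(double*& p) const override {
    std::copy(W.memptr(), W.memptr() + W.n_elem, p); p += W.n_elem;
    std::copy(b.memptr(), b.memptr() + b.n_elem, p); p += b.n_elem;
  }
  void get_grads(double*& g) const override {
    std::copy(dW.memptr(), dW.memptr() + dW.n_elem, g); g += dW.n_elem;
    std::copy(db.memptr(), db.memptr() + db.n_elem, g); g += db.n_elem;
  }
  void zero_grad() override { dW.zeros(); db.zeros(); }
  void param_info(std::vector<ParamInfo>& out, const std::string& prefix) const override {
    out.push_back({prefix + ".W", (int)W.n_elem, in_n, "weight"});
    out.push_back({prefix + ".b", (int)b.n_elem, in_n, "bias"});
  }
  std::vector<cube> forward(const std::vector<cube>& x, bool train) override {
    int n = x.size();
    x_cache.assign(n, vec());
    std::vector<cube> y(n);
    for (int s = 0; s < n; ++s) {
      vec xv(const_cast<double*>(x[s].memptr()), x[s].n_elem);
      vec yv = W * xv + b;
      y[s] = cube(1, 1, out_n);
      std::copy(yv.memptr(), yv.memptr() + out_n, y[s].memptr());
      x_cache[s] = xv;
    }
    return y;
  }
  std::vector<cube> backward(const std::vector<cube>& dy) override {
    int n = dy.size();
    std::vector<cube> dx(n);
    for (int s = 0; s < n; ++s) {
      vec dyv(const_cast<double*>(dy[s].memptr()), dy[s].n_elem);
      dW += dyv * x_cache[s].t();
      db += dyv;
      vec dxv = W.t() * dyv;
      dx[s] = cube(1, 1, in_n);
      std::copy(dxv.memptr(), dxv.memptr() + in_n, dx[s].memptr());
    }
    return dx;
  }
};

// -------------------------------------------------------------- SplitHead --
// Regression head with separate branches: rotation (6 values) from globally
// averaged features, translation (3 values) from the flattened feature map
// through a small MLP. Translation-branch parameters receive gradients only
// from the translation loss, so with Adam they train at full speed however
// small the lambda weighting makes that loss term.
struct SplitHead : Layer {
  GlobalAvgPool gap;
  Flatten fl;
  Conv2d reduce;   // 1x1 conv: keeps the translation branch spatially aware
  Linear lin_rot, lin_t1, lin_t2;
  ReLU relu_r, relu_t;

  SplitHead(int channels, int spatial, int t_chans, int hidden)
    : reduce(channels, t_chans, 1, 1, 0), lin_rot(channels, 6),
      lin_t1(t_chans * spatial * spatial, hidden), lin_t2(hidden, 3) {}

  template <typename F> void each(F f) {
    f(reduce); f(lin_rot); f(lin_t1); f(lin_t2);
  }
  template <typename F> void each_const(F f) const {
    f(reduce); f(lin_rot); f(lin_t1); f(lin_t2);
  }
  int nparams() const override {
    int n = 0; each_const([&](const Layer& l) { n += l.nparams(); }); return n;
  }
  void set_params(const double*& p) override { each([&](Layer& l) { l.set_params(p); }); }
  void get_params(double*& p) const override { each_const([&](const Layer& l) { l.get_params(p); }); }
  void get_grads(double*& g) const override { each_const([&](const Layer& l) { l.get_grads(g); }); }
  void zero_grad() override { each([&](Layer& l) { l.zero_grad(); }); }
  void param_info(std::vector<ParamInfo>& out, const std::string& prefix) const override {
    reduce.param_info(out, prefix + ".reduce");
    lin_rot.param_info(out, prefix + ".rot");
    lin_t1.param_info(out, prefix + ".t1");
    lin_t2.param_info(out, prefix + ".t2");
  }

  std::vector<cube> forward(const std::vector<cube>& x, bool train) override {
    std::vector<cube> r = lin_rot.forward(gap.forward(x, train), train);
    std::vector<cube> t = lin_t2.forward(relu_t.forward(lin_t1.forward(
      fl.forward(relu_r.forward(reduce.forward(x, train), train), train),
      train), train), train);
    int n = x.size();
    std::vector<cube> y(n);
    for (int s = 0; s < n; ++s) {
      y[s] = cube(1, 1, 9);
      for (int j = 0; j < 3; ++j) y[s](0, 0, j) = t[s](0, 0, j);
      for (int j = 0; j < 6; ++j) y[s](0, 0, 3 + j) = r[s](0, 0, j);
    }
    return y;
  }

  std::vector<cube> backward(const std::vector<cube>& dy) override {
    int n = dy.size();
    std::vector<cube> dt(n), dr(n);
    for (int s = 0; s < n; ++s) {
      dt[s] = cube(1, 1, 3);
      dr[s] = cube(1, 1, 6);
      for (int j = 0; j < 3; ++j) dt[s](0, 0, j) = dy[s](0, 0, j);
      for (int j = 0; j < 6; ++j) dr[s](0, 0, j) = dy[s](0, 0, 3 + j);
    }
    std::vector<cube> dx_r = gap.backward(lin_rot.backward(dr));
    std::vector<cube> dx_t = reduce.backward(relu_r.backward(fl.backward(
      lin_t1.backward(relu_t.backward(lin_t2.backward(dt))))));
    for (int s = 0; s < n; ++s) dx_r[s] += dx_t[s];
    return dx_r;
  }
};

// ------------------------------------------------- residual basic block --
struct BasicBlock : Layer {
  Conv2d conv1, conv2;
  BatchNorm2d bn1, bn2;
  ReLU relu1;
  bool has_down;
  Conv2d down_conv;
  BatchNorm2d down_bn;
  std::vector<cube> sum_out; // post-add pre... cached ReLU output of the sum

  BasicBlock(int in_c, int out_c, int stride)
    : conv1(in_c, out_c, 3, stride, 1), conv2(out_c, out_c, 3, 1, 1),
      bn1(out_c), bn2(out_c),
      has_down(stride != 1 || in_c != out_c),
      down_conv(in_c, out_c, 1, stride, 0), down_bn(out_c) {}

  template <typename F> void each(F f) {
    f(conv1); f(bn1); f(conv2); f(bn2);
    if (has_down) { f(down_conv); f(down_bn); }
  }
  template <typename F> void each_const(F f) const {
    f(conv1); f(bn1); f(conv2); f(bn2);
    if (has_down) { f(down_conv); f(down_bn); }
  }
  int nparams() const override {
    int n = 0; each_const([&](const Layer& l) { n += l.nparams(); }); return n;
  }
  void set_params(const double*& p) override { each([&](Layer& l) { l.set_params(p); }); }
  void get_params(double*& p) const override { each_const([&](const Layer& l) { l.get_params(p); }); }
  void get_grads(double*& g) const override { each_const([&](const Layer& l) { l.get_grads(g); }); }
  void zero_grad() override { each([&](Layer& l) { l.zero_grad(); }); }
  int nbuffers() const override {
    int n = 0; each_const([&](const Layer& l) { n += l.nbuffers(); }); return n;
  }
  void set_buffers(const double*& p) override { each([&](Layer& l) { l.set_buffers(p); }); }
  void get_buffers(double*& p) const override { each_const([&](const Layer& l) { l.get_buffers(p); }); }
  void param_info(std::vector<ParamInfo>& out, const std::string& prefix) const override {
    conv1.param_info(out, prefix + ".conv1");
    bn1.param_info(out, prefix + ".bn1");
    conv2.param_info(out, prefix + ".conv2");
    bn2.param_info(out, prefix + ".bn2");
    if (has_down) {
      down_conv.param_info(out, prefix + ".down_conv");
      down_bn.param_info(out, prefix + ".down_bn");
    }
  }

  std::vector<cube> forward(const std::vector<cube>& x, bool train) override {
    std::vector<cube> h = bn1.forward(conv1.forward(x, train), train);
    h = relu1.forward(h, train);
    h = bn2.forward(conv2.forward(h, train), train);
    std::vector<cube> sc = has_down
      ? down_bn.forward(down_conv.forward(x, train), train) : x;
    int n = x.size();
    std::vector<cube> y(n);
    sum_out.assign(n, cube());
    for (int s = 0; s < n; ++s) {
      y[s] = arma::clamp(h[s] + sc[s], 0.0, arma::datum::inf);
      sum_out[s] = y[s];
    }
    return y;
  }

  std::vector<cube> backward(const std::vector<cube>& dy) override {
    int n = dy.size();
    std::vector<cube> dsum(n);
    for (int s = 0; s < n; ++s)
      dsum[s] = dy[s] % arma::conv_to<cube>::from(sum_out[s] > 0);
    std::vector<cube> dmain = conv1.backward(
      bn1.backward(relu1.backward(conv2.backward(bn2.backward(dsum)))));
    std::vector<cube> dsc = has_down
      ? down_conv.backward(down_bn.backward(dsum)) : dsum;
    for (int s = 0; s < n; ++s) dmain[s] += dsc[s];
    return dmain;
  }
};

// ------------------------------------------------------------------- Net --
struct Net {
  std::string backbone;
  int image_size, in_channels;
  // when true, input channels 2 and 3 are fixed x/y coordinate ramps in
  // [-1, 1] so the (otherwise shift-invariant) conv + GAP trunk can observe
  // absolute in-plane position — needed to regress in-plane translation
  bool coord_channels = false;
  std::vector<std::unique_ptr<Layer>> layers;

  int nparams() const {
    int n = 0;
    for (const auto& l : layers) n += l->nparams();
    return n;
  }
  int nbuffers() const {
    int n = 0;
    for (const auto& l : layers) n += l->nbuffers();
    return n;
  }
  std::vector<cube> forward(const std::vector<cube>& x, bool train) {
    std::vector<cube> h = x;
    for (auto& l : layers) h = l->forward(h, train);
    return h;
  }
  std::vector<cube> backward(const std::vector<cube>& dy) {
    std::vector<cube> g = dy;
    for (auto it = layers.rbegin(); it != layers.rend(); ++it)
      g = (*it)->backward(g);
    return g;
  }
};

static Net* build_net(const std::string& backbone, int image_size, int in_channels) {
  auto* net = new Net();
  net->backbone = backbone;
  net->image_size = image_size;
  net->in_channels = in_channels;
  auto& L = net->layers;
  if (backbone == "smallconv") {
    if (image_size % 16 != 0)
      stop("smallconv requires image_size divisible by 16, got %d", image_size);
    // 5 conv blocks, global average pooling and a small linear head: the
    // GAP head keeps the parameter count low so desk-scale datasets do not
    // just get memorized
    int chans[5] = {32, 64, 128, 128, 256};
    int strides[5] = {2, 2, 2, 1, 2};
    int in_c = in_channels;
    for (int blk = 0; blk < 5; ++blk) {
      int k = blk == 0 ? 5 : 3;
      L.emplace_back(new Conv2d(in_c, chans[blk], k, strides[blk], k / 2));
      L.emplace_back(new BatchNorm2d(chans[blk]));
      L.emplace_back(new ReLU());
      in_c = chans[blk];
    }
    L.emplace_back(new SplitHead(in_c, image_size / 16, 16, 64));
  } else if (backbone == "resnet18") {
    L.emplace_back(new Conv2d(in_channels, 64, 7, 2, 3));
    L.emplace_back(new BatchNorm2d(64));
    L.emplace_back(new ReLU());
    L.emplace_back(new MaxPool(3, 2, 1));
    int chans[4] = {64, 128, 256, 512};
    int in_c = 64;
    for (int stage = 0; stage < 4; ++stage) {
      int oc = chans[stage];
      int stride = stage == 0 ? 1 : 2;
      L.emplace_back(new BasicBlock(in_c, oc, stride));
      L.emplace_back(new BasicBlock(oc, oc, 1));
      in_c = oc;
    }
    L.emplace_back(new GlobalAvgPool());
    L.emplace_back(new Linear(512, 9));
  } else {
    stop("unknown backbone '" + backbone + "' (supported: smallconv, resnet18)");
  }
  return net;
}

static std::vector<cube> images_to_batch(const NumericVector& images,
                                         const Net& net) {
  IntegerVector d = images.attr("dim");
  if (d.size() != 3) stop("images must be an H x W x N array");
  int H = d[0], W = d[1], N = d[2];
  mat coord_x, coord_y;
  if (net.coord_channels) {
    coord_x.set_size(H, W);
    coord_y.set_size(H, W);
    for (int j = 0; j < W; ++j)
      coord_x.col(j).fill(W > 1 ? 2.0 * j / (W - 1) - 1.0 : 0.0);
    for (int i = 0; i < H; ++i)
      coord_y.row(i).fill(H > 1 ? 2.0 * i / (H - 1) - 1.0 : 0.0);
  }
  std::vector<cube> x(N);
  const double* p = images.begin();
  for (int s = 0; s < N; ++s) {
    cube im(H, W, net.in_channels);
    mat one(const_cast<double*>(p + (R_xlen_t)s * H * W), H, W, false, true);
    if (net.coord_channels) {
      im.slice(0) = one;
      im.slice(1) = coord_x;
      im.slice(2) = coord_y;
    } else {
      for (int c = 0; c < net.in_channels; ++c) im.slice(c) = one;
    }
    x[s] = std::move(im);
  }
  return x;
}

// ------------------------------------------ Gram-Schmidt head + losses ----
struct GSCache {
  vec v1, v2, e1, u2, e2, e3;
  double n1, n2;
};

static mat gs_forward(const vec& v1, const vec& v2, GSCache& cc, double eps = 1e-8) {
  cc.v1 = v1; cc.v2 = v2;
  cc.n1 = std::max(arma::norm(v1), eps);
  cc.e1 = v1 / cc.n1;
  cc.u2 = v2 - arma::dot(cc.e1, v2) * cc.e1;
  cc.n2 = std::max(arma::norm(cc.u2), eps);
  cc.e2 = cc.u2 / cc.n2;
  cc.e3 = arma::cross(cc.e1, cc.e2);
  mat R(3, 3);
  R.col(0) = cc.e1; R.col(1) = cc.e2; R.col(2) = cc.e3;
  return R;
}

static void gs_backward(const mat& dR, const GSCache& cc, vec& dv1, vec& dv2) {
  vec de1 = dR.col(0), de2 = dR.col(1), de3 = dR.col(2);
  // e3 = e1 x e2
  vec ge1 = de1 + arma::cross(cc.e2, de3);
  vec ge2 = de2 + arma::cross(de3, cc.e1);
  // e2 = u2 / |u2|
  vec gu2 = (ge2 - cc.e2 * arma::dot(cc.e2, ge2)) / cc.n2;
  // u2 = v2 - (e1 . v2) e1
  dv2 = gu2 - cc.e1 * arma::dot(cc.e1, gu2);
  ge1 += -arma::dot(cc.e1, gu2) * cc.v2 - arma::dot(cc.e1, cc.v2) * gu2;
  // e1 = v1 / |v1|
  dv1 = (ge1 - cc.e1 * arma::dot(cc.e1, ge1)) / cc.n1;
}

// [[Rcpp::export]]
NumericMatrix gs_rotation_cpp(NumericVector v1, NumericVector v2) {
  GSCache cc;
  mat R = gs_forward(vec(v1.begin(), 3), vec(v2.begin(), 3), cc);
  return wrap(R);
}

// -------------------------------------------------------- R entry points --
typedef XPtr<Net> NetPtr;

// [[Rcpp::export]]
SEXP nn_create(std::string backbone, int image_size, int in_channels) {
  return NetPtr(build_net(backbone, image_size, in_channels), true);
}

// TRUE iff the external pointer still holds a live network (serialized
// pointers come back NULL after readRDS).
// [[Rcpp::export]]
bool nn_ptr_valid(SEXP ptr) {
  return TYPEOF(ptr) == EXTPTRSXP && R_ExternalPtrAddr(ptr) != nullptr;
}

// [[Rcpp::export]]
int nn_nparams(SEXP ptr) { return NetPtr(ptr)->nparams(); }

// [[Rcpp::export]]
int nn_nbuffers(SEXP ptr) { return NetPtr(ptr)->nbuffers(); }

// [[Rcpp::export]]
List nn_param_info(SEXP ptr) {
  NetPtr net(ptr);
  std::vector<ParamInfo> info;
  for (size_t i = 0; i < net->layers.size(); ++i)
    net->layers[i]->param_info(info, "layer" + std::to_string(i));
  int n = info.size();
  CharacterVector name(n), kind(n);
  IntegerVector size(n), fan_in(n);
  for (int i = 0; i < n; ++i) {
    name[i] = info[i].name; kind[i] = info[i].kind;
    size[i] = info[i].size; fan_in[i] = info[i].fan_in;
  }
  return List::create(_["name"] = name, _["size"] = size,
                      _["fan_in"] = fan_in, _["kind"] = kind);
}

// [[Rcpp::export]]
void nn_set_params(SEXP ptr, NumericVector params) {
  NetPtr net(ptr);
  if ((int)params.size() != net->nparams())
    stop("parameter vector has length %d, expected %d", (int)params.size(), net->nparams());
  const double* p = params.begin();
  for (auto& l : net->layers) l->set_params(p);
}

// [[Rcpp::export]]
NumericVector nn_get_params(SEXP ptr) {
  NetPtr net(ptr);
  NumericVector out(net->nparams());
  double* p = out.begin();
  for (auto& l : net->layers) l->get_params(p);
  return out;
}

// [[Rcpp::export]]
void nn_set_buffers(SEXP ptr, NumericVector buf) {
  NetPtr net(ptr);
  if ((int)buf.size() != net->nbuffers())
    stop("buffer vector has length %d, expected %d", (int)buf.size(), net->nbuffers());
  const double* p = buf.begin();
  for (auto& l : net->layers) l->set_buffers(p);
}

// [[Rcpp::export]]
NumericVector nn_get_buffers(SEXP ptr) {
  NetPtr net(ptr);
  NumericVector out(net->nbuffers());
  double* p = out.begin();
  for (auto& l : net->layers) l->get_buffers(p);
  return out;
}

// Forward pass only: returns the 9 x N raw head output.
// [[Rcpp::export]]
NumericMatrix nn_forward_cpp(SEXP ptr, NumericVector images, bool train = false) {
  NetPtr net(ptr);
  std::vector<cube> x = images_to_batch(images, *net);
  std::vector<cube> y = net->forward(x, train);
  int N = y.size();
  NumericMatrix out(9, N);
  for (int s = 0; s < N; ++s)
    for (int j = 0; j < 9; ++j) out(j, s) = y[s](0, 0, j);
  return out;
}

// Full loss (and optionally gradient) for a batch.
// t_gt: 3 x N, R_gt: 3 x 3 x N (ground-truth rotation matrices).
// Losses follow the training objective: mean over the batch of the
// Euclidean / Frobenius norm of the difference (or of the squared norm when
// squared = true); total = rot + lambda * trans.
// [[Rcpp::export]]
List nn_loss_grad_cpp(SEXP ptr, NumericVector images, NumericMatrix t_gt,
                      NumericVector R_gt, double lambda, bool squared = false,
                      bool want_grad = true) {
  NetPtr net(ptr);
  std::vector<cube> x = images_to_batch(images, *net);
  std::vector<cube> y = net->forward(x, want_grad);
  int N = y.size();
  if (t_gt.ncol() != N) stop("t_gt has %d columns, expected %d", t_gt.ncol(), N);
  const cube Rg(const_cast<double*>(R_gt.begin()), 3, 3, N, false, true);

  double l_trans = 0, l_rot = 0;
  std::vector<cube> dy(N);
  const double eps = 1e-12;
  for (int s = 0; s < N; ++s) {
    vec th(9);
    for (int j = 0; j < 9; ++j) th(j) = y[s](0, 0, j);
    vec tp = th.subvec(0, 2), v1 = th.subvec(3, 5), v2 = th.subvec(6, 8);
    vec tg(const_cast<double*>(&t_gt(0, s)), 3, false, true);
    GSCache cc;
    mat Rp = gs_forward(v1, v2, cc);
    mat dRm = Rp - Rg.slice(s);
    vec dt = tp - tg;
    double nt = arma::norm(dt), nr = arma::norm(dRm, "fro");
    vec g(9, arma::fill::zeros);
    if (squared) {
      l_trans += nt * nt;
      l_rot += nr * nr;
      g.subvec(0, 2) = (2.0 * lambda / N) * dt;
      dRm *= 2.0 / N;
    } else {
      l_trans += nt;
      l_rot += nr;
      g.subvec(0, 2) = (lambda / N) * dt / std::max(nt, eps);
      dRm /= N * std::max(nr, eps);
    }
    if (want_grad) {
      vec dv1, dv2;
      gs_backward(dRm, cc, dv1, dv2);
      g.subvec(3, 5) = dv1;
      g.subvec(6, 8) = dv2;
      dy[s] = cube(1, 1, 9);
      std::copy(g.memptr(), g.memptr() + 9, dy[s].memptr());
    }
  }
  l_trans /= N;
  l_rot /= N;

  List out = List::create(_["loss_total"] = l_rot + lambda * l_trans,
                          _["loss_rot"] = l_rot, _["loss_trans"] = l_trans);
  if (want_grad) {
    for (auto& l : net->layers) l->zero_grad();
    net->backward(dy);
    NumericVector grad(net->nparams());
    double* g = grad.begin();
    for (auto& l : net->layers) l->get_grads(g);
    out["grad"] = grad;
  }
  return out;
}
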