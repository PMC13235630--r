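// Conditional GAN core: U-Net generator + PatchGAN discriminator trained with
// a least-squares adversarial loss and an L1 reconstruction term, all in
// float32 with im2col/GEMM convolutions. Tensors are stored channel-major:
// a (C x H*W*B) matrix whose column index is b*H*W + x*H + y, so channel
// concatenation is a row-bind and convolution is one GEMM per layer.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;

struct Tensor {
  fmat m;            // C x (H*W*B)
  int H = 0, W = 0, C = 0, B = 0;
};

// columns of the result enumerate (b, ow, oh); rows enumerate (kw, kh, c)
// with channel fastest, matching the weight layout used below.
static fmat im2col(const Tensor& X, int k, int s, int p, int& Ho, int& Wo) {
  Ho = (X.H + 2 * p - k) / s + 1;
  Wo = (X.W + 2 * p - k) / s + 1;
  fmat cols(k * k * X.C, (size_t)Ho * Wo * X.B, arma::fill::zeros);
  const int HW = X.H * X.W;
  for (int b = 0; b < X.B; ++b)
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh) {
        const size_t j = (size_t)b * Ho * Wo + (size_t)ow * Ho + oh;
        float* cp = cols.colptr(j);
        for (int kw = 0; kw < k; ++kw) {
          const int iw = ow * s - p + kw;
          if (iw < 0 || iw >= X.W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int ih = oh * s - p + kh;
            if (ih < 0 || ih >= X.H) continue;
            std::memcpy(cp + (size_t)(kw * k + kh) * X.C,
                        X.m.colptr((size_t)b * HW + (size_t)iw * X.H + ih),
                        X.C * sizeof(float));
          }
        }
      }
  return cols;
}

// adjoint of im2col: scatter-add columns indexed by (b, wpos, hpos) into an
// image of shape (Himg, Wimg, C, B). Also serves as the forward pass of the
// stride-2 transposed convolution (conv backward-data duality).
static Tensor col2im(const fmat& cols, int C, int B, int k, int s, int p,
                     int Himg, int Wimg, int Hpos, int Wpos) {
  Tensor X;
  X.H = Himg; X.W = Wimg; X.C = C; X.B = B;
  X.m.zeros(C, (size_t)Himg * Wimg * B);
  const int HW = Himg * Wimg;
  for (int b = 0; b < B; ++b)
    for (int ow = 0; ow < Wpos; ++ow)
      for (int oh = 0; oh < Hpos; ++oh) {
        const size_t j = (size_t)b * Hpos * Wpos + (size_t)ow * Hpos + oh;
        const float* cp = cols.colptr(j);
        for (int kw = 0; kw < k; ++kw) {
          const int iw = ow * s - p + kw;
          if (iw < 0 || iw >= Wimg) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int ih = oh * s - p + kh;
            if (ih < 0 || ih >= Himg) continue;
            const float* src = cp + (size_t)(kw * k + kh) * C;
            float* dst = X.m.colptr((size_t)b * HW + (size_t)iw * Himg + ih);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
  return X;
}

struct Param {
  fmat W, g, m, v;
  void init(int r, int c) {
    W.zeros(r, c); g.zeros(r, c); m.zeros(r, c); v.zeros(r, c);
  }
  void randn(std::mt19937& rng, float sd) {
    std::normal_distribution<float> nd(0.f, sd);
    for (arma::uword i = 0; i < W.n_elem; ++i) W[i] = nd(rng);
  }
};

static void adam_step(Param& p, float lr, float b1, float b2, int t) {
  const float eps = 1e-8f;
  p.m = b1 * p.m + (1 - b1) * p.g;
  p.v = b2 * p.v + (1 - b2) * arma::square(p.g);
  const float c1 = 1 - std::pow(b1, (float)t), c2 = 1 - std::pow(b2, (float)t);
  p.W -= lr * (p.m / c1) / (arma::sqrt(p.v / c2) + eps);
}

struct Conv {
  int cin, cout, k, s, p;
  Param W, b;
  fmat cols;
  int Hin = 0, Win = 0, Bc = 0;
  void init(int cin_, int cout_, int k_, int s_, int p_, std::mt19937& rng) {
    cin = cin_; cout = cout_; k = k_; s = s_; p = p_;
    W.init(cout, k * k * cin); W.randn(rng, 0.02f);
    b.init(cout, 1);
  }
  Tensor forward(const Tensor& X) {
    Hin = X.H; Win = X.W; Bc = X.B;
    int Ho, Wo;
    cols = im2col(X, k, s, p, Ho, Wo);
    Tensor Y; Y.H = Ho; Y.W = Wo; Y.C = cout; Y.B = X.B;
    Y.m = W.W * cols;
    fvec bv = b.W.col(0);
    Y.m.each_col() += bv;
    return Y;
  }
  Tensor backward(const Tensor& dY) {
    W.g += dY.m * cols.t();
    b.g += arma::sum(dY.m, 1);
    fmat dcols = W.W.t() * dY.m;
    return col2im(dcols, cin, Bc, k, s, p, Hin, Win, dY.H, dY.W);
  }
};

struct ConvT {
  int cin, cout, k, s, p;
  Param A, b;  // A: (k*k*cout) x cin
  fmat Xm;
  int Hin = 0, Win = 0, Bc = 0;
  void init(int cin_, int cout_, int k_, int s_, int p_, std::mt19937& rng) {
    cin = cin_; cout = cout_; k = k_; s = s_; p = p_;
    A.init(k * k * cout, cin); A.randn(rng, 0.02f);
    b.init(cout, 1);
  }
  Tensor forward(const Tensor& X) {
    Hin = X.H; Win = X.W; Bc = X.B; Xm = X.m;
    const int Ho = (X.H - 1) * s - 2 * p + k, Wo = (X.W - 1) * s - 2 * p + k;
    fmat colsT = A.W * X.m;
    Tensor Y = col2im(colsT, cout, X.B, k, s, p, Ho, Wo, X.H, X.W);
    fvec bv = b.W.col(0);
    Y.m.each_col() += bv;
    return Y;
  }
  Tensor backward(const Tensor& dY) {
    int Hpos, Wpos;
    fmat g = im2col(dY, k, s, p, Hpos, Wpos);  // positions == input grid
    A.g += g * Xm.t();
    b.g += arma::sum(dY.m, 1);
    Tensor dX; dX.H = Hin; dX.W = Win; dX.C = cin; dX.B = Bc;
    dX.m = A.W.t() * g;
    return dX;
  }
};

// per-sample, per-channel normalization: deterministic at inference,
// no running statistics.
struct INorm {
  int C = 0;
  Param g, be;
  fmat xhat, invstd;  // invstd: C x B
  int H = 0, W = 0, Bc = 0;
  void init(int C_) {
    C = C_;
    g.init(C, 1); g.W.ones();
    be.init(C, 1);
  }
  Tensor forward(const Tensor& X) {
    H = X.H; W = X.W; Bc = X.B;
    const int n = H * W;
    Tensor Y = X;
    xhat.set_size(C, (size_t)n * Bc);
    invstd.set_size(C, Bc);
    for (int b = 0; b < Bc; ++b)
      for (int c = 0; c < C; ++c) {
        double mu = 0, ss = 0;
        for (int t = 0; t < n; ++t) mu += X.m(c, (size_t)b * n + t);
        mu /= n;
        for (int t = 0; t < n; ++t) {
          const double d = X.m(c, (size_t)b * n + t) - mu;
          ss += d * d;
        }
        const float is = (float)(1.0 / std::sqrt(ss / n + 1e-5));
        invstd(c, b) = is;
        const float gc = g.W(c, 0), bc = be.W(c, 0);
        for (int t = 0; t < n; ++t) {
          const float xh = ((float)X.m(c, (size_t)b * n + t) - (float)mu) * is;
          xhat(c, (size_t)b * n + t) = xh;
          Y.m(c, (size_t)b * n + t) = gc * xh + bc;
        }
      }
    return Y;
  }
  Tensor backward(const Tensor& dY) {
    const int n = H * W;
    Tensor dX = dY;
    for (int b = 0; b < Bc; ++b)
      for (int c = 0; c < C; ++c) {
        const float gc = g.W(c, 0), is = invstd(c, b);
        double m1 = 0, m2 = 0, sg = 0, sb = 0;
        for (int t = 0; t < n; ++t) {
          const size_t j = (size_t)b * n + t;
          const float dy = dY.m(c, j), xh = xhat(c, j);
          m1 += dy; m2 += dy * xh; sg += dy * xh; sb += dy;
        }
        const float a1 = (float)(gc * m1 / n), a2 = (float)(gc * m2 / n);
        for (int t = 0; t < n; ++t) {
          const size_t j = (size_t)b * n + t;
          dX.m(c, j) = is * (gc * dY.m(c, j) - a1 - xhat(c, j) * a2);
        }
        g.g(c, 0) += (float)sg;
        be.g(c, 0) += (float)sb;
      }
    return dX;
  }
};

struct Act {  // 0 = leaky ReLU (0.2), 1 = ReLU, 2 = tanh
  int type = 0;
  fmat cache;
  Tensor forward(Tensor X) {
    if (type == 2) {
      X.m = arma::tanh(X.m);
      cache = X.m;
    } else {
      const float a = type == 0 ? 0.2f : 0.f;
      cache.set_size(arma::size(X.m));
      for (arma::uword i = 0; i < X.m.n_elem; ++i) {
        cache[i] = X.m[i] > 0 ? 1.f : a;
        X.m[i] *= cache[i];
      }
    }
    return X;
  }
  Tensor backward(Tensor dY) {
    if (type == 2)
      dY.m %= (1.f - arma::square(cache));
    else
      dY.m %= cache;
    return dY;
  }
};

struct Drop {
  fmat mask;
  bool active = false;
  Tensor forward(Tensor X, std::mt19937& rng, bool training) {
    active = training;
    if (!training) return X;
    std::uniform_real_distribution<float> u(0.f, 1.f);
    mask.set_size(arma::size(X.m));
    for (arma::uword i = 0; i < mask.n_elem; ++i)
      mask[i] = u(rng) < 0.5f ? 0.f : 2.f;
    X.m %= mask;
    return X;
  }
  Tensor backward(Tensor dY) {
    if (active) dY.m %= mask;
    return dY;
  }
};

static Tensor concat_c(const Tensor& A, const Tensor& B) {
  Tensor Y = A;
  Y.C = A.C + B.C;
  Y.m = arma::join_cols(A.m, B.m);
  return Y;
}

static void add_into(Tensor& acc, const Tensor& x) {
  if (acc.m.n_elem == 0) acc = x; else acc.m += x.m;
}

struct Gen {
  int S, F, d;
  std::vector<int> ec;
  std::vector<Conv> enc;
  std::vector<INorm> encN;
  std::vector<Act> encA;
  std::vector<ConvT> dec;
  std::vector<INorm> decN;
  std::vector<Drop> decD;
  std::vector<Act> decA;
  std::vector<Tensor> skips;

  Gen(int S_, int F_, std::mt19937& rng) : S(S_), F(F_) {
    d = 0;
    for (int t = S; t > 2; t /= 2) ++d;  // log2(S) - 1 downsampling stages
    ec.resize(d);
    for (int i = 0; i < d; ++i) ec[i] = std::min(F << i, 8 * F);
    enc.resize(d); encN.resize(d - 1); encA.resize(d);
    dec.resize(d); decN.resize(d - 1); decD.resize(3); decA.resize(d);
    for (int i = 0; i < d; ++i) {
      enc[i].init(i == 0 ? 1 : ec[i - 1], ec[i], 4, 2, 1, rng);
      encA[i].type = 0;
      if (i > 0) encN[i - 1].init(ec[i]);
    }
    for (int j = 0; j < d; ++j) {
      const int cin = j == 0 ? ec[d - 1] : 2 * ec[d - 1 - j];
      const int cout = j < d - 1 ? ec[d - 2 - j] : 1;
      dec[j].init(cin, cout, 4, 2, 1, rng);
      decA[j].type = j < d - 1 ? 1 : 2;
      if (j < d - 1) decN[j].init(cout);
    }
  }

  Tensor forward(const Tensor& X, bool training, std::mt19937& rng) {
    skips.assign(d, Tensor());
    Tensor T = X;
    for (int i = 0; i < d; ++i) {
      T = enc[i].forward(T);
      if (i > 0) T = encN[i - 1].forward(T);
      T = encA[i].forward(T);
      skips[i] = T;
    }
    for (int j = 0; j < d; ++j) {
      Tensor in = j == 0 ? skips[d - 1] : concat_c(T, skips[d - 1 - j]);
      T = dec[j].forward(in);
      if (j < d - 1) {
        T = decN[j].forward(T);
        if (j < 3) T = decD[j].forward(T, rng, training);
      }
      T = decA[j].forward(T);
    }
    return T;
  }

  Tensor backward(const Tensor& dOut) {
    std::vector<Tensor> dskips(d);
    Tensor dT = dOut;
    for (int j = d - 1; j >= 0; --j) {
      dT = decA[j].backward(dT);
      if (j < d - 1) {
        if (j < 3) dT = decD[j].backward(dT);
        dT = decN[j].backward(dT);
      }
      Tensor dIn = dec[j].backward(dT);
      if (j == 0) {
        add_into(dskips[d - 1], dIn);
      } else {
        const int c1 = ec[d - 1 - j];
        Tensor dPrev = dIn, dSk = dIn;
        dPrev.m = dIn.m.rows(0, c1 - 1); dPrev.C = c1;
        dSk.m = dIn.m.rows(c1, dIn.C - 1); dSk.C = dIn.C - c1;
        add_into(dskips[d - 1 - j], dSk);
        dT = dPrev;
      }
    }
    Tensor dE = dskips[d - 1];
    for (int i = d - 1; i >= 0; --i) {
      dE = encA[i].backward(dE);
      if (i > 0) dE = encN[i - 1].backward(dE);
      Tensor dX = enc[i].backward(dE);
      if (i == 0) return dX;
      dE = dX;
      if (dskips[i - 1].m.n_elem) dE.m += dskips[i - 1].m;
    }
    return dE;  // unreached
  }

  void params(std::vector<std::pair<std::string, Param*>>& out) {
    for (int i = 0; i < d; ++i) {
      out.push_back({"enc" + std::to_string(i) + "_W", &enc[i].W});
      out.push_back({"enc" + std::to_string(i) + "_b", &enc[i].b});
      if (i > 0) {
        out.push_back({"enc" + std::to_string(i) + "_g", &encN[i - 1].g});
        out.push_back({"enc" + std::to_string(i) + "_beta", &encN[i - 1].be});
      }
    }
    for (int j = 0; j < d; ++j) {
      out.push_back({"dec" + std::to_string(j) + "_W", &dec[j].A});
      out.push_back({"dec" + std::to_string(j) + "_b", &dec[j].b});
      if (j < d - 1) {
        out.push_back({"dec" + std::to_string(j) + "_g", &decN[j].g});
        out.push_back({"dec" + std::to_string(j) + "_beta", &decN[j].be});
      }
    }
  }
};

struct Disc {
  int F;
  Conv c0, c1, c2, c3, c4;
  INorm n1, n2, n3;
  Act a0, a1, a2, a3;
  Disc(int F_, std::mt19937& rng) : F(F_) {
    c0.init(2, F, 4, 2, 1, rng);
    c1.init(F, 2 * F, 4, 2, 1, rng); n1.init(2 * F);
    c2.init(2 * F, 4 * F, 4, 2, 1, rng); n2.init(4 * F);
    c3.init(4 * F, 8 * F, 4, 1, 1, rng); n3.init(8 * F);
    c4.init(8 * F, 1, 4, 1, 1, rng);
    a0.type = a1.type = a2.type = a3.type = 0;
  }
  Tensor forward(const Tensor& X) {
    Tensor T = a0.forward(c0.forward(X));
    T = a1.forward(n1.forward(c1.forward(T)));
    T = a2.forward(n2.forward(c2.forward(T)));
    T = a3.forward(n3.forward(c3.forward(T)));
    return c4.forward(T);
  }
  Tensor backward(const Tensor& dP) {
    Tensor dT = c4.backward(dP);
    dT = c3.backward(n3.backward(a3.backward(dT)));
    dT = c2.backward(n2.backward(a2.backward(dT)));
    dT = c1.backward(n1.backward(a1.backward(dT)));
    return c0.backward(a0.backward(dT));
  }
  void params(std::vector<std::pair<std::string, Param*>>& out) {
    out.push_back({"c0_W", &c0.W}); out.push_back({"c0_b", &c0.b});
    out.push_back({"c1_W", &c1.W}); out.push_back({"c1_b", &c1.b});
    out.push_back({"n1_g", &n1.g}); out.push_back({"n1_beta", &n1.be});
    out.push_back({"c2_W", &c2.W}); out.push_back({"c2_b", &c2.b});
    out.push_back({"n2_g", &n2.g}); out.push_back({"n2_beta", &n2.be});
    out.push_back({"c3_W", &c3.W}); out.push_back({"c3_b", &c3.b});
    out.push_back({"n3_g", &n3.g}); out.push_back({"n3_beta", &n3.be});
    out.push_back({"c4_W", &c4.W}); out.push_back({"c4_b", &c4.b});
  }
};

template <class Net>
static void zero_grads(Net& net) {
  std::vector<std::pair<std::string, Param*>> ps;
  net.params(ps);
  for (auto& pr : ps) pr.second->g.zeros();
}

template <class Net>
static void step_all(Net& net, float lr, float b1, float b2, int t) {
  std::vector<std::pair<std::string, Param*>> ps;
  net.params(ps);
  for (auto& pr : ps) adam_step(*pr.second, lr, b1, b2, t);
}

template <class Net>
static List dump_weights(Net& net) {
  std::vector<std::pair<std::string, Param*>> ps;
  net.params(ps);
  List out(ps.size());
  CharacterVector nm(ps.size());
  for (size_t i = 0; i < ps.size(); ++i) {
    nm[i] = ps[i].first;
    out[i] = wrap(arma::conv_to<arma::mat>::from(ps[i].second->W));
  }
  out.attr("names") = nm;
  return out;
}

template <class Net>
static void load_weights(Net& net, const List& w) {
  std::vector<std::pair<std::string, Param*>> ps;
  net.params(ps);
  if ((size_t)w.size() != ps.size())
    stop("weight list has %d entries, expected %d", (int)w.size(), (int)ps.size());
  for (size_t i = 0; i < ps.size(); ++i) {
    arma::mat M = as<arma::mat>(w[i]);
    if (M.n_rows != ps[i].second->W.n_rows || M.n_cols != ps[i].second->W.n_cols)
      stop("weight '%s' has wrong shape", ps[i].first.c_str());
    ps[i].second->W = arma::conv_to<fmat>::from(M);
  }
}

// columns of `slices` are flattened (S x S) axial slices.
static Tensor make_batch(const arma::mat& slices, const arma::ivec& idx, int S) {
  Tensor X;
  X.H = S; X.W = S; X.C = 1; X.B = idx.n_elem;
  X.m.set_size(1, (size_t)S * S * idx.n_elem);
  for (arma::uword b = 0; b < idx.n_elem; ++b) {
    const double* src = slices.colptr(idx[b] - 1);
    float* dst = X.m.memptr() + (size_t)b * S * S;
    for (int t = 0; t < S * S; ++t) dst[t] = (float)src[t];
  }
  return X;
}

// [[Rcpp::export]]
List gan_train_cpp(const arma::mat& fdg, const arma::mat& amy,
                   const arma::imat& batch_idx, int S, int nb_per_epoch, int F,
                   double lr, double beta1, double beta2, double lambda_l1,
                   int seed) {
  std::mt19937 rng_g((unsigned)seed), rng_d((unsigned)seed + 1),
      rng_drop((unsigned)seed + 2);
  Gen gen(S, F, rng_g);
  Disc disc(F, rng_d);
  const int n_iter = batch_idx.n_cols;
  const int epochs = n_iter / nb_per_epoch;
  arma::mat loss(epochs, 3, arma::fill::zeros);
  const float flr = (float)lr, b1 = (float)beta1, b2 = (float)beta2;
  const float lam = (float)lambda_l1;

  for (int it = 0; it < n_iter; ++it) {
    arma::ivec idx = batch_idx.col(it);
    Tensor X = make_batch(fdg, idx, S);
    Tensor Yr = make_batch(amy, idx, S);
    Tensor fake = gen.forward(X, true, rng_drop);
    if (!fake.m.is_finite()) stop("non-finite generator output at iteration %d", it + 1);

    // discriminator: 0.5*mean((D(real)-1)^2) + 0.5*mean(D(fake)^2)
    zero_grads(disc);
    Tensor realPair = concat_c(X, Yr);
    Tensor Pr = disc.forward(realPair);
    const float Np = (float)Pr.m.n_elem;
    const double l_dr = 0.5 * arma::mean(arma::mean(arma::square(Pr.m - 1.f)));
    Tensor dPr = Pr; dPr.m = (Pr.m - 1.f) / Np;
    disc.backward(dPr);
    Tensor fakePair = concat_c(X, fake);  // detached: no grad flows to G here
    Tensor Pf = disc.forward(fakePair);
    const double l_df = 0.5 * arma::mean(arma::mean(arma::square(Pf.m)));
    Tensor dPf = Pf; dPf.m = Pf.m / Np;
    disc.backward(dPf);
    step_all(disc, flr, b1, b2, it + 1);

    // generator: mean((D(fake)-1)^2) + lambda * mean|fake - real|
    zero_grads(disc);
    Tensor Pf2 = disc.forward(fakePair);
    const double l_ga = arma::mean(arma::mean(arma::square(Pf2.m - 1.f)));
    Tensor dP = Pf2; dP.m = 2.f * (Pf2.m - 1.f) / Np;
    Tensor dPair = disc.backward(dP);
    Tensor dFake = dPair;
    dFake.m = dPair.m.row(1);  // amyloid channel
    dFake.C = 1;
    const float Nx = (float)fake.m.n_elem;
    const double l_l1 = arma::mean(arma::mean(arma::abs(fake.m - Yr.m)));
    dFake.m += lam * arma::sign(fake.m - Yr.m) / Nx;
    zero_grads(gen);
    gen.backward(dFake);
    step_all(gen, flr, b1, b2, it + 1);

    const int ep = it / nb_per_epoch;
    loss(ep, 0) += (l_dr + l_df) / nb_per_epoch;
    loss(ep, 1) += l_ga / nb_per_epoch;
    loss(ep, 2) += l_l1 / nb_per_epoch;
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["gen"] = dump_weights(gen),
                      _["disc"] = dump_weights(disc),
                      _["loss"] = wrap(loss));
}

// [[Rcpp::export]]
List gan_init_cpp(int S, int F, int seed, std::string type) {
  std::mt19937 rng_g((unsigned)seed), rng_d((unsigned)seed + 1);
  if (type == "gen") {
    Gen gen(S, F, rng_g);
    return dump_weights(gen);
  }
  Disc disc(F, rng_d);
  return dump_weights(disc);
}

// [[Rcpp::export]]
arma::mat gan_generator_forward_cpp(const List& weights, const arma::mat& x,
                                    int S, int F) {
  std::mt19937 rng(0);
  Gen gen(S, F, rng);
  load_weights(gen, weights);
  const int N = x.n_cols;
  arma::mat out(x.n_rows, N);
  const int chunk = 16;
  for (int start = 0; start < N; start += chunk) {
    const int nb = std::min(chunk, N - start);
    arma::ivec idx(nb);
    for (int i = 0; i < nb; ++i) idx[i] = start + i + 1;
    Tensor X = make_batch(x, idx, S);
    Tensor Y = gen.forward(X, false, rng);
    for (int i = 0; i < nb; ++i) {
      const float* src = Y.m.memptr() + (size_t)i * S * S;
      double* dst = out.colptr(start + i);
      for (int t = 0; t < S * S; ++t) dst[t] = (double)src[t];
    }
  }
  return out;
}

// [[Rcpp::export]]
List gan_disc_forward_cpp(const List& weights, const arma::mat& x,
                          const arma::mat& y, int S, int F) {
  std::mt19937 rng(0);
  Disc disc(F, rng);
  load_weights(disc, weights);
  const int N = x.n_cols;
  arma::ivec idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i + 1;
  Tensor X = make_batch(x, idx, S), Y = make_batch(y, idx, S);
  Tensor P = disc.forward(concat_c(X, Y));
  arma::mat scores(P.H * P.W, N);
  for (int i = 0; i < N; ++i) {
    const float* src = P.m.memptr() + (size_t)i * P.H * P.W;
    for (int t = 0; t < P.H * P.W; ++t) scores(t, i) = (double)src[t];
  }
  return List::create(_["scores"] = scores, _["hp"] = P.H, _["wp"] = P.W);
}
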