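// Recurrent sequence-labeling network for sharp-wave ripple detection.
//
// Layer stack (dimensions inferred from the parameter shapes):
//   gaussian noise (train only) -> conv1d -> dropout -> conv1d -> batchnorm ->
//   relu -> dropout -> (bi)LSTM -> batchnorm -> dropout -> (bi)LSTM ->
//   dropout -> batchnorm -> dropout -> time-distributed dense + sigmoid
//
// Activations are stored time-major as (batch*T x channels) matrices, row
// index b + t*batch, so convolution taps, input projections, batch-norm and
// all elementwise ops are single large BLAS calls; only the recurrent
// h * Wh product runs per time step.  Training implements full BPTT with
// Adam; all randomness (shuffling, input noise, dropout) comes from a
// private xorshift/Box-Muller generator seeded from R, so runs are
// reproducible on a fixed device independent of the C++ standard library.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static const double BN_EPS = 1e-3;
static const double CLIP = 1e-7;  // probability clipping in the loss

// ---------------------------------------------------------------------------
// deterministic RNG (xorshift64* + Box-Muller), independent of libstdc++
// ---------------------------------------------------------------------------
struct RNG {
  uint64_t s;
  explicit RNG(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  void shuffle(std::vector<uword>& v) {  // Fisher-Yates
    for (uword i = v.size(); i > 1; --i) {
      uword j = (uword)(unif() * i);
      if (j >= i) j = i - 1;
      std::swap(v[i - 1], v[j]);
    }
  }
};

// ---------------------------------------------------------------------------
// parameter container
// ---------------------------------------------------------------------------
struct LSTMW { mat Wx, Wh; vec b; };
struct BNW   { vec gamma, beta, rmean, rvar; };

struct Net {
  cube W1; vec b1;        // conv1: (k, cin, cout)
  cube W2; vec b2;        // conv2
  BNW bn1;                // after conv2
  bool bidir;
  LSTMW l1f, l1b;         // lstm layer 1 (fwd / optional bwd)
  BNW bn2;
  LSTMW l2f, l2b;         // lstm layer 2
  BNW bn3;
  vec Wd; double bd;      // time-distributed dense -> 1 unit
};

static BNW bn_from(const List& p, const std::string& nm) {
  BNW b;
  b.gamma = Rcpp::as<vec>(p[nm + "_gamma"]); b.beta = Rcpp::as<vec>(p[nm + "_beta"]);
  b.rmean = Rcpp::as<vec>(p[nm + "_mean"]);  b.rvar = Rcpp::as<vec>(p[nm + "_var"]);
  return b;
}
static LSTMW lstm_from(const List& p, const std::string& nm) {
  LSTMW l;
  l.Wx = Rcpp::as<mat>(p[nm + "_Wx"]); l.Wh = Rcpp::as<mat>(p[nm + "_Wh"]);
  l.b = Rcpp::as<vec>(p[nm + "_b"]);
  return l;
}

static Net net_from(const List& p) {
  Net n;
  n.W1 = Rcpp::as<cube>(p["conv1_W"]); n.b1 = Rcpp::as<vec>(p["conv1_b"]);
  n.W2 = Rcpp::as<cube>(p["conv2_W"]); n.b2 = Rcpp::as<vec>(p["conv2_b"]);
  n.bn1 = bn_from(p, "bn1");
  n.bidir = p.containsElementNamed("lstm1_bwd_Wx");
  n.l1f = lstm_from(p, "lstm1_fwd");
  if (n.bidir) n.l1b = lstm_from(p, "lstm1_bwd");
  n.bn2 = bn_from(p, "bn2");
  n.l2f = lstm_from(p, "lstm2_fwd");
  if (n.bidir) n.l2b = lstm_from(p, "lstm2_bwd");
  n.bn3 = bn_from(p, "bn3");
  n.Wd = Rcpp::as<vec>(p["dense_W"]); n.bd = Rcpp::as<double>(p["dense_b"]);
  return n;
}

static void bn_to(List& p, const std::string& nm, const BNW& b) {
  p[nm + "_gamma"] = b.gamma; p[nm + "_beta"] = b.beta;
  p[nm + "_mean"] = b.rmean;  p[nm + "_var"] = b.rvar;
}
static void lstm_to(List& p, const std::string& nm, const LSTMW& l) {
  p[nm + "_Wx"] = l.Wx; p[nm + "_Wh"] = l.Wh; p[nm + "_b"] = l.b;
}
static List net_to(const Net& n) {
  List p;
  p["conv1_W"] = n.W1; p["conv1_b"] = n.b1;
  p["conv2_W"] = n.W2; p["conv2_b"] = n.b2;
  bn_to(p, "bn1", n.bn1);
  lstm_to(p, "lstm1_fwd", n.l1f);
  if (n.bidir) lstm_to(p, "lstm1_bwd", n.l1b);
  bn_to(p, "bn2", n.bn2);
  lstm_to(p, "lstm2_fwd", n.l2f);
  if (n.bidir) lstm_to(p, "lstm2_bwd", n.l2b);
  bn_to(p, "bn3", n.bn3);
  p["dense_W"] = n.Wd; p["dense_b"] = n.bd;
  return p;
}

static Net net_zeros_like(const Net& n) {
  Net z = n;
  z.W1.zeros(); z.b1.zeros(); z.W2.zeros(); z.b2.zeros();
  z.bn1.gamma.zeros(); z.bn1.beta.zeros();
  z.l1f.Wx.zeros(); z.l1f.Wh.zeros(); z.l1f.b.zeros();
  if (n.bidir) { z.l1b.Wx.zeros(); z.l1b.Wh.zeros(); z.l1b.b.zeros(); }
  z.bn2.gamma.zeros(); z.bn2.beta.zeros();
  z.l2f.Wx.zeros(); z.l2f.Wh.zeros(); z.l2f.b.zeros();
  if (n.bidir) { z.l2b.Wx.zeros(); z.l2b.Wh.zeros(); z.l2b.b.zeros(); }
  z.bn3.gamma.zeros(); z.bn3.beta.zeros();
  z.Wd.zeros(); z.bd = 0.0;
  return z;
}

// flat list of trainable parameter arrays in a fixed order (the Adam state
// is kept in parallel structures; bn running stats and the dense bias
// scalar are handled separately)
struct Flat { std::vector<double*> ptr; std::vector<uword> len; };
static Flat flatten(Net& n) {
  Flat f;
  auto add = [&](double* p, uword l) { f.ptr.push_back(p); f.len.push_back(l); };
  add(n.W1.memptr(), n.W1.n_elem); add(n.b1.memptr(), n.b1.n_elem);
  add(n.W2.memptr(), n.W2.n_elem); add(n.b2.memptr(), n.b2.n_elem);
  add(n.bn1.gamma.memptr(), n.bn1.gamma.n_elem); add(n.bn1.beta.memptr(), n.bn1.beta.n_elem);
  auto addl = [&](LSTMW& l) {
    add(l.Wx.memptr(), l.Wx.n_elem); add(l.Wh.memptr(), l.Wh.n_elem); add(l.b.memptr(), l.b.n_elem);
  };
  addl(n.l1f); if (n.bidir) addl(n.l1b);
  add(n.bn2.gamma.memptr(), n.bn2.gamma.n_elem); add(n.bn2.beta.memptr(), n.bn2.beta.n_elem);
  addl(n.l2f); if (n.bidir) addl(n.l2b);
  add(n.bn3.gamma.memptr(), n.bn3.gamma.n_elem); add(n.bn3.beta.memptr(), n.bn3.beta.n_elem);
  add(n.Wd.memptr(), n.Wd.n_elem);
  return f;
}

// ---------------------------------------------------------------------------
// layer primitives on (batch*T x channels) time-major activations
// ---------------------------------------------------------------------------

// per-tap (cin x cout) weight views of the (k, cin, cout) kernel cube
static std::vector<mat> conv_taps(const cube& W) {
  const uword k = W.n_rows, cin = W.n_cols, cout_ = W.n_slices;
  std::vector<mat> Wt(k);
  for (uword j = 0; j < k; ++j) {
    mat m(cin, cout_);
    for (uword a = 0; a < cin; ++a)
      for (uword c = 0; c < cout_; ++c) m(a, c) = W(j, a, c);
    Wt[j] = m;
  }
  return Wt;
}

// 'same' 1-D convolution (odd kernel): one submatrix GEMM per tap
static mat conv1d(const mat& x, const cube& W, const vec& b,
                  uword batch, uword T) {
  const uword k = W.n_rows, cout_ = W.n_slices;
  const sword pad = (sword)((k - 1) / 2);
  std::vector<mat> Wt = conv_taps(W);
  mat out(x.n_rows, cout_, fill::zeros);
  for (uword j = 0; j < k; ++j) {
    sword s = (sword)j - pad;                    // input t = output t + s
    sword t0 = std::max<sword>(0, -s), t1 = std::min<sword>(T - 1, T - 1 - s);
    if (t0 > t1) continue;
    out.rows(t0 * batch, (t1 + 1) * batch - 1) +=
      x.rows((t0 + s) * batch, (t1 + s + 1) * batch - 1) * Wt[j];
  }
  out.each_row() += b.t();
  return out;
}

static void conv1d_backward(const mat& x, const cube& W, const mat& dout,
                            uword batch, uword T,
                            mat& dx, cube& dW, vec& db) {
  const uword k = W.n_rows, cin = W.n_cols, cout_ = W.n_slices;
  const sword pad = (sword)((k - 1) / 2);
  std::vector<mat> Wt = conv_taps(W);
  dx.zeros(x.n_rows, cin);
  dW.zeros(k, cin, cout_);
  db = sum(dout, 0).t();
  for (uword j = 0; j < k; ++j) {
    sword s = (sword)j - pad;
    sword t0 = std::max<sword>(0, -s), t1 = std::min<sword>(T - 1, T - 1 - s);
    if (t0 > t1) continue;
    auto orows = dout.rows(t0 * batch, (t1 + 1) * batch - 1);
    auto xrows = x.rows((t0 + s) * batch, (t1 + s + 1) * batch - 1);
    dx.rows((t0 + s) * batch, (t1 + s + 1) * batch - 1) += orows * Wt[j].t();
    mat dWj = xrows.t() * orows;
    for (uword a = 0; a < cin; ++a)
      for (uword c = 0; c < cout_; ++c) dW(j, a, c) = dWj(a, c);
  }
}

struct BNCache { mat xhat; rowvec invstd; };

static mat batchnorm(const mat& x, BNW& bn, bool training, BNCache* cache,
                     double momentum = 0.99) {
  const double N = (double)x.n_rows;
  rowvec m, v;
  if (training) {
    m = mean(x, 0);
    v = sum(square(x.each_row() - m), 0) / N;   // biased batch variance
    bn.rmean = momentum * bn.rmean + (1.0 - momentum) * m.t();
    bn.rvar = momentum * bn.rvar + (1.0 - momentum) * v.t();
  } else {
    m = bn.rmean.t(); v = bn.rvar.t();
  }
  rowvec invstd = 1.0 / sqrt(v + BN_EPS);
  mat xhat = (x.each_row() - m);
  xhat.each_row() %= invstd;
  mat out = xhat;
  out.each_row() %= bn.gamma.t().as_row();
  out.each_row() += bn.beta.t().as_row();
  if (cache) { cache->xhat = std::move(xhat); cache->invstd = invstd; }
  return out;
}

static mat batchnorm_backward(const mat& dout, const BNCache& c, const BNW& bn,
                              vec& dgamma, vec& dbeta) {
  const double N = (double)dout.n_rows;
  dbeta = sum(dout, 0).t();
  dgamma = sum(dout % c.xhat, 0).t();
  mat dxhat = dout;
  dxhat.each_row() %= bn.gamma.t().as_row();
  rowvec s1 = sum(dxhat, 0), s2 = sum(dxhat % c.xhat, 0);
  mat dx = dxhat * N;
  dx.each_row() -= s1;
  dx -= c.xhat.each_row() % s2;
  dx.each_row() %= (c.invstd / N);
  return dx;
}

struct LSTMCache { mat I, F, G, O, C, Ct, H; };

// reverse=false: t = 0..T-1; reverse=true: t = T-1..0 with the output
// stored back at the original index (bidirectional wrapper convention)
static mat lstm_forward(const mat& x, const LSTMW& w, uword batch, uword T,
                        bool reverse, LSTMCache* cache) {
  const uword h = w.Wh.n_rows;
  mat Z0 = x * w.Wx;                          // input projection, one GEMM
  Z0.each_row() += w.b.t().as_row();
  mat hprev(batch, h, fill::zeros), cprev(batch, h, fill::zeros);
  mat H(x.n_rows, h);
  if (cache) {
    cache->I.set_size(x.n_rows, h); cache->F.set_size(x.n_rows, h);
    cache->G.set_size(x.n_rows, h); cache->O.set_size(x.n_rows, h);
    cache->C.set_size(x.n_rows, h); cache->Ct.set_size(x.n_rows, h);
  }
  for (uword step = 0; step < T; ++step) {
    uword t = reverse ? (T - 1 - step) : step;
    uword r0 = t * batch, r1 = r0 + batch - 1;
    mat z = Z0.rows(r0, r1) + hprev * w.Wh;
    mat i = 1.0 / (1.0 + exp(-z.cols(0, h - 1)));
    mat f = 1.0 / (1.0 + exp(-z.cols(h, 2 * h - 1)));
    mat g = tanh(z.cols(2 * h, 3 * h - 1));
    mat o = 1.0 / (1.0 + exp(-z.cols(3 * h, 4 * h - 1)));
    mat cnew = f % cprev + i % g;
    mat ct = tanh(cnew);
    hprev = o % ct;
    cprev = cnew;
    H.rows(r0, r1) = hprev;
    if (cache) {
      cache->I.rows(r0, r1) = i; cache->F.rows(r0, r1) = f;
      cache->G.rows(r0, r1) = g; cache->O.rows(r0, r1) = o;
      cache->C.rows(r0, r1) = cnew; cache->Ct.rows(r0, r1) = ct;
    }
  }
  if (cache) cache->H = H;
  return H;
}

static mat lstm_backward(const mat& x, const LSTMW& w, const LSTMCache& c,
                         const mat& dH, uword batch, uword T, bool reverse,
                         mat& dWx, mat& dWh, vec& db) {
  const uword h = w.Wh.n_rows;
  dWh.zeros(h, 4 * h);
  mat dZ(x.n_rows, 4 * h);
  mat dh_next(batch, h, fill::zeros), dc_next(batch, h, fill::zeros);
  for (uword step = 0; step < T; ++step) {
    uword t = reverse ? step : (T - 1 - step);   // opposite of forward order
    uword r0 = t * batch, r1 = r0 + batch - 1;
    mat dh = dH.rows(r0, r1) + dh_next;
    mat i = c.I.rows(r0, r1), f = c.F.rows(r0, r1), g = c.G.rows(r0, r1),
        o = c.O.rows(r0, r1), ct = c.Ct.rows(r0, r1);
    mat dc = dc_next + dh % o % (1.0 - square(ct));
    bool has_prev = (step + 1 < T);
    uword tprev = reverse ? (t + 1) : (t - 1);
    mat cprev(batch, h, fill::zeros), hprev(batch, h, fill::zeros);
    if (has_prev) {
      cprev = c.C.rows(tprev * batch, tprev * batch + batch - 1);
      hprev = c.H.rows(tprev * batch, tprev * batch + batch - 1);
    }
    mat dz(batch, 4 * h);
    dz.cols(0, h - 1) = (dc % g) % i % (1.0 - i);
    dz.cols(h, 2 * h - 1) = (dc % cprev) % f % (1.0 - f);
    dz.cols(2 * h, 3 * h - 1) = (dc % i) % (1.0 - square(g));
    dz.cols(3 * h, 4 * h - 1) = (dh % ct) % o % (1.0 - o);
    dZ.rows(r0, r1) = dz;
    dWh += hprev.t() * dz;
    dh_next = dz * w.Wh.t();
    dc_next = dc % f;
  }
  dWx = x.t() * dZ;
  db = sum(dZ, 0).t();
  return dZ * w.Wx.t();                        // dx
}

static mat dropout_mask(RNG& rng, uword nr, uword nc, double rate) {
  mat m(nr, nc);
  double scale = 1.0 / (1.0 - rate);
  double* p = m.memptr();
  for (uword e = 0; e < nr * nc; ++e)
    p[e] = (rng.unif() >= rate) ? scale : 0.0;
  return m;
}

// ---------------------------------------------------------------------------
// full forward pass; caches retained only for backprop
// ---------------------------------------------------------------------------
struct FwdCache {
  mat x0, a1, m1, a1d, a2;
  BNCache bc1; mat relu_in, m2, r1d;
  LSTMCache lc1f, lc1b; mat h1;
  BNCache bc2; mat m3, h1d;
  LSTMCache lc2f, lc2b; mat h2;
  mat m4, h2d;
  BNCache bc3; mat m5, h2dd;
  mat yhat;                                    // (batch x T)
};

static mat forward(Net& net, const mat& X, bool training, RNG* rng,
                   double noise_sd, double dropout, FwdCache* cc,
                   double bn_momentum = 0.99) {
  const uword batch = X.n_rows, T = X.n_cols;
  // (batch x T) is memory-identical to the time-major (batch*T x 1) layout
  mat x0(const_cast<double*>(X.memptr()), batch * T, 1);
  if (training && noise_sd > 0.0) {
    double* p = x0.memptr();
    for (uword e = 0; e < x0.n_rows; ++e) p[e] += noise_sd * rng->norm();
  }
  const bool drop = training && dropout > 0.0;

  mat a1 = conv1d(x0, net.W1, net.b1, batch, T);
  mat m1, a1d;
  if (drop) { m1 = dropout_mask(*rng, a1.n_rows, a1.n_cols, dropout); a1d = a1 % m1; }
  else a1d = a1;
  mat a2 = conv1d(a1d, net.W2, net.b2, batch, T);
  BNCache bc1;
  mat relu_in = batchnorm(a2, net.bn1, training, cc ? &bc1 : nullptr,
                          bn_momentum);
  mat r1 = relu_in;
  r1.transform([](double v) { return v > 0.0 ? v : 0.0; });
  mat m2, r1d;
  if (drop) { m2 = dropout_mask(*rng, r1.n_rows, r1.n_cols, dropout); r1d = r1 % m2; }
  else r1d = r1;

  LSTMCache lc1f, lc1b;
  mat h1 = lstm_forward(r1d, net.l1f, batch, T, false, cc ? &lc1f : nullptr);
  if (net.bidir)
    h1 = join_rows(h1, lstm_forward(r1d, net.l1b, batch, T, true,
                                    cc ? &lc1b : nullptr));
  BNCache bc2;
  mat h1bn = batchnorm(h1, net.bn2, training, cc ? &bc2 : nullptr,
                       bn_momentum);
  mat m3, h1d;
  if (drop) { m3 = dropout_mask(*rng, h1bn.n_rows, h1bn.n_cols, dropout); h1d = h1bn % m3; }
  else h1d = h1bn;

  LSTMCache lc2f, lc2b;
  mat h2 = lstm_forward(h1d, net.l2f, batch, T, false, cc ? &lc2f : nullptr);
  if (net.bidir)
    h2 = join_rows(h2, lstm_forward(h1d, net.l2b, batch, T, true,
                                    cc ? &lc2b : nullptr));
  mat m4, h2d;
  if (drop) { m4 = dropout_mask(*rng, h2.n_rows, h2.n_cols, dropout); h2d = h2 % m4; }
  else h2d = h2;
  BNCache bc3;
  mat h2bn = batchnorm(h2d, net.bn3, training, cc ? &bc3 : nullptr,
                       bn_momentum);
  mat m5, h2dd;
  if (drop) { m5 = dropout_mask(*rng, h2bn.n_rows, h2bn.n_cols, dropout); h2dd = h2bn % m5; }
  else h2dd = h2bn;

  vec z = h2dd * net.Wd + net.bd;
  z = 1.0 / (1.0 + exp(-z));
  mat yhat(z.memptr(), batch, T);              // same memory order

  if (cc) {
    cc->x0 = x0; cc->a1 = std::move(a1); cc->m1 = std::move(m1);
    cc->a1d = std::move(a1d); cc->a2 = std::move(a2); cc->bc1 = std::move(bc1);
    cc->relu_in = std::move(relu_in); cc->m2 = std::move(m2);
    cc->r1d = std::move(r1d); cc->lc1f = std::move(lc1f);
    cc->lc1b = std::move(lc1b); cc->h1 = std::move(h1);
    cc->bc2 = std::move(bc2); cc->m3 = std::move(m3); cc->h1d = std::move(h1d);
    cc->lc2f = std::move(lc2f); cc->lc2b = std::move(lc2b);
    cc->h2 = std::move(h2); cc->m4 = std::move(m4); cc->h2d = std::move(h2d);
    cc->bc3 = std::move(bc3); cc->m5 = std::move(m5);
    cc->h2dd = std::move(h2dd); cc->yhat = yhat;
  }
  return yhat;
}

static double bce(const mat& y, const mat& yhat) {
  mat p = clamp(yhat, CLIP, 1.0 - CLIP);
  return -accu(y % log(p) + (1.0 - y) % log(1.0 - p)) / (double)y.n_elem;
}

// backward pass: gradient of the mean BCE wrt all trainable parameters
static void backward(Net& net, const FwdCache& c, const mat& y, Net& g) {
  const uword batch = y.n_rows, T = y.n_cols;
  const double N = (double)(batch * T);
  const bool drop = (c.m1.n_elem > 0);

  // dense + sigmoid: d(pre-activation) = (yhat - y) / N
  vec dz = vectorise(c.yhat - y) / N;
  g.Wd = c.h2dd.t() * dz;
  g.bd = accu(dz);
  mat dh2dd = dz * net.Wd.t();

  if (drop) dh2dd %= c.m5;
  mat dh2d = batchnorm_backward(dh2dd, c.bc3, net.bn3, g.bn3.gamma, g.bn3.beta);
  if (drop) dh2d %= c.m4;

  mat dh1d;
  {
    uword hf = net.l2f.Wh.n_rows;
    dh1d = lstm_backward(c.h1d, net.l2f, c.lc2f, dh2d.cols(0, hf - 1),
                         batch, T, false, g.l2f.Wx, g.l2f.Wh, g.l2f.b);
    if (net.bidir)
      dh1d += lstm_backward(c.h1d, net.l2b, c.lc2b,
                            dh2d.cols(hf, dh2d.n_cols - 1),
                            batch, T, true, g.l2b.Wx, g.l2b.Wh, g.l2b.b);
  }
  if (drop) dh1d %= c.m3;
  mat dh1 = batchnorm_backward(dh1d, c.bc2, net.bn2, g.bn2.gamma, g.bn2.beta);

  mat dr1d;
  {
    uword hf = net.l1f.Wh.n_rows;
    dr1d = lstm_backward(c.r1d, net.l1f, c.lc1f, dh1.cols(0, hf - 1),
                         batch, T, false, g.l1f.Wx, g.l1f.Wh, g.l1f.b);
    if (net.bidir)
      dr1d += lstm_backward(c.r1d, net.l1b, c.lc1b,
                            dh1.cols(hf, dh1.n_cols - 1),
                            batch, T, true, g.l1b.Wx, g.l1b.Wh, g.l1b.b);
  }
  if (drop) dr1d %= c.m2;
  dr1d %= conv_to<mat>::from(c.relu_in > 0.0);  // relu gate
  mat da2 = batchnorm_backward(dr1d, c.bc1, net.bn1, g.bn1.gamma, g.bn1.beta);

  mat da1d;
  conv1d_backward(c.a1d, net.W2, da2, batch, T, da1d, g.W2, g.b2);
  if (drop) da1d %= c.m1;
  mat dx0;
  conv1d_backward(c.x0, net.W1, da1d, batch, T, dx0, g.W1, g.b1);
}

// ---------------------------------------------------------------------------
// exported functions
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".net_forward")]]
arma::mat net_forward_cpp(List params, arma::mat X, int batch_size = 128) {
  Net net = net_from(params);
  const uword n = X.n_rows, T = X.n_cols;
  mat out(n, T);
  for (uword i0 = 0; i0 < n; i0 += (uword)batch_size) {
    uword i1 = std::min(n, i0 + (uword)batch_size) - 1;
    mat Xb = X.rows(i0, i1);
    out.rows(i0, i1) = forward(net, Xb, false, nullptr, 0.0, 0.0, nullptr);
  }
  return out;
}

// Gradients of the mean BCE in training mode (batch statistics for the
// batch-norm layers, no noise/dropout); used by the finite-difference
// correctness tests.
// [[Rcpp::export(name = ".net_gradients")]]
List net_gradients_cpp(List params, arma::mat X, arma::mat y) {
  Net net = net_from(params);
  Net g = net_zeros_like(net);
  FwdCache cc;
  forward(net, X, true, nullptr, 0.0, 0.0, &cc);
  backward(net, cc, y, g);
  List out = net_to(g);
  out["loss"] = bce(y, cc.yhat);
  return out;
}

// [[Rcpp::export(name = ".net_loss")]]
double net_loss_cpp(List params, arma::mat X, arma::mat y) {
  Net net = net_from(params);
  FwdCache cc;
  forward(net, X, true, nullptr, 0.0, 0.0, &cc);
  return bce(y, cc.yhat);
}

// [[Rcpp::export(name = ".net_train")]]
List net_train_cpp(List params, arma::mat X, arma::mat y,
                   arma::mat Xval, arma::mat yval,
                   double lr, double beta1, double beta2, double eps,
                   int batch_size, int epochs,
                   double noise_sd, double dropout, int seed,
                   double bn_momentum = 0.99) {
  Net net = net_from(params);
  Net m = net_zeros_like(net), v = net_zeros_like(net);
  Flat fp = flatten(net), fm = flatten(m), fv = flatten(v);
  double m_bd = 0.0, v_bd = 0.0;
  RNG rng((uint64_t)seed * 2654435761ULL + 1ULL);

  const uword n = X.n_rows;
  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;

  vec hist_loss(epochs), hist_mse(epochs), hist_vloss(epochs), hist_vmse(epochs);
  long long step = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    rng.shuffle(idx);
    double ep_loss = 0.0, ep_mse = 0.0, ep_n = 0.0;
    for (uword i0 = 0; i0 < n; i0 += (uword)batch_size) {
      uword i1 = std::min(n, i0 + (uword)batch_size) - 1;
      uvec sel(i1 - i0 + 1);
      for (uword j = 0; j <= i1 - i0; ++j) sel[j] = idx[i0 + j];
      mat Xb = X.rows(sel), yb = y.rows(sel);
      FwdCache cc;
      forward(net, Xb, true, &rng, noise_sd, dropout, &cc, bn_momentum);
      Net g = net_zeros_like(net);
      backward(net, cc, yb, g);
      Flat fg = flatten(g);
      ++step;
      double bc1 = 1.0 - std::pow(beta1, (double)step);
      double bc2 = 1.0 - std::pow(beta2, (double)step);
      for (size_t pi = 0; pi < fp.ptr.size(); ++pi) {
        double *p = fp.ptr[pi], *gm = fm.ptr[pi], *gv = fv.ptr[pi], *gr = fg.ptr[pi];
        for (uword e = 0; e < fp.len[pi]; ++e) {
          gm[e] = beta1 * gm[e] + (1.0 - beta1) * gr[e];
          gv[e] = beta2 * gv[e] + (1.0 - beta2) * gr[e] * gr[e];
          p[e] -= lr * (gm[e] / bc1) / (std::sqrt(gv[e] / bc2) + eps);
        }
      }
      m_bd = beta1 * m_bd + (1.0 - beta1) * g.bd;
      v_bd = beta2 * v_bd + (1.0 - beta2) * g.bd * g.bd;
      net.bd -= lr * (m_bd / bc1) / (std::sqrt(v_bd / bc2) + eps);

      double w = (double)Xb.n_rows;
      ep_loss += w * bce(yb, cc.yhat);
      ep_mse += w * accu(square(yb - cc.yhat)) / (double)yb.n_elem;
      ep_n += w;
    }
    hist_loss[ep] = ep_loss / ep_n;
    hist_mse[ep] = ep_mse / ep_n;
    double vl = 0.0, vm = 0.0, vn = 0.0;   // validation in inference mode
    for (uword i0 = 0; i0 < Xval.n_rows; i0 += (uword)batch_size) {
      uword i1 = std::min((uword)Xval.n_rows, i0 + (uword)batch_size) - 1;
      mat Xb = Xval.rows(i0, i1), yb = yval.rows(i0, i1);
      mat yh = forward(net, Xb, false, nullptr, 0.0, 0.0, nullptr);
      double w = (double)Xb.n_rows;
      vl += w * bce(yb, yh);
      vm += w * accu(square(yb - yh)) / (double)yb.n_elem;
      vn += w;
    }
    hist_vloss[ep] = vn > 0 ? vl / vn : datum::nan;
    hist_vmse[ep] = vn > 0 ? vm / vn : datum::nan;
    Rcpp::checkUserInterrupt();
  }

  return List::create(
    Named("params") = net_to(net),
    Named("loss") = hist_loss, Named("mse") = hist_mse,
    Named("val_loss") = hist_vloss, Named("val_mse") = hist_vmse);
}
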