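// Dense tile-wise Vision Transformer: forward, backward and AdamW steps.
//
// Tokens are the pixels of a 20x16 tile (320 tokens), the embedding is the
// raw 184-band spectrum (no patch projection). Pre-norm blocks:
//   x += Wo * MHSA(LN1(x));  x += W2 * gelu(W1 * LN2(x))
// followed by a per-token linear head. Single precision is the training
// and inference path; a double instantiation backs the finite-difference
// gradient check in the test suite.
//
// Parameter list order (fixed, shared with the R side):
//   [optional pos (N x D)]
//   per block: ln1_g, ln1_b, Wqkv (D x 3D), bqkv, Wo (D x D), bo,
//              ln2_g, ln2_b, W1 (D x Hid), b1, W2 (Hid x D), b2
//   head: Wh (D x C), bh
// Vectors are stored as 1 x n row matrices.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <functional>
#include <cstdint>
using namespace Rcpp;

static const double LN_EPS = 1e-5;

template <typename T>
struct Params {
  std::vector<arma::Mat<T>> P;
  int n_blocks, D, heads, hid, C, N;
  bool has_pos;
  int block_off(int b) const { return (has_pos ? 1 : 0) + 12 * b; }
  int head_off() const { return (has_pos ? 1 : 0) + 12 * n_blocks; }
};

template <typename T>
Params<T> unpack(const List& plist, int n_tokens, int n_heads, bool has_pos) {
  Params<T> pp;
  pp.P.reserve(plist.size());
  for (int i = 0; i < plist.size(); ++i) {
    NumericMatrix m = plist[i];
    arma::Mat<T> a(m.nrow(), m.ncol());
    for (int j = 0; j < m.nrow() * m.ncol(); ++j) a[j] = (T)m[j];
    pp.P.push_back(std::move(a));
  }
  pp.has_pos = has_pos;
  pp.N = n_tokens;
  pp.heads = n_heads;
  int nb = (plist.size() - (has_pos ? 1 : 0) - 2) / 12;
  pp.n_blocks = nb;
  const arma::Mat<T>& Wh = pp.P[pp.head_off()];
  pp.D = Wh.n_rows;
  pp.C = Wh.n_cols;
  pp.hid = pp.P[pp.block_off(0) + 8].n_cols;
  return pp;
}

template <typename T>
List pack(const std::vector<arma::Mat<T>>& P) {
  List out(P.size());
  for (size_t i = 0; i < P.size(); ++i) {
    NumericMatrix m(P[i].n_rows, P[i].n_cols);
    for (arma::uword j = 0; j < P[i].n_elem; ++j) m[j] = (double)P[i][j];
    out[i] = m;
  }
  return out;
}

// ---- primitives ------------------------------------------------------

template <typename T>
void layernorm(const arma::Mat<T>& x, const arma::Mat<T>& g,
               const arma::Mat<T>& b, arma::Mat<T>& y,
               arma::Col<T>& inv_std, arma::Mat<T>& xhat) {
  arma::Col<T> mu = arma::mean(x, 1);
  arma::Col<T> va = arma::var(x, 1 /* population */, 1);
  inv_std = 1.0 / arma::sqrt(va + (T)LN_EPS);
  xhat = x;
  xhat.each_col() -= mu;
  xhat.each_col() %= inv_std;
  y = xhat;
  y.each_row() %= g.row(0);
  y.each_row() += b.row(0);
}

template <typename T>
void layernorm_backward(const arma::Mat<T>& dy, const arma::Mat<T>& g,
                        const arma::Mat<T>& xhat, const arma::Col<T>& inv_std,
                        arma::Mat<T>& dx, arma::Mat<T>& dg, arma::Mat<T>& db) {
  dg += arma::sum(dy % xhat, 0);
  db += arma::sum(dy, 0);
  arma::Mat<T> dxh = dy;
  dxh.each_row() %= g.row(0);
  arma::Col<T> m1 = arma::mean(dxh, 1);
  arma::Col<T> m2 = arma::mean(dxh % xhat, 1);
  dx = dxh;
  dx.each_col() -= m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() %= inv_std;
}

template <typename T>
arma::Mat<T> gelu(const arma::Mat<T>& x) {
  return 0.5 * x % (1.0 + arma::erf(x / (T)std::sqrt(2.0)));
}

template <typename T>
arma::Mat<T> gelu_grad(const arma::Mat<T>& x) {
  arma::Mat<T> cdf = 0.5 * (1.0 + arma::erf(x / (T)std::sqrt(2.0)));
  arma::Mat<T> pdf = arma::exp(-0.5 * arma::square(x)) / (T)std::sqrt(2.0 * M_PI);
  return cdf + x % pdf;
}

template <typename T>
void softmax_rows(arma::Mat<T>& s) {
  s.each_col() -= arma::max(s, 1);
  s = arma::exp(s);
  s.each_col() /= arma::sum(s, 1);
}

// ---- forward with caches --------------------------------------------

template <typename T>
struct BlockCache {
  arma::Mat<T> x_in, xhat1, h1, QKV, O, x_mid, xhat2, h2, M1, A1;
  arma::Col<T> istd1, istd2;
  arma::Cube<T> A;  // attention weights per head, N x N x heads
};

// one tile; caches filled only when cache != nullptr
template <typename T>
arma::Mat<T> forward_tile(const Params<T>& pp, arma::Mat<T> x,
                          std::vector<BlockCache<T>>* cache) {
  const int dh = pp.D / pp.heads;
  const T scale = (T)(1.0 / std::sqrt((double)dh));
  if (pp.has_pos) x += pp.P[0];
  for (int b = 0; b < pp.n_blocks; ++b) {
    const int o = pp.block_off(b);
    BlockCache<T>* cc = cache ? &((*cache)[b]) : nullptr;
    if (cc) cc->x_in = x;
    arma::Mat<T> h1, xhat1; arma::Col<T> istd1;
    layernorm(x, pp.P[o], pp.P[o + 1], h1, istd1, xhat1);
    arma::Mat<T> QKV = h1 * pp.P[o + 2];
    QKV.each_row() += pp.P[o + 3].row(0);
    arma::Mat<T> O(pp.N, pp.D);
    arma::Cube<T> Acube;
    if (cc) Acube.set_size(pp.N, pp.N, pp.heads);
    for (int h = 0; h < pp.heads; ++h) {
      arma::Mat<T> Q = QKV.cols(h * dh, (h + 1) * dh - 1);
      arma::Mat<T> K = QKV.cols(pp.D + h * dh, pp.D + (h + 1) * dh - 1);
      arma::Mat<T> V = QKV.cols(2 * pp.D + h * dh, 2 * pp.D + (h + 1) * dh - 1);
      arma::Mat<T> S = (Q * K.t()) * scale;
      softmax_rows(S);
      O.cols(h * dh, (h + 1) * dh - 1) = S * V;
      if (cc) Acube.slice(h) = S;
    }
    arma::Mat<T> attn = O * pp.P[o + 4];
    attn.each_row() += pp.P[o + 5].row(0);
    arma::Mat<T> x_mid = x + attn;
    arma::Mat<T> h2, xhat2; arma::Col<T> istd2;
    layernorm(x_mid, pp.P[o + 6], pp.P[o + 7], h2, istd2, xhat2);
    arma::Mat<T> M1 = h2 * pp.P[o + 8];
    M1.each_row() += pp.P[o + 9].row(0);
    arma::Mat<T> A1 = gelu(M1);
    arma::Mat<T> M2 = A1 * pp.P[o + 10];
    M2.each_row() += pp.P[o + 11].row(0);
    x = x_mid + M2;
    if (cc) {
      cc->xhat1 = std::move(xhat1); cc->h1 = std::move(h1);
      cc->istd1 = std::move(istd1); cc->QKV = std::move(QKV);
      cc->O = std::move(O); cc->x_mid = std::move(x_mid);
      cc->xhat2 = std::move(xhat2); cc->h2 = std::move(h2);
      cc->istd2 = std::move(istd2); cc->M1 = std::move(M1);
      cc->A1 = std::move(A1); cc->A = std::move(Acube);
    }
  }
  const int ho = pp.head_off();
  arma::Mat<T> logits = x * pp.P[ho];
  logits.each_row() += pp.P[ho + 1].row(0);
  if (cache) {
    cache->resize(pp.n_blocks + 1);
    (*cache)[pp.n_blocks].x_in = x;  // head input
  }
  return logits;
}

// backward for one tile; grads accumulated into G (same layout as P)
template <typename T>
void backward_tile(const Params<T>& pp, const std::vector<BlockCache<T>>& cache,
                   const arma::Mat<T>& dlogits, std::vector<arma::Mat<T>>& G,
                   arma::Mat<T>* dpos) {
  const int dh = pp.D / pp.heads;
  const T scale = (T)(1.0 / std::sqrt((double)dh));
  const int ho = pp.head_off();
  const arma::Mat<T>& xout = cache[pp.n_blocks].x_in;
  G[ho] += xout.t() * dlogits;
  G[ho + 1] += arma::sum(dlogits, 0);
  arma::Mat<T> dx = dlogits * pp.P[ho].t();
  for (int b = pp.n_blocks - 1; b >= 0; --b) {
    const int o = pp.block_off(b);
    const BlockCache<T>& cc = cache[b];
    // MLP branch
    arma::Mat<T> dM2 = dx;  // residual: dx flows to both x_mid and M2
    G[o + 11] += arma::sum(dM2, 0);
    G[o + 10] += cc.A1.t() * dM2;
    arma::Mat<T> dA1 = dM2 * pp.P[o + 10].t();
    arma::Mat<T> dM1 = dA1 % gelu_grad(cc.M1);
    G[o + 9] += arma::sum(dM1, 0);
    G[o + 8] += cc.h2.t() * dM1;
    arma::Mat<T> dh2 = dM1 * pp.P[o + 8].t();
    arma::Mat<T> dx_mid;
    layernorm_backward(dh2, pp.P[o + 6], cc.xhat2, cc.istd2,
                       dx_mid, G[o + 6], G[o + 7]);
    dx_mid += dx;
    // attention branch
    arma::Mat<T> dattn = dx_mid;
    G[o + 5] += arma::sum(dattn, 0);
    G[o + 4] += cc.O.t() * dattn;
    arma::Mat<T> dO = dattn * pp.P[o + 4].t();
    arma::Mat<T> dQKV(pp.N, 3 * pp.D);
    for (int h = 0; h < pp.heads; ++h) {
      arma::Mat<T> Q = cc.QKV.cols(h * dh, (h + 1) * dh - 1);
      arma::Mat<T> K = cc.QKV.cols(pp.D + h * dh, pp.D + (h + 1) * dh - 1);
      arma::Mat<T> V = cc.QKV.cols(2 * pp.D + h * dh, 2 * pp.D + (h + 1) * dh - 1);
      const arma::Mat<T>& A = cc.A.slice(h);
      arma::Mat<T> dOh = dO.cols(h * dh, (h + 1) * dh - 1);
      arma::Mat<T> dA = dOh * V.t();
      arma::Mat<T> dV = A.t() * dOh;
      arma::Col<T> rs = arma::sum(dA % A, 1);
      arma::Mat<T> dS = A % (dA.each_col() - rs);
      dS *= scale;
      dQKV.cols(h * dh, (h + 1) * dh - 1) = dS * K;
      dQKV.cols(pp.D + h * dh, pp.D + (h + 1) * dh - 1) = dS.t() * Q;
      dQKV.cols(2 * pp.D + h * dh, 2 * pp.D + (h + 1) * dh - 1) = dV;
    }
    G[o + 3] += arma::sum(dQKV, 0);
    G[o + 2] += cc.h1.t() * dQKV;
    arma::Mat<T> dh1 = dQKV * pp.P[o + 2].t();
    arma::Mat<T> dx_in;
    layernorm_backward(dh1, pp.P[o], cc.xhat1, cc.istd1,
                       dx_in, G[o], G[o + 1]);
    dx = dx_mid + dx_in;
  }
  if (pp.has_pos && dpos) *dpos += dx;
}

// ---- loss ------------------------------------------------------------

// label-smoothed cross entropy with a cost factor W[t, argmax] treated as
// a constant scale (no gradient through the argmax); labels use 255 for
// pixels excluded from the loss. Returns summed (unnormalized) loss and
// writes dlogits (caller divides by total labeled count).
template <typename T>
double loss_tile(const arma::Mat<T>& logits, const int* labels,
                 const arma::mat& Wpen, double eps_smooth,
                 arma::Mat<T>& dlogits, int& n_labeled, int& n_correct) {
  const int N = logits.n_rows, C = logits.n_cols;
  arma::Mat<T> p = logits;
  softmax_rows(p);
  dlogits.zeros(N, C);
  double loss = 0.0;
  for (int i = 0; i < N; ++i) {
    int t = labels[i];
    if (t < 0 || t >= C) continue;  // 255 etc: excluded
    arma::uword yhat = 0;
    T best = p(i, 0);
    for (int c = 1; c < C; ++c) if (p(i, c) > best) { best = p(i, c); yhat = c; }
    double w = Wpen(t, yhat);
    double ll = 0.0;
    const double u = eps_smooth / C;
    for (int c = 0; c < C; ++c) {
      double q = u + ((c == t) ? (1.0 - eps_smooth) : 0.0);
      double lp = std::log(std::max((double)p(i, c), 1e-30));
      ll -= q * lp;
      dlogits(i, c) = (T)(w * ((double)p(i, c) - q));
    }
    loss += w * ll;
    n_labeled++;
    if ((int)yhat == t) n_correct++;
  }
  return loss;
}

// ---- exported entry points ------------------------------------------

template <typename T>
NumericMatrix vit_forward_impl(const NumericMatrix& X, const List& plist,
                               int n_tokens, int n_heads, bool has_pos) {
  Params<T> pp = unpack<T>(plist, n_tokens, n_heads, has_pos);
  const int ntot = X.nrow();
  if (ntot % n_tokens != 0) stop("token count not a multiple of tile size");
  const int B = ntot / n_tokens;
  NumericMatrix out(ntot, pp.C);
  arma::Mat<T> x(n_tokens, pp.D);
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < pp.D; ++j)
      for (int i = 0; i < n_tokens; ++i)
        x(i, j) = (T)X(b * n_tokens + i, j);
    arma::Mat<T> lg = forward_tile<T>(pp, x, nullptr);
    for (int j = 0; j < pp.C; ++j)
      for (int i = 0; i < n_tokens; ++i)
        out(b * n_tokens + i, j) = (double)lg(i, j);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_vit_forward(NumericMatrix X, List params, int n_tokens,
                              int n_heads, bool has_pos,
                              std::string precision = "single") {
  if (precision == "double")
    return vit_forward_impl<double>(X, params, n_tokens, n_heads, has_pos);
  return vit_forward_impl<float>(X, params, n_tokens, n_heads, has_pos);
}

// loss and full gradient for a batch, double precision (gradient checks)
// [[Rcpp::export]]
List cpp_vit_loss_grad(NumericMatrix X, IntegerVector labels, List params,
                       int n_tokens, int n_heads, bool has_pos,
                       NumericMatrix Wpen, double eps_smooth) {
  typedef double T;
  Params<T> pp = unpack<T>(params, n_tokens, n_heads, has_pos);
  const int B = X.nrow() / n_tokens;
  std::vector<arma::Mat<T>> G;
  for (auto& m : pp.P) G.push_back(arma::Mat<T>(m.n_rows, m.n_cols, arma::fill::zeros));
  arma::mat W(Wpen.begin(), Wpen.nrow(), Wpen.ncol());
  double loss = 0.0; int n_lab = 0, n_cor = 0;
  // first pass to count labeled pixels for normalization
  int total_lab = 0;
  for (int i = 0; i < labels.size(); ++i)
    if (labels[i] >= 0 && labels[i] < pp.C) total_lab++;
  if (total_lab == 0) stop("no labeled pixels in batch");
  for (int b = 0; b < B; ++b) {
    arma::Mat<T> x(n_tokens, pp.D);
    for (int j = 0; j < pp.D; ++j)
      for (int i = 0; i < n_tokens; ++i)
        x(i, j) = X(b * n_tokens + i, j);
    std::vector<BlockCache<T>> cache(pp.n_blocks);
    arma::Mat<T> lg = forward_tile<T>(pp, x, &cache);
    arma::Mat<T> dlg;
    loss += loss_tile<T>(lg, &labels[b * n_tokens], W, eps_smooth, dlg,
                         n_lab, n_cor);
    dlg /= (T)total_lab;
    arma::Mat<T>* dpos = pp.has_pos ? &G[0] : nullptr;
    backward_tile<T>(pp, cache, dlg, G, dpos);
  }
  return List::create(_["loss"] = loss / total_lab,
                      _["acc"] = (double)n_cor / total_lab,
                      _["grads"] = pack<T>(G));
}

// one training epoch with AdamW; params/m/v passed and returned as lists
// [[Rcpp::export]]
List cpp_vit_epoch(NumericMatrix X, IntegerVector labels, List params,
                   List adam_m, List adam_v, int step0,
                   NumericVector lrs, IntegerVector order, int batch_tiles,
                   int n_tokens, int n_heads, bool has_pos,
                   NumericMatrix Wpen, double eps_smooth, double weight_decay,
                   IntegerVector decay_mask) {
  typedef float T;
  Params<T> pp = unpack<T>(params, n_tokens, n_heads, has_pos);
  Params<T> mm = unpack<T>(adam_m, n_tokens, n_heads, has_pos);
  Params<T> vv = unpack<T>(adam_v, n_tokens, n_heads, has_pos);
  arma::mat W(Wpen.begin(), Wpen.nrow(), Wpen.ncol());
  const int n_tiles = order.size();
  const int B = X.nrow() / n_tokens;
  const double b1 = 0.9, b2 = 0.999, ae = 1e-8;
  double ep_loss = 0.0; long ep_lab = 0, ep_cor = 0;
  int step = step0;
  std::vector<arma::Mat<T>> G;
  for (auto& m : pp.P) G.push_back(arma::Mat<T>(m.n_rows, m.n_cols));
  int nbatch = (n_tiles + batch_tiles - 1) / batch_tiles;
  for (int bi = 0; bi < nbatch; ++bi) {
    int lo = bi * batch_tiles;
    int hi = std::min(lo + batch_tiles, n_tiles);
    for (auto& g : G) g.zeros();
    // count labeled pixels in this batch
    int total_lab = 0;
    for (int k = lo; k < hi; ++k) {
      int t = order[k];
      if (t < 0 || t >= B) stop("tile index out of range");
      for (int i = 0; i < n_tokens; ++i) {
        int lb = labels[t * n_tokens + i];
        if (lb >= 0 && lb < pp.C) total_lab++;
      }
    }
    if (total_lab == 0) continue;
    double bloss = 0.0; int n_lab = 0, n_cor = 0;
    for (int k = lo; k < hi; ++k) {
      int t = order[k];
      arma::Mat<T> x(n_tokens, pp.D);
      for (int j = 0; j < pp.D; ++j)
        for (int i = 0; i < n_tokens; ++i)
          x(i, j) = (T)X(t * n_tokens + i, j);
      std::vector<BlockCache<T>> cache(pp.n_blocks);
      arma::Mat<T> lg = forward_tile<T>(pp, x, &cache);
      arma::Mat<T> dlg;
      bloss += loss_tile<T>(lg, &labels[t * n_tokens], W, eps_smooth, dlg,
                            n_lab, n_cor);
      dlg /= (T)total_lab;
      arma::Mat<T>* dpos = pp.has_pos ? &G[0] : nullptr;
      backward_tile<T>(pp, cache, dlg, G, dpos);
    }
    // AdamW update
    step++;
    double lr = lrs[std::min(bi, (int)lrs.size() - 1)];
    double bc1 = 1.0 - std::pow(b1, (double)step);
    double bc2 = 1.0 - std::pow(b2, (double)step);
    for (size_t p = 0; p < pp.P.size(); ++p) {
      mm.P[p] = (T)b1 * mm.P[p] + (T)(1.0 - b1) * G[p];
      vv.P[p] = (T)b2 * vv.P[p] + (T)(1.0 - b2) * arma::square(G[p]);
      arma::Mat<T> upd = (mm.P[p] / (T)bc1) /
        (arma::sqrt(vv.P[p] / (T)bc2) + (T)ae);
      if (weight_decay > 0 && decay_mask[p]) upd += (T)weight_decay * pp.P[p];
      pp.P[p] -= (T)lr * upd;
    }
    ep_loss += bloss; ep_lab += n_lab; ep_cor += n_cor;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = pack<T>(pp.P),
                      _["m"] = pack<T>(mm.P), _["v"] = pack<T>(vv.P),
                      _["step"] = step,
                      _["loss"] = ep_lab ? ep_loss / ep_lab : NA_REAL,
                      _["acc"] = ep_lab ? (double)ep_cor / ep_lab : NA_REAL);
}

// per-row min and max of a matrix in one pass (normalization hot path)
// [[Rcpp::export]]
NumericMatrix cpp_row_range(NumericMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  NumericMatrix out(nr, 2);
  for (int i = 0; i < nr; ++i) { out(i, 0) = m(i, 0); out(i, 1) = m(i, 0); }
  for (int j = 1; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double v = m(i, j);
      if (v < out(i, 0)) out(i, 0) = v;
      if (v > out(i, 1)) out(i, 1) = v;
    }
  return out;
}

// ---- morphology ------------------------------------------------------

// 3x3 full-kernel binary erosion; pixels outside the image count as
// background, so blobs touching the border lose their rim like any other.
// [[Rcpp::export]]
LogicalMatrix cpp_erode3x3(LogicalMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      bool keep = true;
      for (int dj = -1; dj <= 1 && keep; ++dj)
        for (int di = -1; di <= 1 && keep; ++di) {
          int ii = i + di, jj = j + dj;
          if (ii < 0 || jj < 0 || ii >= nr || jj >= nc || !m(ii, jj))
            keep = false;
        }
      out(i, j) = keep;
    }
  return out;
}

// 8-connected component labelling (two-pass union-find); 0 = background
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!m(i, j)) continue;
      // neighbours already visited in column-major order
      int best = 0;
      const int di[4] = {-1, -1, 0, 1};
      const int dj[4] = {0, -1, -1, -1};
      for (int k = 0; k < 4; ++k) {
        int ii = i + di[k], jj = j + dj[k];
        if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
        int l = lab(ii, jj);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
        }
      }
      if (best == 0) {
        best = ++next;
        parent.push_back(best);
      }
      lab(i, j) = best;
    }
  // second pass: compress and renumber densely
  std::vector<int> remap(next + 1, 0);
  int nlab = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!lab(i, j)) continue;
      int r = find(lab(i, j));
      if (!remap[r]) remap[r] = ++nlab;
      lab(i, j) = remap[r];
    }
  return lab;
}
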