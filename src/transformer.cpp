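// Label-embedding Transformer core: forward pass, analytic backward pass and
// the BCE training objective, operating on a flat parameter vector whose
// canonical layout is mirrored by param_layout() on the R side.
//
// Canonical parameter order (column-major within each tensor):
//   enc_in_W (40 x d), enc_in_b (d)
//   per encoder layer: Wq,bq,Wk,bk,Wv,bv,Wo,bo, ln1_g,ln1_b,
//                      ffW1 (d x f), ffb1 (f), ffW2 (f x d), ffb2 (d), ln2_g,ln2_b
//   dec_in_W (C x d), dec_in_b (d)
//   per decoder layer: self {Wq..bo}, ln1_g,ln1_b, cross {Wq..bo}, ln2_g,ln2_b,
//                      ffW1,ffb1,ffW2,ffb2, ln3_g,ln3_b
//   w_single (d), b_single (1), W_spec (d x C), b_spec (C)
//
// Numerical conventions:
//  * attention logits are scaled by sqrt(d_model) (the model's printed form),
//    not per-head sqrt(d_k); heads are conventional d_model/h slices.
//  * padded key positions receive -Inf logits, so their weights are exactly 0
//    and padded features can never leak into the function representations.
//    When the padding mask is a suffix (the pad/truncate rule always pads at
//    the end) the padded rows are dropped from the computation entirely —
//    they carry exactly zero attention weight and zero gradient either way.
//  * decoder self-attention (function-function attention) uses sorted,
//    permutation-invariant summation for the softmax normalizer and for the
//    weights*V contraction, which makes the forward pass bit-exactly
//    equivariant under permutation of the function tokens.
//
// The whole minibatch is processed as one row-stacked matrix per tensor
// (samples delimited by offset/length indices), so that every projection,
// layer norm and feed-forward runs as a single large GEMM; only the
// attention score/apply step loops over samples.

#include <RcppArmadillo.h>
#include <random>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::cube;
using arma::uword;

struct Cfg {
  int d, h, n_enc, n_dec, f, L, C, mask_pad;
  double pe_base;
  int d_pe;
};

static Cfg read_cfg(const List& cfg) {
  Cfg c;
  c.d = as<int>(cfg["d_model"]);
  c.h = as<int>(cfg["h"]);
  c.n_enc = as<int>(cfg["n_enc_layers"]);
  c.n_dec = as<int>(cfg["n_dec_layers"]);
  c.f = as<int>(cfg["d_ff"]);
  c.L = as<int>(cfg["L"]);
  c.C = as<int>(cfg["C"]);
  c.mask_pad = as<bool>(cfg["mask_padding"]) ? 1 : 0;
  c.pe_base = as<double>(cfg["pe_base"]);
  c.d_pe = as<int>(cfg["d_pe"]);
  if (c.d % c.h != 0) stop("d_model must be divisible by h");
  return c;
}

// ---------------------------------------------------------------- parameters

struct Attn { mat Wq, Wk, Wv, Wo; vec bq, bk, bv, bo; };
struct LNp  { vec g, b; };
struct FFp  { mat W1, W2; vec b1, b2; };
struct EncLayer { Attn att; LNp ln1; FFp ff; LNp ln2; };
struct DecLayer { Attn self; LNp ln1; Attn cross; LNp ln2; FFp ff; LNp ln3; };

struct Params {
  mat enc_in_W; vec enc_in_b;
  std::vector<EncLayer> enc;
  mat dec_in_W; vec dec_in_b;
  std::vector<DecLayer> dec;
  vec w_single; double b_single;
  mat W_spec; vec b_spec;
};

struct RCur {
  const double* p; size_t pos;
  mat M(int r, int c) { mat m(&p[pos], r, c); pos += (size_t)r * c; return m; }
  vec V(int n) { vec v(&p[pos], n); pos += n; return v; }
  double S() { return p[pos++]; }
};

struct WCur {
  double* p; size_t pos;
  void M(const mat& m) { std::copy(m.memptr(), m.memptr() + m.n_elem, p + pos); pos += m.n_elem; }
  void V(const vec& v) { std::copy(v.memptr(), v.memptr() + v.n_elem, p + pos); pos += v.n_elem; }
  void S(double s) { p[pos++] = s; }
};

static Attn read_attn(RCur& c, int d) {
  Attn a;
  a.Wq = c.M(d, d); a.bq = c.V(d);
  a.Wk = c.M(d, d); a.bk = c.V(d);
  a.Wv = c.M(d, d); a.bv = c.V(d);
  a.Wo = c.M(d, d); a.bo = c.V(d);
  return a;
}
static LNp read_ln(RCur& c, int d) { LNp l; l.g = c.V(d); l.b = c.V(d); return l; }
static FFp read_ff(RCur& c, int d, int f) {
  FFp p; p.W1 = c.M(d, f); p.b1 = c.V(f); p.W2 = c.M(f, d); p.b2 = c.V(d); return p;
}

static Params unpack(const double* ptr, const Cfg& cfg) {
  RCur c{ptr, 0};
  Params P;
  P.enc_in_W = c.M(40, cfg.d); P.enc_in_b = c.V(cfg.d);
  for (int l = 0; l < cfg.n_enc; ++l) {
    EncLayer e;
    e.att = read_attn(c, cfg.d); e.ln1 = read_ln(c, cfg.d);
    e.ff = read_ff(c, cfg.d, cfg.f); e.ln2 = read_ln(c, cfg.d);
    P.enc.push_back(e);
  }
  P.dec_in_W = c.M(cfg.C, cfg.d); P.dec_in_b = c.V(cfg.d);
  for (int l = 0; l < cfg.n_dec; ++l) {
    DecLayer dl;
    dl.self = read_attn(c, cfg.d); dl.ln1 = read_ln(c, cfg.d);
    dl.cross = read_attn(c, cfg.d); dl.ln2 = read_ln(c, cfg.d);
    dl.ff = read_ff(c, cfg.d, cfg.f); dl.ln3 = read_ln(c, cfg.d);
    P.dec.push_back(dl);
  }
  P.w_single = c.V(cfg.d); P.b_single = c.S();
  P.W_spec = c.M(cfg.d, cfg.C); P.b_spec = c.V(cfg.C);
  return P;
}

static void zero_attn(Attn& a, int d) {
  a.Wq.zeros(d, d); a.bq.zeros(d);
  a.Wk.zeros(d, d); a.bk.zeros(d);
  a.Wv.zeros(d, d); a.bv.zeros(d);
  a.Wo.zeros(d, d); a.bo.zeros(d);
}

static Params zeros_like(const Cfg& cfg) {
  Params P;
  P.enc_in_W.zeros(40, cfg.d); P.enc_in_b.zeros(cfg.d);
  for (int l = 0; l < cfg.n_enc; ++l) {
    EncLayer e;
    zero_attn(e.att, cfg.d);
    e.ln1.g.zeros(cfg.d); e.ln1.b.zeros(cfg.d);
    e.ff.W1.zeros(cfg.d, cfg.f); e.ff.b1.zeros(cfg.f);
    e.ff.W2.zeros(cfg.f, cfg.d); e.ff.b2.zeros(cfg.d);
    e.ln2.g.zeros(cfg.d); e.ln2.b.zeros(cfg.d);
    P.enc.push_back(e);
  }
  P.dec_in_W.zeros(cfg.C, cfg.d); P.dec_in_b.zeros(cfg.d);
  for (int l = 0; l < cfg.n_dec; ++l) {
    DecLayer dl;
    zero_attn(dl.self, cfg.d);
    dl.ln1.g.zeros(cfg.d); dl.ln1.b.zeros(cfg.d);
    zero_attn(dl.cross, cfg.d);
    dl.ln2.g.zeros(cfg.d); dl.ln2.b.zeros(cfg.d);
    dl.ff.W1.zeros(cfg.d, cfg.f); dl.ff.b1.zeros(cfg.f);
    dl.ff.W2.zeros(cfg.f, cfg.d); dl.ff.b2.zeros(cfg.d);
    dl.ln3.g.zeros(cfg.d); dl.ln3.b.zeros(cfg.d);
    P.dec.push_back(dl);
  }
  P.w_single.zeros(cfg.d); P.b_single = 0.0;
  P.W_spec.zeros(cfg.d, cfg.C); P.b_spec.zeros(cfg.C);
  return P;
}

static void write_attn(WCur& c, const Attn& a) {
  c.M(a.Wq); c.V(a.bq); c.M(a.Wk); c.V(a.bk);
  c.M(a.Wv); c.V(a.bv); c.M(a.Wo); c.V(a.bo);
}

static void pack(double* ptr, const Params& P, const Cfg& cfg) {
  WCur c{ptr, 0};
  c.M(P.enc_in_W); c.V(P.enc_in_b);
  for (int l = 0; l < cfg.n_enc; ++l) {
    const EncLayer& e = P.enc[l];
    write_attn(c, e.att); c.V(e.ln1.g); c.V(e.ln1.b);
    c.M(e.ff.W1); c.V(e.ff.b1); c.M(e.ff.W2); c.V(e.ff.b2);
    c.V(e.ln2.g); c.V(e.ln2.b);
  }
  c.M(P.dec_in_W); c.V(P.dec_in_b);
  for (int l = 0; l < cfg.n_dec; ++l) {
    const DecLayer& dl = P.dec[l];
    write_attn(c, dl.self); c.V(dl.ln1.g); c.V(dl.ln1.b);
    write_attn(c, dl.cross); c.V(dl.ln2.g); c.V(dl.ln2.b);
    c.M(dl.ff.W1); c.V(dl.ff.b1); c.M(dl.ff.W2); c.V(dl.ff.b2);
    c.V(dl.ln3.g); c.V(dl.ln3.b);
  }
  c.V(P.w_single); c.S(P.b_single);
  c.M(P.W_spec); c.V(P.b_spec);
}

static size_t param_count(const Cfg& c) {
  size_t attn = 4 * ((size_t)c.d * c.d + c.d);
  size_t ln = 2 * (size_t)c.d;
  size_t ff = (size_t)c.d * c.f + c.f + (size_t)c.f * c.d + c.d;
  size_t enc = 40 * (size_t)c.d + c.d + c.n_enc * (attn + ln + ff + ln);
  size_t dec = (size_t)c.C * c.d + c.d + c.n_dec * (2 * attn + 3 * ln + ff);
  size_t heads = (size_t)c.d + 1 + (size_t)c.d * c.C + c.C;
  return enc + dec + heads;
}

// [[Rcpp::export(name = ".cpp_param_count")]]
int cpp_param_count(List cfg) {
  return (int)param_count(read_cfg(cfg));
}

// ------------------------------------------------------------------- pieces

static mat linear(const mat& X, const mat& W, const vec& b) {
  mat Y = X * W;
  Y.each_row() += b.t();
  return Y;
}

// [[Rcpp::export(name = ".cpp_positional_encoding")]]
arma::mat cpp_positional_encoding(int L, int d, double base, int d_pe) {
  mat pe(L, d);
  for (int pos = 0; pos < L; ++pos)
    for (int j = 0; j < d; ++j) {
      int i = j / 2;
      double ang = pos / std::pow(base, (2.0 * i) / d_pe);
      pe(pos, j) = (j % 2 == 0) ? std::sin(ang) : std::cos(ang);
    }
  return pe;
}

static double sorted_sum(std::vector<double>& v) {
  std::sort(v.begin(), v.end());
  double s = 0.0;
  for (double x : v) s += x;
  return s;
}

// row softmax over (already masked) logits; sorted_mode uses a
// permutation-invariant summation for the normalizer
static mat softmax_rows(const mat& S, bool sorted_mode) {
  if (!sorted_mode) {
    vec mx = arma::max(S, 1);
    mat W = arma::exp(S.each_col() - mx);
    W.each_col() /= arma::sum(W, 1);
    return W;
  }
  mat W(S.n_rows, S.n_cols);
  std::vector<double> buf;
  for (uword i = 0; i < S.n_rows; ++i) {
    rowvec s = S.row(i);
    double mx = s.max();
    rowvec e = arma::exp(s - mx);
    buf.assign(e.begin(), e.end());
    W.row(i) = e / sorted_sum(buf);
  }
  return W;
}

static mat matmul_sorted(const mat& W, const mat& V) {
  mat O(W.n_rows, V.n_cols);
  std::vector<double> buf(W.n_cols);
  for (uword i = 0; i < W.n_rows; ++i)
    for (uword k = 0; k < V.n_cols; ++k) {
      for (uword j = 0; j < W.n_cols; ++j) buf[j] = W(i, j) * V(j, k);
      O(i, k) = sorted_sum(buf);
    }
  return O;
}

struct LNCache { mat X, xhat; vec istd; };

static mat ln_fwd(const mat& X, const LNp& p, LNCache& c) {
  c.X = X;
  vec mu = arma::mean(X, 1);
  mat Xc = X.each_col() - mu;
  vec v = arma::mean(arma::square(Xc), 1);
  c.istd = 1.0 / arma::sqrt(v + 1e-5);
  c.xhat = Xc.each_col() % c.istd;
  mat Y = c.xhat.each_row() % p.g.t();
  Y.each_row() += p.b.t();
  return Y;
}

static mat ln_bwd(const LNCache& c, const LNp& p, LNp& g, const mat& dY) {
  g.g += arma::sum(dY % c.xhat, 0).t();
  g.b += arma::sum(dY, 0).t();
  mat dxh = dY.each_row() % p.g.t();
  vec m1 = arma::mean(dxh, 1);
  vec m2 = arma::mean(dxh % c.xhat, 1);
  mat dX = dxh.each_col() - m1;
  dX -= c.xhat.each_col() % m2;
  dX.each_col() %= c.istd;
  return dX;
}

struct FFCache { mat X, A1; };

static mat ff_fwd(const mat& X, const FFp& p, FFCache& c) {
  c.X = X;
  c.A1 = linear(X, p.W1, p.b1);
  c.A1.transform([](double x) { return x > 0.0 ? x : 0.0; });
  return linear(c.A1, p.W2, p.b2);
}

static mat ff_bwd(const FFCache& c, const FFp& p, FFp& g, const mat& dY) {
  g.W2 += c.A1.t() * dY;
  g.b2 += arma::sum(dY, 0).t();
  mat dA1 = dY * p.W2.t();
  dA1.elem(arma::find(c.A1 == 0.0)).zeros();
  g.W1 += c.X.t() * dA1;
  g.b1 += arma::sum(dA1, 0).t();
  return dA1 * p.W1.t();
}

static mat drop_fwd(const mat& X, double p, std::mt19937_64& rng, mat& mask) {
  if (p <= 0.0) { mask.reset(); return X; }
  mask.set_size(arma::size(X));
  std::uniform_real_distribution<double> u(0.0, 1.0);
  double keep = 1.0 - p;
  for (uword i = 0; i < mask.n_elem; ++i)
    mask(i) = (u(rng) < keep) ? 1.0 / keep : 0.0;
  return X % mask;
}

// ----------------------------------------------------------- batch indexing

// Row ranges of each sample inside a stacked matrix.
struct BatchIdx {
  std::vector<uword> off, len;
  uword total;
};

static BatchIdx uniform_idx(int B, uword n) {
  BatchIdx bi;
  bi.off.resize(B); bi.len.resize(B);
  for (int b = 0; b < B; ++b) { bi.off[b] = (uword)b * n; bi.len[b] = n; }
  bi.total = (uword)B * n;
  return bi;
}

// ------------------------------------------------- batched multi-head attn

struct MHACache {
  mat Xq, Xkv, Q, K, V, ConcO;
  std::vector<std::vector<mat>> W;  // [sample][head]
};

// keymask[b]: indices (within sample b's kv rows) of masked-out keys
static mat mha_fwd(const mat& Xq, const BatchIdx& qi,
                   const mat& Xkv, const BatchIdx& ki,
                   const Attn& a, const Cfg& cfg,
                   const std::vector<arma::uvec>* keymask, bool sorted_mode,
                   MHACache& c, std::vector<cube>* attn_out) {
  int B = qi.off.size();
  int dk = cfg.d / cfg.h;
  double scale = std::sqrt((double)cfg.d);
  c.Xq = Xq; c.Xkv = Xkv;
  c.Q = linear(Xq, a.Wq, a.bq);
  c.K = linear(Xkv, a.Wk, a.bk);
  c.V = linear(Xkv, a.Wv, a.bv);
  c.ConcO.set_size(qi.total, cfg.d);
  c.W.assign(B, std::vector<mat>());
  if (attn_out) attn_out->resize(B);
  for (int b = 0; b < B; ++b) {
    uword q0 = qi.off[b], q1 = q0 + qi.len[b] - 1;
    uword k0 = ki.off[b], k1 = k0 + ki.len[b] - 1;
    if (attn_out) (*attn_out)[b].set_size(qi.len[b], ki.len[b], cfg.h);
    for (int t = 0; t < cfg.h; ++t) {
      uword c0 = (uword)t * dk, c1 = c0 + dk - 1;
      mat S = (c.Q.submat(q0, c0, q1, c1) * c.K.submat(k0, c0, k1, c1).t()) / scale;
      if (keymask && !(*keymask)[b].is_empty())
        for (uword jj : (*keymask)[b]) S.col(jj).fill(-arma::datum::inf);
      mat W = softmax_rows(S, sorted_mode);
      if (attn_out) (*attn_out)[b].slice(t) = W;
      c.ConcO.submat(q0, c0, q1, c1) =
        sorted_mode ? matmul_sorted(W, c.V.submat(k0, c0, k1, c1))
                    : mat(W * c.V.submat(k0, c0, k1, c1));
      c.W[b].push_back(std::move(W));
    }
  }
  return linear(c.ConcO, a.Wo, a.bo);
}

static void mha_bwd(const MHACache& c, const BatchIdx& qi, const BatchIdx& ki,
                    const Attn& a, Attn& g, const Cfg& cfg,
                    const mat& dOut, mat& dXq_acc, mat& dXkv_acc) {
  int B = qi.off.size();
  int dk = cfg.d / cfg.h;
  double scale = std::sqrt((double)cfg.d);
  mat dConc = dOut * a.Wo.t();
  g.Wo += c.ConcO.t() * dOut;
  g.bo += arma::sum(dOut, 0).t();
  mat dQ(c.Q.n_rows, cfg.d, arma::fill::zeros);
  mat dK(c.K.n_rows, cfg.d, arma::fill::zeros);
  mat dV(c.V.n_rows, cfg.d, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    uword q0 = qi.off[b], q1 = q0 + qi.len[b] - 1;
    uword k0 = ki.off[b], k1 = k0 + ki.len[b] - 1;
    for (int t = 0; t < cfg.h; ++t) {
      uword c0 = (uword)t * dk, c1 = c0 + dk - 1;
      const mat& W = c.W[b][t];
      mat dOh = dConc.submat(q0, c0, q1, c1);
      mat dW = dOh * c.V.submat(k0, c0, k1, c1).t();
      dV.submat(k0, c0, k1, c1) += W.t() * dOh;
      vec rs = arma::sum(dW % W, 1);
      mat dS = W % (dW.each_col() - rs);
      dQ.submat(q0, c0, q1, c1) += (dS * c.K.submat(k0, c0, k1, c1)) / scale;
      dK.submat(k0, c0, k1, c1) += (dS.t() * c.Q.submat(q0, c0, q1, c1)) / scale;
    }
  }
  dXq_acc += dQ * a.Wq.t();
  g.Wq += c.Xq.t() * dQ; g.bq += arma::sum(dQ, 0).t();
  dXkv_acc += dK * a.Wk.t() + dV * a.Wv.t();
  g.Wk += c.Xkv.t() * dK; g.bk += arma::sum(dK, 0).t();
  g.Wv += c.Xkv.t() * dV; g.bv += arma::sum(dV, 0).t();
}

// ------------------------------------------------------------ batch passes

struct EncLayerCache { MHACache mha; mat dm1; LNCache ln1; FFCache ff; mat dm2; LNCache ln2; };
struct DecLayerCache {
  MHACache self; mat dm1; LNCache ln1;
  MHACache cross; mat dm2; LNCache ln2;
  FFCache ff; mat dm3; LNCache ln3;
};

struct BatchCache {
  mat X40, Xt_rep, Henc;
  BatchIdx ei, di;
  std::vector<arma::uvec> keymask;
  std::vector<EncLayerCache> enc;
  std::vector<DecLayerCache> dec;
  mat Z;  // stacked (B*C_t) x d
};

struct AttnRec { std::vector<std::vector<cube>> enc, dec_self, dec_cross; };  // [layer][sample]

// Does the mask column consist of ones followed by zeros?
static int suffix_mask_len(const double* m, int L) {
  int n = 0;
  while (n < L && m[n] == 1.0) ++n;
  for (int j = n; j < L; ++j)
    if (m[j] != 0.0) return -1;
  return n;
}

// Build the stacked encoder input. When every mask is a suffix mask (and
// padding is masked), padded rows are dropped; otherwise full rows are kept
// and the per-sample masked key indices recorded.
static void stack_inputs(const arma::cube& X, const arma::mat& maskM,
                         const Cfg& cfg, bool keep_full,
                         mat& X40, BatchIdx& ei,
                         std::vector<arma::uvec>& keymask) {
  int B = X.n_slices;
  ei.off.resize(B); ei.len.resize(B);
  keymask.assign(B, arma::uvec());
  std::vector<int> nreal(B);
  bool all_suffix = cfg.mask_pad && !keep_full;
  for (int b = 0; b < B; ++b) {
    nreal[b] = suffix_mask_len(maskM.colptr(b), cfg.L);
    if (nreal[b] <= 0) all_suffix = false;
  }
  uword pos = 0;
  for (int b = 0; b < B; ++b) {
    uword n = all_suffix ? (uword)nreal[b] : (uword)cfg.L;
    ei.off[b] = pos; ei.len[b] = n;
    pos += n;
  }
  ei.total = pos;
  X40.set_size(pos, 40);
  for (int b = 0; b < B; ++b)
    X40.rows(ei.off[b], ei.off[b] + ei.len[b] - 1) =
      X.slice(b).rows(0, ei.len[b] - 1);
  if (!all_suffix && cfg.mask_pad) {
    for (int b = 0; b < B; ++b)
      keymask[b] = arma::find(arma::vec(maskM.colptr(b), cfg.L) == 0.0);
  }
}

static void forward_batch(const Params& P, const Cfg& cfg,
                          const arma::cube& X, const arma::mat& maskM,
                          const mat& Xt, bool keep_full,
                          double dropout, std::mt19937_64& rng,
                          BatchCache& bc, AttnRec* rec) {
  int B = X.n_slices;
  stack_inputs(X, maskM, cfg, keep_full || rec != nullptr, bc.X40, bc.ei,
               bc.keymask);
  const std::vector<arma::uvec>* km =
    (cfg.mask_pad && !bc.keymask.empty() &&
     std::any_of(bc.keymask.begin(), bc.keymask.end(),
                 [](const arma::uvec& u) { return !u.is_empty(); }))
    ? &bc.keymask : nullptr;
  bc.enc.assign(cfg.n_enc, EncLayerCache());
  bc.dec.assign(cfg.n_dec, DecLayerCache());
  if (rec) {
    rec->enc.resize(cfg.n_enc);
    rec->dec_self.resize(cfg.n_dec);
    rec->dec_cross.resize(cfg.n_dec);
  }
  // the input embeddings are scaled by sqrt(d_model) before the positional
  // encodings are added (the standard Transformer convention; without it
  // the unit-amplitude PE would drown the content signal)
  double emb_scale = std::sqrt((double)cfg.d);
  mat pe = cpp_positional_encoding(cfg.L, cfg.d, cfg.pe_base, cfg.d_pe);
  mat H = linear(bc.X40, P.enc_in_W, P.enc_in_b) * emb_scale;
  for (int b = 0; b < B; ++b)
    H.rows(bc.ei.off[b], bc.ei.off[b] + bc.ei.len[b] - 1) +=
      pe.rows(0, bc.ei.len[b] - 1);
  for (int l = 0; l < cfg.n_enc; ++l) {
    EncLayerCache& ec = bc.enc[l];
    mat A = mha_fwd(H, bc.ei, H, bc.ei, P.enc[l].att, cfg, km, false, ec.mha,
                    rec ? &rec->enc[l] : nullptr);
    A = drop_fwd(A, dropout, rng, ec.dm1);
    H = ln_fwd(H + A, P.enc[l].ln1, ec.ln1);
    mat F = ff_fwd(H, P.enc[l].ff, ec.ff);
    F = drop_fwd(F, dropout, rng, ec.dm2);
    H = ln_fwd(H + F, P.enc[l].ln2, ec.ln2);
  }
  bc.Henc = H;
  // decoder input: Xt (n_t x C) replicated per sample
  uword n_t = Xt.n_rows;
  bc.di = uniform_idx(B, n_t);
  bc.Xt_rep.set_size(bc.di.total, Xt.n_cols);
  for (int b = 0; b < B; ++b)
    bc.Xt_rep.rows(bc.di.off[b], bc.di.off[b] + n_t - 1) = Xt;
  mat D = linear(bc.Xt_rep, P.dec_in_W, P.dec_in_b) * emb_scale;
  for (int l = 0; l < cfg.n_dec; ++l) {
    DecLayerCache& dc = bc.dec[l];
    mat A1 = mha_fwd(D, bc.di, D, bc.di, P.dec[l].self, cfg, nullptr, true,
                     dc.self, rec ? &rec->dec_self[l] : nullptr);
    A1 = drop_fwd(A1, dropout, rng, dc.dm1);
    D = ln_fwd(D + A1, P.dec[l].ln1, dc.ln1);
    mat A2 = mha_fwd(D, bc.di, bc.Henc, bc.ei, P.dec[l].cross, cfg, km, false,
                     dc.cross, rec ? &rec->dec_cross[l] : nullptr);
    A2 = drop_fwd(A2, dropout, rng, dc.dm2);
    D = ln_fwd(D + A2, P.dec[l].ln2, dc.ln2);
    mat F = ff_fwd(D, P.dec[l].ff, dc.ff);
    F = drop_fwd(F, dropout, rng, dc.dm3);
    D = ln_fwd(D + F, P.dec[l].ln3, dc.ln3);
  }
  bc.Z = D;
}

static void backward_batch(const Params& P, Params& G, const Cfg& cfg,
                           const BatchCache& bc, const mat& dZ) {
  mat dD = dZ;
  mat dHenc(bc.Henc.n_rows, bc.Henc.n_cols, arma::fill::zeros);
  for (int l = cfg.n_dec - 1; l >= 0; --l) {
    const DecLayerCache& dc = bc.dec[l];
    mat dR3 = ln_bwd(dc.ln3, P.dec[l].ln3, G.dec[l].ln3, dD);
    mat dF = dc.dm3.is_empty() ? dR3 : mat(dR3 % dc.dm3);
    mat dD2 = dR3 + ff_bwd(dc.ff, P.dec[l].ff, G.dec[l].ff, dF);
    mat dR2 = ln_bwd(dc.ln2, P.dec[l].ln2, G.dec[l].ln2, dD2);
    mat dA2 = dc.dm2.is_empty() ? dR2 : mat(dR2 % dc.dm2);
    mat dD1 = dR2;
    mha_bwd(dc.cross, bc.di, bc.ei, P.dec[l].cross, G.dec[l].cross, cfg,
            dA2, dD1, dHenc);
    mat dR1 = ln_bwd(dc.ln1, P.dec[l].ln1, G.dec[l].ln1, dD1);
    mat dA1 = dc.dm1.is_empty() ? dR1 : mat(dR1 % dc.dm1);
    mat dD0 = dR1;
    mha_bwd(dc.self, bc.di, bc.di, P.dec[l].self, G.dec[l].self, cfg,
            dA1, dD0, dD0);
    dD = dD0;
  }
  double emb_scale = std::sqrt((double)cfg.d);
  G.dec_in_W += emb_scale * (bc.Xt_rep.t() * dD);
  G.dec_in_b += emb_scale * arma::sum(dD, 0).t();
  mat dH = dHenc;
  for (int l = cfg.n_enc - 1; l >= 0; --l) {
    const EncLayerCache& ec = bc.enc[l];
    mat dR2 = ln_bwd(ec.ln2, P.enc[l].ln2, G.enc[l].ln2, dH);
    mat dF = ec.dm2.is_empty() ? dR2 : mat(dR2 % ec.dm2);
    mat dH1 = dR2 + ff_bwd(ec.ff, P.enc[l].ff, G.enc[l].ff, dF);
    mat dR1 = ln_bwd(ec.ln1, P.enc[l].ln1, G.enc[l].ln1, dH1);
    mat dA = ec.dm1.is_empty() ? dR1 : mat(dR1 % ec.dm1);
    mat dX = dR1;
    mha_bwd(ec.mha, bc.ei, bc.ei, P.enc[l].att, G.enc[l].att, cfg, dA, dX, dX);
    dH = dX;
  }
  G.enc_in_W += emb_scale * (bc.X40.t() * dH);
  G.enc_in_b += emb_scale * arma::sum(dH, 0).t();
}

// ------------------------------------------------------------------ exports

// [[Rcpp::export(name = ".cpp_forward")]]
List cpp_forward(NumericVector par, List cfg_, arma::cube X, arma::mat maskM,
                 arma::mat Xt, bool want_attention) {
  Cfg cfg = read_cfg(cfg_);
  if (par.size() != (R_xlen_t)param_count(cfg)) stop("parameter vector length mismatch");
  if ((int)X.n_rows != cfg.L || (int)X.n_cols != 40) stop("X must be L x 40 x B");
  if ((int)Xt.n_cols != cfg.C) stop("Xt must have C columns");
  if ((int)maskM.n_rows != cfg.L || maskM.n_cols != X.n_slices)
    stop("mask must be L x B");
  Params P = unpack(REAL(par), cfg);
  int B = X.n_slices;
  uword n_t = Xt.n_rows;
  std::mt19937_64 rng(0);
  BatchCache bc;
  AttnRec rec;
  forward_batch(P, cfg, X, maskM, Xt, false, 0.0, rng, bc,
                want_attention ? &rec : nullptr);
  cube Z(n_t, cfg.d, B);
  for (int b = 0; b < B; ++b)
    Z.slice(b) = bc.Z.rows(bc.di.off[b], bc.di.off[b] + n_t - 1);
  if (!want_attention) return List::create(_["Z"] = Z);
  List attn(B);
  for (int b = 0; b < B; ++b) {
    List e(cfg.n_enc), ds(cfg.n_dec), dx(cfg.n_dec);
    for (int l = 0; l < cfg.n_enc; ++l) e[l] = rec.enc[l][b];
    for (int l = 0; l < cfg.n_dec; ++l) {
      ds[l] = rec.dec_self[l][b];
      dx[l] = rec.dec_cross[l][b];
    }
    attn[b] = List::create(_["residue_residue"] = e,
                           _["function_function"] = ds,
                           _["function_residue"] = dx);
  }
  return List::create(_["Z"] = Z, _["attention"] = attn);
}

// head_mode: 0 = single shared classifier, 1 = function-specific classifiers
// loss_mask: per-function weights on the BCE terms (1s normally; a one-hot
// vector when retraining a single classifier)
// [[Rcpp::export(name = ".cpp_loss_grad")]]
List cpp_loss_grad(NumericVector par, List cfg_, arma::cube X, arma::mat maskM,
                   arma::mat Y, int head_mode, arma::vec loss_mask,
                   double dropout, int seed) {
  Cfg cfg = read_cfg(cfg_);
  if (par.size() != (R_xlen_t)param_count(cfg)) stop("parameter vector length mismatch");
  int B = X.n_slices;
  if ((int)Y.n_rows != B || (int)Y.n_cols != cfg.C) stop("Y must be B x C");
  Params P = unpack(REAL(par), cfg);
  Params G = zeros_like(cfg);
  mat Xt(cfg.C, cfg.C, arma::fill::eye);
  std::mt19937_64 rng((uint64_t)seed);
  BatchCache bc;
  forward_batch(P, cfg, X, maskM, Xt, false, dropout, rng, bc, nullptr);
  double loss = 0.0;
  const double eps = 1e-7;
  mat probs(B, cfg.C);
  mat dZ(bc.Z.n_rows, cfg.d, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    mat Zb = bc.Z.rows(bc.di.off[b], bc.di.off[b] + cfg.C - 1);
    vec u(cfg.C);
    if (head_mode == 0) {
      u = Zb * P.w_single + P.b_single;
    } else {
      for (int c = 0; c < cfg.C; ++c)
        u(c) = arma::dot(P.W_spec.col(c), Zb.row(c).t()) + P.b_spec(c);
    }
    vec p = 1.0 / (1.0 + arma::exp(-u));
    probs.row(b) = p.t();
    vec y = Y.row(b).t();
    for (int c = 0; c < cfg.C; ++c) {
      double pc = std::min(std::max(p(c), eps), 1.0 - eps);
      loss += loss_mask(c) * -(y(c) * std::log(pc) + (1.0 - y(c)) * std::log(1.0 - pc));
    }
    vec du = ((p - y) % loss_mask) / (double)B;
    if (head_mode == 0) {
      dZ.rows(bc.di.off[b], bc.di.off[b] + cfg.C - 1) = du * P.w_single.t();
      G.w_single += Zb.t() * du;
      G.b_single += arma::accu(du);
    } else {
      for (int c = 0; c < cfg.C; ++c) {
        dZ.row(bc.di.off[b] + c) = du(c) * P.W_spec.col(c).t();
        G.W_spec.col(c) += du(c) * Zb.row(c).t();
        G.b_spec(c) += du(c);
      }
    }
  }
  backward_batch(P, G, cfg, bc, dZ);
  loss /= (double)B;
  NumericVector grad((R_xlen_t)param_count(cfg));
  pack(REAL(grad), G, cfg);
  return List::create(_["loss"] = loss, _["grad"] = grad, _["probs"] = probs);
}
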