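// Hierarchical attention network core: fused-feature projection,
// residue-level Bi-GRU + attention within each K-mer, K-mer-level Bi-GRU
// + attention across K-mers, softmax output; forward plus analytic
// backpropagation for the class-weighted cross-entropy. The pure-R
// reference in R/han_model.R implements the same computation; the test
// suite asserts agreement between the two paths.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

namespace {

struct ParamTable {
  std::map<std::string, std::array<long, 3>> entries;  // offset, nrow, ncol
  const double* base;

  mat get(const std::string& name) const {
    auto it = entries.find(name);
    if (it == entries.end()) stop("unknown parameter tensor: " + name);
    const auto& e = it->second;
    return mat(base + e[0], e[1], e[2]);  // copies (params are small)
  }
  vec getv(const std::string& name) const {
    mat m = get(name);
    return vec(m.memptr(), m.n_elem);
  }
  void add_grad(NumericVector& out, const std::string& name, const mat& g) const {
    const auto& e = entries.at(name);
    double* dst = REAL(out) + e[0];
    const double* src = g.memptr();
    for (arma::uword i = 0; i < g.n_elem; ++i) dst[i] += src[i];
  }
};

struct GruP {
  mat Wz, Uz, Wr, Ur, Wh, Uh;
  vec bz, br, bh;
};

struct GruG {
  mat Wz, Uz, Wr, Ur, Wh, Uh;
  vec bz, br, bh;
  GruG(int u, int din)
      : Wz(u, din, arma::fill::zeros), Uz(u, u, arma::fill::zeros),
        Wr(u, din, arma::fill::zeros), Ur(u, u, arma::fill::zeros),
        Wh(u, din, arma::fill::zeros), Uh(u, u, arma::fill::zeros),
        bz(u, arma::fill::zeros), br(u, arma::fill::zeros),
        bh(u, arma::fill::zeros) {}
};

GruP load_gru(const ParamTable& P, int level, const char* dir) {
  auto nm = [&](const char* kind, char gate) {
    return std::string(kind) + "_" + gate + std::to_string(level) + dir;
  };
  GruP g;
  g.Wz = P.get(nm("W", 'z')); g.Uz = P.get(nm("U", 'z')); g.bz = P.getv(nm("b", 'z'));
  g.Wr = P.get(nm("W", 'r')); g.Ur = P.get(nm("U", 'r')); g.br = P.getv(nm("b", 'r'));
  g.Wh = P.get(nm("W", 'h')); g.Uh = P.get(nm("U", 'h')); g.bh = P.getv(nm("b", 'h'));
  return g;
}

void store_gru(const ParamTable& P, NumericVector& grad, int level,
               const char* dir, const GruG& g) {
  auto nm = [&](const char* kind, char gate) {
    return std::string(kind) + "_" + gate + std::to_string(level) + dir;
  };
  P.add_grad(grad, nm("W", 'z'), g.Wz); P.add_grad(grad, nm("U", 'z'), g.Uz);
  P.add_grad(grad, nm("b", 'z'), g.bz);
  P.add_grad(grad, nm("W", 'r'), g.Wr); P.add_grad(grad, nm("U", 'r'), g.Ur);
  P.add_grad(grad, nm("b", 'r'), g.br);
  P.add_grad(grad, nm("W", 'h'), g.Wh); P.add_grad(grad, nm("U", 'h'), g.Uh);
  P.add_grad(grad, nm("b", 'h'), g.bh);
}

inline vec sigmoid(const vec& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// Cache for one direction of a GRU run.
struct GruCache {
  std::vector<vec> z, r, hc, hprev;
  std::vector<char> active;
};

// Single-direction GRU over rows of X (T x din); masked rows copy the
// previous hidden state. Returns H (T x u).
mat gru_forward(const mat& X, const std::vector<int>& mask, const GruP& p,
                GruCache& c) {
  const int T = X.n_rows;
  const int u = p.Wz.n_rows;
  mat H(T, u, arma::fill::zeros);
  vec h(u, arma::fill::zeros);
  c.z.assign(T, vec()); c.r.assign(T, vec()); c.hc.assign(T, vec());
  c.hprev.assign(T, vec()); c.active.assign(T, 0);
  for (int t = 0; t < T; ++t) {
    if (!mask[t]) { H.row(t) = h.t(); continue; }
    vec x = X.row(t).t();
    vec z = sigmoid(p.Wz * x + p.Uz * h + p.bz);
    vec r = sigmoid(p.Wr * x + p.Ur * h + p.br);
    vec hc = arma::tanh(p.Wh * x + p.Uh * (r % h) + p.bh);
    c.z[t] = z; c.r[t] = r; c.hc[t] = hc; c.hprev[t] = h; c.active[t] = 1;
    h = (1.0 - z) % h + z % hc;
    H.row(t) = h.t();
  }
  return H;
}

// Backprop one direction. dH (T x u) is the gradient w.r.t. the outputs;
// gradients are accumulated into g and dX.
void gru_backward(const mat& X, const std::vector<int>& mask, const GruP& p,
                  const GruCache& c, const mat& dH, GruG& g, mat& dX) {
  const int T = X.n_rows;
  const int u = p.Wz.n_rows;
  vec dh(u, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    dh += dH.row(t).t();
    if (!c.active[t]) continue;  // h_t == h_{t-1}: gradient passes through
    const vec& z = c.z[t];
    const vec& r = c.r[t];
    const vec& hc = c.hc[t];
    const vec& hp = c.hprev[t];
    vec x = X.row(t).t();

    vec dz = dh % (hc - hp);
    vec dhc = dh % z;
    vec dhp = dh % (1.0 - z);

    vec dah = dhc % (1.0 - hc % hc);
    g.Wh += dah * x.t();
    g.bh += dah;
    vec rh = r % hp;
    g.Uh += dah * rh.t();
    vec drh = p.Uh.t() * dah;
    vec dr = drh % hp;
    dhp += drh % r;

    vec daz = dz % (z % (1.0 - z));
    g.Wz += daz * x.t();
    g.bz += daz;
    g.Uz += daz * hp.t();
    dhp += p.Uz.t() * daz;

    vec dar = dr % (r % (1.0 - r));
    g.Wr += dar * x.t();
    g.br += dar;
    g.Ur += dar * hp.t();
    dhp += p.Ur.t() * dar;

    dX.row(t) += (p.Wz.t() * daz + p.Wr.t() * dar + p.Wh.t() * dah).t();
    dh = dhp;
  }
}

// Bidirectional GRU: H = [forward | backward], each T x u.
struct BiGruCache {
  GruCache fwd, bwd;
  mat Xrev;
  std::vector<int> mask_rev;
};

mat bigru_forward(const mat& X, const std::vector<int>& mask, const GruP& pf,
                  const GruP& pb, BiGruCache& c) {
  const int T = X.n_rows;
  mat Hf = gru_forward(X, mask, pf, c.fwd);
  c.Xrev = arma::flipud(X);
  c.mask_rev.assign(mask.rbegin(), mask.rend());
  mat Hb = gru_forward(c.Xrev, c.mask_rev, pb, c.bwd);
  return arma::join_rows(Hf, arma::flipud(Hb));
}

void bigru_backward(const mat& X, const std::vector<int>& mask, const GruP& pf,
                    const GruP& pb, const BiGruCache& c, const mat& dH,
                    GruG& gf, GruG& gb, mat& dX) {
  const int u = pf.Wz.n_rows;
  mat dHf = dH.cols(0, u - 1);
  mat dHb = arma::flipud(dH.cols(u, 2 * u - 1));
  gru_backward(X, mask, pf, c.fwd, dHf, gf, dX);
  mat dXrev(X.n_rows, X.n_cols, arma::fill::zeros);
  gru_backward(c.Xrev, c.mask_rev, pb, c.bwd, dHb, gb, dXrev);
  dX += arma::flipud(dXrev);
}

// Attention pooling: s_t = u_ctx . tanh(Wa h_t + ba); softmax over
// unmasked positions; v = sum_t alpha_t h_t.
struct AttnCache {
  mat Tnh;   // T x a, tanh activations
  vec alpha; // T
};

vec attn_forward(const mat& H, const mat& Wa, const vec& ba, const vec& uc,
                 const std::vector<int>& mask, AttnCache& c) {
  const int T = H.n_rows;
  const int a = Wa.n_rows;
  c.Tnh.set_size(T, a);
  vec s(T);
  for (int t = 0; t < T; ++t) {
    if (!mask[t]) { s(t) = -arma::datum::inf; c.Tnh.row(t).zeros(); continue; }
    vec th = arma::tanh(Wa * H.row(t).t() + ba);
    c.Tnh.row(t) = th.t();
    s(t) = arma::dot(uc, th);
  }
  double smax = s.max();
  vec e = arma::exp(s - smax);
  for (int t = 0; t < T; ++t) if (!mask[t]) e(t) = 0.0;
  c.alpha = e / arma::accu(e);
  return H.t() * c.alpha;
}

void attn_backward(const mat& H, const mat& Wa, const vec& uc,
                   const std::vector<int>& mask, const AttnCache& c,
                   const vec& dv, mat& dWa, vec& dba, vec& duc, mat& dH) {
  const int T = H.n_rows;
  vec dalpha(T);
  for (int t = 0; t < T; ++t) {
    dalpha(t) = arma::dot(dv, H.row(t).t());
    dH.row(t) += c.alpha(t) * dv.t();
  }
  double inner = arma::dot(c.alpha, dalpha);
  vec ds = c.alpha % (dalpha - inner);
  for (int t = 0; t < T; ++t) {
    if (!mask[t] || ds(t) == 0.0) continue;
    vec th = c.Tnh.row(t).t();
    duc += ds(t) * th;
    vec dpre = ds(t) * (uc % (1.0 - th % th));
    dWa += dpre * H.row(t);
    dba += dpre;
    dH.row(t) += (Wa.t() * dpre).t();
  }
}

std::vector<int> kmer_chunk_sizes(int w, int k) {
  std::vector<int> sizes;
  for (int s = 0; s < w; s += k) sizes.push_back(std::min(k, w - s));
  return sizes;
}

}  // namespace

// Forward (and optionally backward) pass over a batch of window fragments.
//
// theta:  flat parameter vector laid out per the shape table
// shapes: list(name, nrow, ncol, offset) describing theta
// cfg:    list(w, k, u, a, P, E, d_fixed, use_emb, w_pos, clip)
// fixed_list[i]: w x d_fixed window matrix (pad rows zero)
// emb_list[i]:   w x E window embedding matrix (ignored if !use_emb)
// mask_list[i]:  length-w 0/1 pad mask
// labels[i]:     0/1, or negative for "no label" (prediction only)
//
// Returns loss_sum = sum_i c_i * (-log p_{y_i}) over labeled fragments,
// n_labeled, probs (n x 2), grad (d loss_sum / d theta) when want_grad,
// and per-fragment attention traces when want_trace.
// [[Rcpp::export]]
List cpp_han_batch(NumericVector theta, List shapes, List cfg,
                   List fixed_list, List emb_list, List mask_list,
                   IntegerVector labels, bool want_grad, bool want_trace) {
  ParamTable P;
  P.base = REAL(theta);
  {
    CharacterVector nm = shapes["name"];
    IntegerVector nr = shapes["nrow"], nc = shapes["ncol"], off = shapes["offset"];
    for (int i = 0; i < nm.size(); ++i) {
      P.entries[as<std::string>(nm[i])] = {(long)off[i], (long)nr[i], (long)nc[i]};
    }
  }
  const int w = cfg["w"], k = cfg["k"], u = cfg["u"];
  const int d_fixed = cfg["d_fixed"];
  const bool use_emb = cfg["use_emb"];
  const int Pdim = use_emb ? (int)cfg["P"] : 0;
  const int E = use_emb ? (int)cfg["E"] : 0;
  const double w_pos = cfg["w_pos"];
  const double clip = cfg["clip"];
  const int din1 = d_fixed + Pdim;
  const int din2 = 2 * u;

  mat Wp; vec bp;
  if (use_emb) { Wp = P.get("W_proj"); bp = P.getv("b_proj"); }
  GruP g1f = load_gru(P, 1, "f"), g1b = load_gru(P, 1, "b");
  GruP g2f = load_gru(P, 2, "f"), g2b = load_gru(P, 2, "b");
  mat Wa1 = P.get("W_a1"); vec ba1 = P.getv("b_a1"), uc1 = P.getv("u_ctx1");
  mat Wa2 = P.get("W_a2"); vec ba2 = P.getv("b_a2"), uc2 = P.getv("u_ctx2");
  mat Wout = P.get("W_out"); vec bout = P.getv("b_out");

  const int n = fixed_list.size();
  if (emb_list.size() != n || mask_list.size() != n || labels.size() != n) {
    stop("batch components have inconsistent lengths");
  }

  // Gradient accumulators.
  mat gWp; vec gbp;
  if (want_grad && use_emb) {
    gWp.zeros(Pdim, E); gbp.zeros(Pdim);
  }
  GruG G1f(u, din1), G1b(u, din1), G2f(u, din2), G2b(u, din2);
  mat gWa1, gWa2, gWout;
  vec gba1, gba2, guc1, guc2, gbout;
  if (want_grad) {
    gWa1.zeros(Wa1.n_rows, Wa1.n_cols); gba1.zeros(ba1.n_elem); guc1.zeros(uc1.n_elem);
    gWa2.zeros(Wa2.n_rows, Wa2.n_cols); gba2.zeros(ba2.n_elem); guc2.zeros(uc2.n_elem);
    gWout.zeros(2, din2); gbout.zeros(2);
  }

  std::vector<int> sizes = kmer_chunk_sizes(w, k);
  const int m = sizes.size();
  std::vector<int> starts(m);
  for (int j = 0, s = 0; j < m; s += sizes[j], ++j) starts[j] = s;

  NumericMatrix probs(n, 2);
  List traces(want_trace ? n : 0);
  double loss_sum = 0.0;
  int n_labeled = 0;

  for (int i = 0; i < n; ++i) {
    NumericMatrix fixed_r = fixed_list[i];
    mat Xf(REAL(fixed_r), fixed_r.nrow(), fixed_r.ncol());
    IntegerVector mask_r = mask_list[i];
    if ((int)Xf.n_rows != w || (int)Xf.n_cols != d_fixed || mask_r.size() != w) {
      stop("fragment %d: window matrix/mask shape mismatch", i + 1);
    }
    std::vector<int> mask(mask_r.begin(), mask_r.end());
    mat Xe;
    if (use_emb) {
      NumericMatrix emb_r = emb_list[i];
      if (emb_r.nrow() != w || emb_r.ncol() != E) {
        stop("fragment %d: embedding window must be w x E", i + 1);
      }
      Xe = mat(REAL(emb_r), w, E);
    }

    // Fused input rows; pad rows stay zero.
    mat X(w, din1, arma::fill::zeros);
    mat proj_pre;  // w x P pre-activations for the relu backward
    if (use_emb) proj_pre.zeros(w, Pdim);
    for (int t = 0; t < w; ++t) {
      if (!mask[t]) continue;
      if (d_fixed > 0) X(t, arma::span(0, d_fixed - 1)) = Xf.row(t);
      if (use_emb) {
        vec pre = Wp * Xe.row(t).t() + bp;
        proj_pre.row(t) = pre.t();
        X(t, arma::span(d_fixed, din1 - 1)) = arma::clamp(pre, 0.0, arma::datum::inf).t();
      }
    }

    // Level 1: per-K-mer Bi-GRU + attention.
    std::vector<BiGruCache> bc1(m);
    std::vector<AttnCache> ac1(m);
    std::vector<mat> H1(m), Xsub(m);
    std::vector<std::vector<int>> msub(m);
    mat V(m, din2, arma::fill::zeros);
    std::vector<int> kmask(m, 0);
    for (int j = 0; j < m; ++j) {
      Xsub[j] = X.rows(starts[j], starts[j] + sizes[j] - 1);
      msub[j].assign(mask.begin() + starts[j], mask.begin() + starts[j] + sizes[j]);
      bool any = false;
      for (int v : msub[j]) any = any || (v != 0);
      if (!any) { ac1[j].alpha.zeros(sizes[j]); continue; }
      kmask[j] = 1;
      H1[j] = bigru_forward(Xsub[j], msub[j], g1f, g1b, bc1[j]);
      V.row(j) = attn_forward(H1[j], Wa1, ba1, uc1, msub[j], ac1[j]).t();
    }

    // Level 2: Bi-GRU + attention over K-mer vectors.
    BiGruCache bc2;
    AttnCache ac2;
    mat H2 = bigru_forward(V, kmask, g2f, g2b, bc2);
    vec d = attn_forward(H2, Wa2, ba2, uc2, kmask, ac2);

    vec logits = Wout * d + bout;
    double lmax = logits.max();
    vec ex = arma::exp(logits - lmax);
    vec p = ex / arma::accu(ex);
    probs(i, 0) = p(0);
    probs(i, 1) = p(1);

    if (want_trace) {
      List rw(m);
      for (int j = 0; j < m; ++j) {
        rw[j] = NumericVector(ac1[j].alpha.begin(), ac1[j].alpha.end());
      }
      traces[i] = List::create(
        _["kmer_weights"] = NumericVector(ac2.alpha.begin(), ac2.alpha.end()),
        _["residue_weights"] = rw);
    }

    int y = labels[i];
    if (y < 0) continue;
    double cw = (y == 1) ? w_pos : 1.0;
    double py = std::max(p(y), clip);
    loss_sum += -cw * std::log(py);
    ++n_labeled;

    if (!want_grad) continue;

    // Backward.
    vec dlogits = p;
    dlogits(y) -= 1.0;
    dlogits *= cw;
    gWout += dlogits * d.t();
    gbout += dlogits;
    vec dd = Wout.t() * dlogits;

    mat dH2(m, din2, arma::fill::zeros);
    attn_backward(H2, Wa2, uc2, kmask, ac2, dd, gWa2, gba2, guc2, dH2);
    mat dV(m, din2, arma::fill::zeros);
    bigru_backward(V, kmask, g2f, g2b, bc2, dH2, G2f, G2b, dV);

    mat dX(w, din1, arma::fill::zeros);
    for (int j = 0; j < m; ++j) {
      if (!kmask[j]) continue;
      vec dvj = dV.row(j).t();
      mat dHj(sizes[j], din2, arma::fill::zeros);
      attn_backward(H1[j], Wa1, uc1, msub[j], ac1[j], dvj, gWa1, gba1, guc1, dHj);
      mat dXj(sizes[j], din1, arma::fill::zeros);
      bigru_backward(Xsub[j], msub[j], g1f, g1b, bc1[j], dHj, G1f, G1b, dXj);
      dX.rows(starts[j], starts[j] + sizes[j] - 1) += dXj;
    }

    if (use_emb) {
      for (int t = 0; t < w; ++t) {
        if (!mask[t]) continue;
        vec dproj = dX(t, arma::span(d_fixed, din1 - 1)).t();
        vec pre = proj_pre.row(t).t();
        vec dpre = dproj % arma::conv_to<vec>::from(pre > 0.0);
        gWp += dpre * Xe.row(t);
        gbp += dpre;
      }
    }
  }

  List out = List::create(
    _["loss_sum"] = loss_sum,
    _["n_labeled"] = n_labeled,
    _["probs"] = probs);

  if (want_grad) {
    NumericVector grad(theta.size());
    if (use_emb) { P.add_grad(grad, "W_proj", gWp); P.add_grad(grad, "b_proj", gbp); }
    store_gru(P, grad, 1, "f", G1f); store_gru(P, grad, 1, "b", G1b);
    store_gru(P, grad, 2, "f", G2f); store_gru(P, grad, 2, "b", G2b);
    P.add_grad(grad, "W_a1", gWa1); P.add_grad(grad, "b_a1", gba1);
    P.add_grad(grad, "u_ctx1", guc1);
    P.add_grad(grad, "W_a2", gWa2); P.add_grad(grad, "b_a2", gba2);
    P.add_grad(grad, "u_ctx2", guc2);
    P.add_grad(grad, "W_out", gWout); P.add_grad(grad, "b_out", gbout);
    out["grad"] = grad;
  }
  if (want_trace) out["traces"] = traces;
  return out;
}
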