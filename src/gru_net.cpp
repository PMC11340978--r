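// Bidirectional GRU sequence classifier with self-attentive pooling and a
// fully connected ordinal head. Forward pass and analytic backpropagation
// (verified against finite differences in the test suite).
//
// Shapes: the feature input is a cube (B x D x T): B recordings, D=39
// frequency bins per frame, T frames. Gate weight matrices stack the
// reset/update/candidate blocks row-wise: Wx is (3H x D), Wh is (3H x H).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::rowvec;
using arma::vec;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct GruDir {
  mat Wx, Wh;
  rowvec bx, bh;
};

struct DirCache {
  cube R, Z, N, HP, H;  // gates, candidate pre-reset term, hidden states
};

struct NetParams {
  std::vector<GruDir> fwd, bwd;
  mat Wa;      // attention projection (A x 2H)
  rowvec ba;   // attention projection bias
  vec va;      // attention score vector (A)
  std::vector<mat> Wh_head;
  std::vector<rowvec> bh_head;
};

static GruDir parse_dir(const List& l) {
  GruDir d;
  d.Wx = as<mat>(l["Wx"]);
  d.Wh = as<mat>(l["Wh"]);
  d.bx = as<rowvec>(l["bx"]);
  d.bh = as<rowvec>(l["bh"]);
  return d;
}

static NetParams parse_params(const List& params) {
  NetParams p;
  List layers = params["layers"];
  for (int l = 0; l < layers.size(); ++l) {
    List lay = layers[l];
    p.fwd.push_back(parse_dir(lay["fwd"]));
    p.bwd.push_back(parse_dir(lay["bwd"]));
  }
  List attn = params["attn"];
  p.Wa = as<mat>(attn["W"]);
  p.ba = as<rowvec>(attn["b"]);
  p.va = as<vec>(attn["v"]);
  List head = params["head"];
  for (int k = 0; k < head.size(); ++k) {
    List hk = head[k];
    p.Wh_head.push_back(as<mat>(hk["W"]));
    p.bh_head.push_back(as<rowvec>(hk["b"]));
  }
  return p;
}

// Stack the time slices of a (B x D x T) cube into a (B*T x D) matrix so
// the input-side gate projections run as one large matrix product.
static mat stack_slices(const cube& X) {
  const arma::uword B = X.n_rows, D = X.n_cols, T = X.n_slices;
  mat out(B * T, D);
  for (arma::uword t = 0; t < T; ++t) out.rows(t * B, t * B + B - 1) = X.slice(t);
  return out;
}

// One GRU direction over the full sequence. rev=true iterates last->first.
static void dir_forward(const cube& X, const GruDir& P, bool rev, DirCache& C) {
  const arma::uword B = X.n_rows, T = X.n_slices;
  const arma::uword H = P.Wh.n_cols;
  C.R.set_size(B, H, T); C.Z.set_size(B, H, T); C.N.set_size(B, H, T);
  C.HP.set_size(B, H, T); C.H.set_size(B, H, T);
  mat PXall = stack_slices(X) * P.Wx.t();
  PXall.each_row() += P.bx;
  mat hprev(B, H, arma::fill::zeros);
  for (arma::uword s = 0; s < T; ++s) {
    arma::uword t = rev ? T - 1 - s : s;
    mat prex = PXall.rows(t * B, t * B + B - 1);
    mat preh = hprev * P.Wh.t();
    preh.each_row() += P.bh;
    mat r = sigm(prex.cols(0, H - 1) + preh.cols(0, H - 1));
    mat z = sigm(prex.cols(H, 2 * H - 1) + preh.cols(H, 2 * H - 1));
    mat hp = preh.cols(2 * H, 3 * H - 1);
    mat n = arma::tanh(prex.cols(2 * H, 3 * H - 1) + r % hp);
    mat h = (1.0 - z) % n + z % hprev;
    C.R.slice(t) = r; C.Z.slice(t) = z; C.N.slice(t) = n;
    C.HP.slice(t) = hp; C.H.slice(t) = h;
    hprev = h;
  }
}

// Backpropagation through one direction. dHout carries dLoss/dh_t from the
// layers above; gradients accumulate into dWx/dWh/dbx/dbh/dX.
static void dir_backward(const cube& X, const GruDir& P, bool rev,
                         const DirCache& C, const cube& dHout,
                         mat& dWx, mat& dWh, rowvec& dbx, rowvec& dbh,
                         cube& dX) {
  const arma::uword B = X.n_rows, T = X.n_slices;
  const arma::uword H = P.Wh.n_cols;
  mat carry(B, H, arma::fill::zeros);
  mat dGall(B * T, 3 * H);
  for (arma::uword s = T; s-- > 0;) {
    arma::uword t = rev ? T - 1 - s : s;
    mat hprev;
    if (s == 0) {
      hprev.zeros(B, H);
    } else {
      arma::uword tprev = rev ? T - s : s - 1;
      hprev = C.H.slice(tprev);
    }
    mat dh = dHout.slice(t) + carry;
    const mat& r = C.R.slice(t);
    const mat& z = C.Z.slice(t);
    const mat& n = C.N.slice(t);
    const mat& hp = C.HP.slice(t);
    mat dz = dh % (hprev - n) % z % (1.0 - z);
    mat dn = dh % (1.0 - z) % (1.0 - n % n);
    mat dhp = dn % r;
    mat dr = dn % hp % r % (1.0 - r);
    mat dGh = arma::join_rows(dr, arma::join_rows(dz, dhp));
    dGall.rows(t * B, t * B + B - 1) = arma::join_rows(dr, arma::join_rows(dz, dn));
    dWh += dGh.t() * hprev;
    dbh += arma::sum(dGh, 0);
    carry = dh % z + dGh * P.Wh;
  }
  mat Xall = stack_slices(X);
  dWx += dGall.t() * Xall;
  dbx += arma::sum(dGall, 0);
  mat dXall = dGall * P.Wx;
  for (arma::uword t = 0; t < T; ++t) {
    dX.slice(t) += dXall.rows(t * B, t * B + B - 1);
  }
}

struct ForwardCache {
  std::vector<cube> layer_in;           // input cube per layer (post-dropout)
  std::vector<DirCache> fwd, bwd;
  std::vector<cube> hcat;               // (B x 2H x T) per layer
  std::vector<cube> drop_mask;          // between-layer dropout (scaled 0 / 1/(1-p))
  cube U;                               // attention tanh activations (B x A x T)
  mat S, W;                             // attention scores / softmax weights (B x T)
  mat pooled;                           // (B x 2H)
  std::vector<mat> head_in;             // input to each head layer
  std::vector<mat> head_pre;            // pre-activations of hidden head layers
  std::vector<mat> head_mask;           // head dropout masks
  mat logits;                           // (B x 4)
};

static void net_forward_impl(const NetParams& P, const cube& x,
                             double dropout_p, bool training,
                             std::mt19937_64& rng, ForwardCache& C) {
  const arma::uword B = x.n_rows, T = x.n_slices;
  const arma::uword L = P.fwd.size();
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const bool use_drop = training && dropout_p > 0.0;
  const double keep_scale = use_drop ? 1.0 / (1.0 - dropout_p) : 1.0;

  cube cur = x;
  for (arma::uword l = 0; l < L; ++l) {
    C.layer_in.push_back(cur);
    DirCache cf, cb;
    dir_forward(cur, P.fwd[l], false, cf);
    dir_forward(cur, P.bwd[l], true, cb);
    const arma::uword H = P.fwd[l].Wh.n_cols;
    cube hc(B, 2 * H, T);
    for (arma::uword t = 0; t < T; ++t) {
      hc.slice(t) = arma::join_rows(cf.H.slice(t), cb.H.slice(t));
    }
    C.fwd.push_back(cf);
    C.bwd.push_back(cb);
    C.hcat.push_back(hc);
    if (l + 1 < L) {
      cube nxt = hc;
      if (use_drop) {
        cube msk(B, 2 * H, T);
        for (arma::uword i = 0; i < msk.n_elem; ++i) {
          msk(i) = (unif(rng) >= dropout_p) ? keep_scale : 0.0;
        }
        C.drop_mask.push_back(msk);
        nxt %= msk;
      } else {
        C.drop_mask.push_back(cube());
      }
      cur = nxt;
    }
  }

  // self-attentive pooling over the top layer's concatenated hidden states
  const cube& top = C.hcat.back();
  const arma::uword D2 = top.n_cols;
  const arma::uword A = P.Wa.n_rows;
  C.U.set_size(B, A, T);
  C.S.set_size(B, T);
  for (arma::uword t = 0; t < T; ++t) {
    mat u = top.slice(t) * P.Wa.t();
    u.each_row() += P.ba;
    u = arma::tanh(u);
    C.U.slice(t) = u;
    C.S.col(t) = u * P.va;
  }
  mat Sm = C.S;
  Sm.each_col() -= arma::max(Sm, 1);
  mat W = arma::exp(Sm);
  W.each_col() /= arma::sum(W, 1);
  C.W = W;
  C.pooled.zeros(B, D2);
  for (arma::uword t = 0; t < T; ++t) {
    mat tmp = top.slice(t);
    tmp.each_col() %= W.col(t);
    C.pooled += tmp;
  }

  // fully connected head: ReLU hidden layers, 4 linear outputs
  mat a = C.pooled;
  const arma::uword K = P.Wh_head.size();
  for (arma::uword k = 0; k < K; ++k) {
    C.head_in.push_back(a);
    mat zk = a * P.Wh_head[k].t();
    zk.each_row() += P.bh_head[k];
    if (k + 1 < K) {
      C.head_pre.push_back(zk);
      a = arma::clamp(zk, 0.0, arma::datum::inf);
      if (use_drop) {
        mat msk(a.n_rows, a.n_cols);
        for (arma::uword i = 0; i < msk.n_elem; ++i) {
          msk(i) = (unif(rng) >= dropout_p) ? keep_scale : 0.0;
        }
        C.head_mask.push_back(msk);
        a %= msk;
      } else {
        C.head_mask.push_back(mat());
      }
    } else {
      C.logits = zk;
    }
  }
}

// [[Rcpp::export]]
List cpp_net_forward(List params, arma::cube x, bool return_hidden = false) {
  NetParams P = parse_params(params);
  std::mt19937_64 rng(0);
  ForwardCache C;
  net_forward_impl(P, x, 0.0, false, rng, C);
  List out = List::create(
    _["logits"] = C.logits,
    _["probs"] = sigm(C.logits),
    _["attention"] = C.W,
    _["pooled"] = C.pooled);
  if (return_hidden) out["hidden"] = C.hcat.back();
  return out;
}

// [[Rcpp::export]]
List cpp_net_loss_grad(List params, arma::cube x, arma::mat targets,
                       double dropout_p, int seed) {
  NetParams P = parse_params(params);
  std::mt19937_64 rng(static_cast<unsigned long long>(seed));
  ForwardCache C;
  net_forward_impl(P, x, dropout_p, true, rng, C);
  const arma::uword B = x.n_rows, T = x.n_slices;
  const arma::uword L = P.fwd.size();
  const arma::uword K = P.Wh_head.size();

  // stabilised binary cross-entropy with logits, averaged over B x 4
  const mat& lg = C.logits;
  mat per = arma::clamp(lg, 0.0, arma::datum::inf) - lg % targets +
            arma::log1p(arma::exp(-arma::abs(lg)));
  double loss = arma::accu(per) / per.n_elem;

  // ---- backward ----
  mat dz = (sigm(lg) - targets) / double(per.n_elem);

  std::vector<mat> dW_head(K);
  std::vector<rowvec> db_head(K);
  for (arma::uword k = K; k-- > 0;) {
    dW_head[k] = dz.t() * C.head_in[k];
    db_head[k] = arma::sum(dz, 0);
    mat da = dz * P.Wh_head[k];
    if (k > 0) {
      if (C.head_mask[k - 1].n_elem > 0) da %= C.head_mask[k - 1];
      dz = da % arma::conv_to<mat>::from(C.head_pre[k - 1] > 0.0);
    } else {
      dz = da;  // d pooled
    }
  }
  mat dpooled = dz;

  // attention backward
  const cube& top = C.hcat.back();
  const arma::uword A = P.Wa.n_rows;
  cube dtop(B, top.n_cols, T, arma::fill::zeros);
  mat dw(B, T);
  for (arma::uword t = 0; t < T; ++t) {
    dw.col(t) = arma::sum(dpooled % top.slice(t), 1);
    mat tmp = dpooled;
    tmp.each_col() %= C.W.col(t);
    dtop.slice(t) += tmp;
  }
  vec rs = arma::sum(dw % C.W, 1);
  mat dS = C.W % (dw.each_col() - rs);
  mat dWa(A, top.n_cols, arma::fill::zeros);
  rowvec dba(A, arma::fill::zeros);
  vec dva(A, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t) {
    const mat& u = C.U.slice(t);
    dva += u.t() * dS.col(t);
    mat du = (dS.col(t) * P.va.t()) % (1.0 - u % u);
    dWa += du.t() * top.slice(t);
    dba += arma::sum(du, 0);
    dtop.slice(t) += du * P.Wa;
  }

  // recurrent layers, top down
  std::vector<mat> dWx_f(L), dWh_f(L), dWx_b(L), dWh_b(L);
  std::vector<rowvec> dbx_f(L), dbh_f(L), dbx_b(L), dbh_b(L);
  cube dout = dtop;
  for (arma::uword l = L; l-- > 0;) {
    const arma::uword H = P.fwd[l].Wh.n_cols;
    cube dHf(B, H, T), dHb(B, H, T);
    for (arma::uword t = 0; t < T; ++t) {
      dHf.slice(t) = dout.slice(t).cols(0, H - 1);
      dHb.slice(t) = dout.slice(t).cols(H, 2 * H - 1);
    }
    const cube& Xl = C.layer_in[l];
    dWx_f[l].zeros(P.fwd[l].Wx.n_rows, P.fwd[l].Wx.n_cols);
    dWh_f[l].zeros(P.fwd[l].Wh.n_rows, P.fwd[l].Wh.n_cols);
    dbx_f[l].zeros(P.fwd[l].bx.n_elem);
    dbh_f[l].zeros(P.fwd[l].bh.n_elem);
    dWx_b[l].zeros(P.bwd[l].Wx.n_rows, P.bwd[l].Wx.n_cols);
    dWh_b[l].zeros(P.bwd[l].Wh.n_rows, P.bwd[l].Wh.n_cols);
    dbx_b[l].zeros(P.bwd[l].bx.n_elem);
    dbh_b[l].zeros(P.bwd[l].bh.n_elem);
    cube dX(B, Xl.n_cols, T, arma::fill::zeros);
    dir_backward(Xl, P.fwd[l], false, C.fwd[l], dHf,
                 dWx_f[l], dWh_f[l], dbx_f[l], dbh_f[l], dX);
    dir_backward(Xl, P.bwd[l], true, C.bwd[l], dHb,
                 dWx_b[l], dWh_b[l], dbx_b[l], dbh_b[l], dX);
    if (l > 0) {
      if (C.drop_mask[l - 1].n_elem > 0) dX %= C.drop_mask[l - 1];
      dout = dX;
    }
  }

  // assemble gradient list mirroring the parameter structure
  List glayers(L);
  for (arma::uword l = 0; l < L; ++l) {
    glayers[l] = List::create(
      _["fwd"] = List::create(_["Wx"] = dWx_f[l], _["Wh"] = dWh_f[l],
                              _["bx"] = dbx_f[l], _["bh"] = dbh_f[l]),
      _["bwd"] = List::create(_["Wx"] = dWx_b[l], _["Wh"] = dWh_b[l],
                              _["bx"] = dbx_b[l], _["bh"] = dbh_b[l]));
  }
  List ghead(K);
  for (arma::uword k = 0; k < K; ++k) {
    ghead[k] = List::create(_["W"] = dW_head[k], _["b"] = db_head[k]);
  }
  List grads = List::create(
    _["layers"] = glayers,
    _["attn"] = List::create(_["W"] = dWa, _["b"] = dba, _["v"] = dva),
    _["head"] = ghead);
  return List::create(_["loss"] = loss, _["grads"] = grads);
}
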