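// Bidirectional LSTM sequence labeler and MLP sample classifier.
// Implemented directly (full BPTT, Adam / SGD) because the per-sample
// motor-intent detectors are the core of this package; everything is
// deterministic given the seed argument (own mt19937_64, no R RNG).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>

using namespace arma;

namespace {

// ---------------------------------------------------------------- utilities

// Glorot-uniform init, seeded.
mat glorot(unsigned int nr, unsigned int nc, std::mt19937_64& rng) {
  double r = std::sqrt(6.0 / (double)(nr + nc));
  std::uniform_real_distribution<double> unif(-r, r);
  mat W(nr, nc);
  for (uword j = 0; j < nc; ++j)
    for (uword i = 0; i < nr; ++i) W(i, j) = unif(rng);
  return W;
}

inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// Column-wise 2-class softmax probabilities of class 1, numerically stable.
inline mat softmax2(const mat& logits) {
  mat z = logits.each_row() - max(logits, 0);
  mat e = exp(z);
  return e.each_row() / sum(e, 0);
}

struct Adam {
  double lr, b1, b2, eps;
  int t = 0;
  std::vector<mat> m, v;
  Adam(double lr_, double b1_, double b2_, double eps_) :
    lr(lr_), b1(b1_), b2(b2_), eps(eps_) {}
  void init(const std::vector<mat*>& params) {
    for (auto* p : params) { m.push_back(zeros(size(*p))); v.push_back(zeros(size(*p))); }
  }
  void step(std::vector<mat*>& params, std::vector<mat*>& grads) {
    ++t;
    double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
    for (size_t k = 0; k < params.size(); ++k) {
      m[k] = b1 * m[k] + (1.0 - b1) * (*grads[k]);
      v[k] = b2 * v[k] + (1.0 - b2) * square(*grads[k]);
      *params[k] -= lr * (m[k] / c1) / (sqrt(v[k] / c2) + eps);
    }
  }
};

// Clip the global gradient norm to `clip` (no-op if clip <= 0).
void clip_global(std::vector<mat*>& grads, double clip) {
  if (clip <= 0) return;
  double ss = 0;
  for (auto* g : grads) ss += accu(square(*g));
  double nrm = std::sqrt(ss);
  if (nrm > clip) for (auto* g : grads) (*g) *= clip / nrm;
}

// ------------------------------------------------------------ LSTM direction

// One direction of a (bi)LSTM layer. Gate order in the stacked 4H rows:
// input i, forget f, cell g, output o.
struct LstmDir {
  mat W;   // 4H x D
  mat R;   // 4H x H
  vec b;   // 4H
  uword H() const { return R.n_cols; }
};

struct LstmCache {
  // per-timestep activations for BPTT; each cube slice is (H x B)
  cube I, F, G, O, C, Hh, Tc;   // gates, cell state, hidden, tanh(C)
};

// Forward over a batch cube X (D x B x T); reverse=true walks time backwards.
// Hidden states are stored at the slice index of the *input* timestep, so
// caller indexing is direction-agnostic.
void lstm_forward_dir(const LstmDir& L, const cube& X, bool reverse,
                      LstmCache* cache, cube& Hout) {
  uword D = X.n_rows, B = X.n_cols, T = X.n_slices, H = L.H();
  (void)D;
  mat h(H, B, fill::zeros), c(H, B, fill::zeros);
  if (cache) {
    cache->I.set_size(H, B, T); cache->F.set_size(H, B, T);
    cache->G.set_size(H, B, T); cache->O.set_size(H, B, T);
    cache->C.set_size(H, B, T); cache->Hh.set_size(H, B, T);
    cache->Tc.set_size(H, B, T);
  }
  Hout.set_size(H, B, T);
  for (uword s = 0; s < T; ++s) {
    uword t = reverse ? (T - 1 - s) : s;
    mat Z = L.W * X.slice(t) + L.R * h;
    Z.each_col() += L.b;
    mat i = sigmoid(Z.rows(0, H - 1));
    mat f = sigmoid(Z.rows(H, 2 * H - 1));
    mat g = tanh(Z.rows(2 * H, 3 * H - 1));
    mat o = sigmoid(Z.rows(3 * H, 4 * H - 1));
    c = f % c + i % g;
    mat tc = tanh(c);
    h = o % tc;
    Hout.slice(t) = h;
    if (cache) {
      cache->I.slice(t) = i; cache->F.slice(t) = f; cache->G.slice(t) = g;
      cache->O.slice(t) = o; cache->C.slice(t) = c; cache->Hh.slice(t) = h;
      cache->Tc.slice(t) = tc;
    }
  }
}

// BPTT for one direction. dH is dLoss/dHout (H x B x T). Accumulates
// parameter gradients; input gradients are not needed (single layer stacks
// are trained on precomputed features).
void lstm_backward_dir(const LstmDir& L, const cube& X, bool reverse,
                       const LstmCache& cc, const cube& dH,
                       mat& dW, mat& dR, vec& db) {
  uword B = X.n_cols, T = X.n_slices, H = L.H();
  dW.zeros(size(L.W)); dR.zeros(size(L.R)); db.zeros(4 * H);
  mat dh_next(H, B, fill::zeros), dc(H, B, fill::zeros);
  for (uword s = 0; s < T; ++s) {
    // walk time in the reverse of the forward order
    uword t = reverse ? s : (T - 1 - s);
    mat dh = dH.slice(t) + dh_next;
    const mat& i = cc.I.slice(t); const mat& f = cc.F.slice(t);
    const mat& g = cc.G.slice(t); const mat& o = cc.O.slice(t);
    const mat& tc = cc.Tc.slice(t);
    mat do_gate = dh % tc;
    dc += dh % o % (1.0 - square(tc));
    // previous cell state in the forward order
    uword tprev = reverse ? t + 1 : t - 1;
    bool has_prev = reverse ? (t + 1 < T) : (t > 0);
    mat cprev = has_prev ? cc.C.slice(tprev) : mat(H, B, fill::zeros);
    mat di = dc % g, dg = dc % i, df = dc % cprev;
    mat dc_prev = dc % f;
    mat dZ(4 * H, B);
    dZ.rows(0, H - 1)         = di % i % (1.0 - i);
    dZ.rows(H, 2 * H - 1)     = df % f % (1.0 - f);
    dZ.rows(2 * H, 3 * H - 1) = dg % (1.0 - square(g));
    dZ.rows(3 * H, 4 * H - 1) = do_gate % o % (1.0 - o);
    dW += dZ * X.slice(t).t();
    mat hprev = has_prev ? cc.Hh.slice(tprev) : mat(H, B, fill::zeros);
    dR += dZ * hprev.t();
    db += sum(dZ, 1);
    dh_next = L.R.t() * dZ;
    dc = dc_prev;
  }
}

LstmDir dir_from_list(const Rcpp::List& l) {
  LstmDir d;
  d.W = Rcpp::as<mat>(l["W"]); d.R = Rcpp::as<mat>(l["R"]);
  d.b = Rcpp::as<vec>(l["b"]);
  return d;
}

Rcpp::List dir_to_list(const LstmDir& d) {
  return Rcpp::List::create(Rcpp::Named("W") = d.W, Rcpp::Named("R") = d.R,
                            Rcpp::Named("b") = d.b);
}

struct BiLstmNet {
  LstmDir fwd, bwd;
  mat V;   // 2 x 2H readout
  vec d;   // 2
};

BiLstmNet net_from_list(const Rcpp::List& l) {
  BiLstmNet n;
  n.fwd = dir_from_list(l["fwd"]); n.bwd = dir_from_list(l["bwd"]);
  n.V = Rcpp::as<mat>(l["V"]); n.d = Rcpp::as<vec>(l["d"]);
  return n;
}

Rcpp::List net_to_list(const BiLstmNet& n) {
  return Rcpp::List::create(Rcpp::Named("fwd") = dir_to_list(n.fwd),
                            Rcpp::Named("bwd") = dir_to_list(n.bwd),
                            Rcpp::Named("V") = n.V, Rcpp::Named("d") = n.d);
}

// Gather minibatch columns of a (D x N x T) cube into (D x B x T).
cube gather(const cube& X, const uvec& idx) {
  cube Xb(X.n_rows, idx.n_elem, X.n_slices);
  for (uword t = 0; t < X.n_slices; ++t) Xb.slice(t) = X.slice(t).cols(idx);
  return Xb;
}

} // namespace

// --------------------------------------------------------------- R interface

// [[Rcpp::export(name = ".cpp_bilstm_init")]]
Rcpp::List cpp_bilstm_init(int input_dim, int hidden, int seed) {
  std::mt19937_64 rng((uint64_t)seed);
  BiLstmNet n;
  auto make_dir = [&](void) {
    LstmDir d;
    d.W = glorot(4 * hidden, input_dim, rng);
    d.R = glorot(4 * hidden, hidden, rng);
    d.b = zeros<vec>(4 * hidden);
    d.b.subvec(hidden, 2 * hidden - 1).fill(1.0);   // forget-gate bias
    return d;
  };
  n.fwd = make_dir();
  n.bwd = make_dir();
  n.V = glorot(2, 2 * hidden, rng);
  n.d = zeros<vec>(2);
  return net_to_list(n);
}

// Train a BiLSTM sequence labeler.
//   X: cube (D x N x T); Y: integer matrix (T x N) with 0/1 labels, -1 = unlabeled.
// Loss: per-sample softmax cross-entropy over labeled samples, Adam optimizer.
// [[Rcpp::export(name = ".cpp_bilstm_train")]]
Rcpp::List cpp_bilstm_train(arma::cube X, arma::imat Y, Rcpp::List init,
                            int epochs, int batch, int seed,
                            double lr, double beta1, double beta2,
                            double grad_clip, bool sgd = false) {
  BiLstmNet net = net_from_list(init);
  uword N = X.n_cols, T = X.n_slices, H = net.fwd.H();
  if ((uword)Y.n_rows != T || (uword)Y.n_cols != N)
    Rcpp::stop("label matrix must be T x N");
  std::mt19937_64 rng((uint64_t)seed + 0x9e3779b97f4a7c15ULL);
  Adam opt(lr, beta1, beta2, 1e-8);
  std::vector<mat*> params = {&net.fwd.W, &net.fwd.R, (mat*)nullptr,
                              &net.bwd.W, &net.bwd.R, (mat*)nullptr,
                              &net.V, (mat*)nullptr};
  // Adam state works on mats; wrap the bias vectors as mats
  mat bf(net.fwd.b), bb(net.bwd.b), bd(net.d);
  params[2] = &bf; params[5] = &bb; params[7] = &bd;
  opt.init(params);
  std::vector<double> loss_hist;
  std::vector<uword> order(N);
  for (uword i = 0; i < N; ++i) order[i] = i;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0; uword ep_n = 0;
    for (uword start = 0; start < N; start += (uword)batch) {
      uword stop = std::min<uword>(start + batch, N);
      uvec idx(stop - start);
      for (uword k = 0; k < idx.n_elem; ++k) idx[k] = order[start + k];
      cube Xb = gather(X, idx);
      uword B = idx.n_elem;
      net.fwd.b = bf.col(0); net.bwd.b = bb.col(0); net.d = bd.col(0);
      LstmCache cf, cb;
      cube Hf, Hb;
      lstm_forward_dir(net.fwd, Xb, false, &cf, Hf);
      lstm_forward_dir(net.bwd, Xb, true,  &cb, Hb);
      // readout + masked cross-entropy
      cube dHf(H, B, T, fill::zeros), dHb(H, B, T, fill::zeros);
      mat dV(2, 2 * H, fill::zeros); vec dd(2, fill::zeros);
      // count labeled samples in batch for loss normalization
      uword n_lab = 0;
      for (uword k = 0; k < B; ++k)
        for (uword t = 0; t < T; ++t) if (Y(t, idx[k]) >= 0) ++n_lab;
      if (n_lab == 0) continue;
      double loss = 0;
      for (uword t = 0; t < T; ++t) {
        mat U = join_cols(Hf.slice(t), Hb.slice(t));   // 2H x B
        mat logits = net.V * U; logits.each_col() += net.d;
        mat P = softmax2(logits);                      // 2 x B
        mat dLog(2, B, fill::zeros);
        for (uword k = 0; k < B; ++k) {
          int y = Y(t, idx[k]);
          if (y < 0) continue;
          loss -= std::log(std::max(P(y, k), 1e-12));
          dLog.col(k) = P.col(k);
          dLog(y, k) -= 1.0;
        }
        dLog /= (double)n_lab;
        dV += dLog * U.t(); dd += sum(dLog, 1);
        mat dU = net.V.t() * dLog;                     // 2H x B
        dHf.slice(t) = dU.rows(0, H - 1);
        dHb.slice(t) = dU.rows(H, 2 * H - 1);
      }
      ep_loss += loss; ep_n += n_lab;
      mat dWf, dRf, dWb, dRb; vec dbf, dbb;
      lstm_backward_dir(net.fwd, Xb, false, cf, dHf, dWf, dRf, dbf);
      lstm_backward_dir(net.bwd, Xb, true,  cb, dHb, dWb, dRb, dbb);
      mat mbf(dbf), mbb(dbb), mdd(dd);
      std::vector<mat*> grads = {&dWf, &dRf, &mbf, &dWb, &dRb, &mbb, &dV, &mdd};
      clip_global(grads, grad_clip);
      if (sgd) {
        for (size_t k = 0; k < params.size(); ++k) *params[k] -= lr * (*grads[k]);
      } else {
        opt.step(params, grads);
      }
    }
    loss_hist.push_back(ep_n ? ep_loss / ep_n : NA_REAL);
    Rcpp::checkUserInterrupt();
  }
  net.fwd.b = bf.col(0); net.bwd.b = bb.col(0); net.d = bd.col(0);
  return Rcpp::List::create(Rcpp::Named("params") = net_to_list(net),
                            Rcpp::Named("loss") = loss_hist);
}

// Per-sample class-1 probabilities for each sequence: returns (T x N) matrix.
// [[Rcpp::export(name = ".cpp_bilstm_prob")]]
arma::mat cpp_bilstm_prob(Rcpp::List params, arma::cube X) {
  BiLstmNet net = net_from_list(params);
  uword N = X.n_cols, T = X.n_slices;
  cube Hf, Hb;
  lstm_forward_dir(net.fwd, X, false, nullptr, Hf);
  lstm_forward_dir(net.bwd, X, true,  nullptr, Hb);
  mat out(T, N);
  for (uword t = 0; t < T; ++t) {
    mat U = join_cols(Hf.slice(t), Hb.slice(t));
    mat logits = net.V * U; logits.each_col() += net.d;
    out.row(t) = softmax2(logits).row(1);
  }
  return out;
}

// Concatenated bidirectional hidden states (features for a stacked layer):
// returns cube (2H x N x T).
// [[Rcpp::export(name = ".cpp_bilstm_hidden")]]
arma::cube cpp_bilstm_hidden(Rcpp::List params, arma::cube X) {
  BiLstmNet net = net_from_list(params);
  cube Hf, Hb;
  lstm_forward_dir(net.fwd, X, false, nullptr, Hf);
  lstm_forward_dir(net.bwd, X, true,  nullptr, Hb);
  cube out(Hf.n_rows * 2, X.n_cols, X.n_slices);
  for (uword t = 0; t < X.n_slices; ++t)
    out.slice(t) = join_cols(Hf.slice(t), Hb.slice(t));
  return out;
}

// ----------------------------------------------------------------------- MLP

// [[Rcpp::export(name = ".cpp_mlp_init")]]
Rcpp::List cpp_mlp_init(int input_dim, Rcpp::IntegerVector hidden, int seed) {
  std::mt19937_64 rng((uint64_t)seed);
  std::vector<int> dims = {input_dim};
  for (int h : hidden) dims.push_back(h);
  dims.push_back(2);
  Rcpp::List Ws(dims.size() - 1), bs(dims.size() - 1);
  for (size_t l = 0; l + 1 < dims.size(); ++l) {
    Ws[l] = glorot(dims[l + 1], dims[l], rng);
    bs[l] = zeros<vec>(dims[l + 1]);
  }
  return Rcpp::List::create(Rcpp::Named("W") = Ws, Rcpp::Named("b") = bs);
}

// Train an MLP per-sample classifier with minibatch SGD.
//   X: D x N matrix of feature vectors, y: 0/1 labels (length N).
// [[Rcpp::export(name = ".cpp_mlp_train")]]
Rcpp::List cpp_mlp_train(arma::mat X, arma::ivec y, Rcpp::List init,
                         int epochs, int batch, int seed, double lr) {
  Rcpp::List Ws0 = init["W"], bs0 = init["b"];
  size_t L = Ws0.size();
  std::vector<mat> W(L); std::vector<vec> b(L);
  for (size_t l = 0; l < L; ++l) { W[l] = Rcpp::as<mat>(Ws0[l]); b[l] = Rcpp::as<vec>(bs0[l]); }
  uword N = X.n_cols;
  if ((uword)y.n_elem != N) Rcpp::stop("label length mismatch");
  std::mt19937_64 rng((uint64_t)seed + 0x7f4a7c15ULL);
  std::vector<uword> order(N);
  for (uword i = 0; i < N; ++i) order[i] = i;
  std::vector<double> loss_hist;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0;
    for (uword start = 0; start < N; start += (uword)batch) {
      uword stop = std::min<uword>(start + batch, N);
      uvec idx(stop - start);
      for (uword k = 0; k < idx.n_elem; ++k) idx[k] = order[start + k];
      mat A = X.cols(idx);
      uword B = idx.n_elem;
      std::vector<mat> acts = {A};
      for (size_t l = 0; l < L; ++l) {
        mat Z = W[l] * acts.back(); Z.each_col() += b[l];
        if (l + 1 < L) Z = clamp(Z, 0.0, datum::inf);   // ReLU
        acts.push_back(Z);
      }
      mat P = softmax2(acts.back());
      mat dZ = P;
      for (uword k = 0; k < B; ++k) {
        int yy = y[idx[k]];
        ep_loss -= std::log(std::max(P(yy, k), 1e-12));
        dZ(yy, k) -= 1.0;
      }
      dZ /= (double)B;
      for (size_t l = L; l-- > 0;) {
        mat dW = dZ * acts[l].t();
        vec db = sum(dZ, 1);
        if (l > 0) {
          mat dA = W[l].t() * dZ;
          dZ = dA % conv_to<mat>::from(acts[l] > 0);
        }
        W[l] -= lr * dW; b[l] -= lr * db;
      }
    }
    loss_hist.push_back(ep_loss / (double)N);
    Rcpp::checkUserInterrupt();
  }
  Rcpp::List Ws(L), bs(L);
  for (size_t l = 0; l < L; ++l) { Ws[l] = W[l]; bs[l] = b[l]; }
  return Rcpp::List::create(
    Rcpp::Named("params") = Rcpp::List::create(Rcpp::Named("W") = Ws,
                                               Rcpp::Named("b") = bs),
    Rcpp::Named("loss") = loss_hist);
}

// Class-1 probability for each column of X.
// [[Rcpp::export(name = ".cpp_mlp_prob")]]
arma::rowvec cpp_mlp_prob(Rcpp::List params, arma::mat X) {
  Rcpp::List Ws = params["W"], bs = params["b"];
  size_t L = Ws.size();
  mat A = X;
  for (size_t l = 0; l < L; ++l) {
    mat Wl = Rcpp::as<mat>(Ws[l]); vec bl = Rcpp::as<vec>(bs[l]);
    A = Wl * A; A.each_col() += bl;
    if (l + 1 < L) A = clamp(A, 0.0, datum::inf);
  }
  return softmax2(A).row(1);
}
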