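// Network math for the window-based FFNN and the two-stage cascaded
// bidirectional-recurrent + convolutional sequence labeler (CBRCNN).
//
// Conventions shared with the R side (see param_layout() in R/model.R):
//  - parameters travel as one flat vector; blocks are unpacked in a fixed
//    order, each matrix column-major, bias as the last column;
//  - encodings are passed transposed (D x L, one column per residue);
//  - labels are 1-based class indices.
//
// CBRCNN stage wiring: a forward chain of memory size NF is updated left
// to right by a two-layer cell (hidden NHF, tanh on both layers) reading
// [previous memory; input columns t-cc..t+cc]; an independent backward
// chain (NB, NHB) runs right to left. A convolutional layer with kernel
// 2*cofb+1 reads windows of the concatenated [forward; backward] memories
// into NHY tanh units; a kernel-1 convolution maps NHY to the class
// softmax. Chain memories and all out-of-range windows are zero.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat softmax_cols(const mat& Z) {
  mat P = Z;
  for (uword j = 0; j < P.n_cols; ++j) {
    vec z = P.col(j);
    z -= z.max();
    vec e = exp(z);
    P.col(j) = e / accu(e);
  }
  return P;
}

// ---------------------------------------------------------------- stage

struct StageDims {
  int din, K, nf, nb, nhf, nhb, nhy, cofb, cc, convin;
  int xw() const { return (2 * cc + 1) * din; }            // cell input window
  int uf() const { return nf + xw() + 1; }                 // fwd cell input (+bias)
  int ub() const { return nb + xw() + 1; }
  int vlen() const {                                       // conv window
    int v = (nf + nb) * (2 * cofb + 1);
    if (convin) v += (2 * cofb + 1) * din;
    return v;
  }
  int n_params() const {
    return nhf * uf() + nf * (nhf + 1) + nhb * ub() + nb * (nhb + 1) +
           nhy * (vlen() + 1) + K * (nhy + 1);
  }
};

static StageDims stage_dims(const Rcpp::List& s) {
  StageDims d;
  d.din = s["din"]; d.K = s["k"]; d.nf = s["nf"]; d.nb = s["nb"];
  d.nhf = s["nhf"]; d.nhb = s["nhb"]; d.nhy = s["nhy"];
  d.cofb = s["cofb"]; d.cc = s["cc"]; d.convin = s["convin"];
  return d;
}

struct StageW { mat Wf1, Wf2, Wb1, Wb2, Wc1, Wc2; };

static StageW unpack_stage(const vec& theta, int& off, const StageDims& d) {
  StageW w;
  auto take = [&](int r, int c) {
    mat m(theta.memptr() + off, r, c);
    off += r * c;
    return m;
  };
  w.Wf1 = take(d.nhf, d.uf());
  w.Wf2 = take(d.nf, d.nhf + 1);
  w.Wb1 = take(d.nhb, d.ub());
  w.Wb2 = take(d.nb, d.nhb + 1);
  w.Wc1 = take(d.nhy, d.vlen() + 1);
  w.Wc2 = take(d.K, d.nhy + 1);
  return w;
}

static void pack_stage(vec& g, int& off, const StageW& w) {
  auto put = [&](const mat& m) {
    g.subvec(off, off + m.n_elem - 1) += vectorise(m);
    off += m.n_elem;
  };
  put(w.Wf1); put(w.Wf2); put(w.Wb1); put(w.Wb2); put(w.Wc1); put(w.Wc2);
}

struct StageCache {
  mat Uf, Hf, F, Ub, Hb, B, V, Hc, P;
};

// input window column [x_{t-cc} ... x_{t+cc}], zero padded
static vec input_window(const mat& X, int t, int cc) {
  const int D = X.n_rows, L = X.n_cols;
  vec out((2 * cc + 1) * D, fill::zeros);
  for (int k = -cc; k <= cc; ++k) {
    int p = t + k;
    if (p >= 0 && p < L)
      out.subvec((k + cc) * D, (k + cc) * D + D - 1) = X.col(p);
  }
  return out;
}

static mat stage_forward(const StageDims& d, const StageW& w, const mat& X,
                         StageCache& c) {
  const int L = X.n_cols;
  c.Uf.set_size(d.uf(), L);  c.Hf.set_size(d.nhf, L);  c.F.set_size(d.nf, L);
  c.Ub.set_size(d.ub(), L);  c.Hb.set_size(d.nhb, L);  c.B.set_size(d.nb, L);
  vec prev(d.nf, fill::zeros);
  for (int t = 0; t < L; ++t) {
    vec u(d.uf());
    u.subvec(0, d.nf - 1) = prev;
    u.subvec(d.nf, d.nf + d.xw() - 1) = input_window(X, t, d.cc);
    u(d.uf() - 1) = 1.0;
    c.Uf.col(t) = u;
    vec h = tanh(w.Wf1 * u);
    c.Hf.col(t) = h;
    vec hb = join_cols(h, vec{1.0});
    prev = tanh(w.Wf2 * hb);
    c.F.col(t) = prev;
  }
  vec nxt(d.nb, fill::zeros);
  for (int t = L - 1; t >= 0; --t) {
    vec u(d.ub());
    u.subvec(0, d.nb - 1) = nxt;
    u.subvec(d.nb, d.nb + d.xw() - 1) = input_window(X, t, d.cc);
    u(d.ub() - 1) = 1.0;
    c.Ub.col(t) = u;
    vec h = tanh(w.Wb1 * u);
    c.Hb.col(t) = h;
    vec hb = join_cols(h, vec{1.0});
    nxt = tanh(w.Wb2 * hb);
    c.B.col(t) = nxt;
  }
  // convolution over chain memories
  const int span = 2 * d.cofb + 1, fb = d.nf + d.nb;
  c.V.set_size(d.vlen(), L);
  c.V.zeros();
  for (int t = 0; t < L; ++t) {
    for (int k = -d.cofb; k <= d.cofb; ++k) {
      int p = t + k;
      if (p < 0 || p >= L) continue;
      int base = (k + d.cofb) * fb;
      c.V.col(t).subvec(base, base + d.nf - 1) = c.F.col(p);
      c.V.col(t).subvec(base + d.nf, base + fb - 1) = c.B.col(p);
    }
    if (d.convin) {
      int base0 = span * fb;
      for (int k = -d.cofb; k <= d.cofb; ++k) {
        int p = t + k;
        if (p < 0 || p >= L) continue;
        int base = base0 + (k + d.cofb) * d.din;
        c.V.col(t).subvec(base, base + d.din - 1) = X.col(p);
      }
    }
  }
  mat Vb = join_cols(c.V, ones<rowvec>(L));
  c.Hc = tanh(w.Wc1 * Vb);
  mat Hcb = join_cols(c.Hc, ones<rowvec>(L));
  c.P = softmax_cols(w.Wc2 * Hcb);
  return c.P;
}

// dZ = dL/d(pre-softmax); returns dX and accumulates weight grads in g.
static mat stage_backward(const StageDims& d, const StageW& w, const mat& X,
                          const StageCache& c, const mat& dZ, StageW& g) {
  const int L = X.n_cols;
  const int span = 2 * d.cofb + 1, fb = d.nf + d.nb;
  mat dX(d.din, L, fill::zeros);

  mat Hcb = join_cols(c.Hc, ones<rowvec>(L));
  g.Wc2 += dZ * Hcb.t();
  mat dHc = w.Wc2.cols(0, d.nhy - 1).t() * dZ;
  dHc %= (1.0 - square(c.Hc));
  mat Vb = join_cols(c.V, ones<rowvec>(L));
  g.Wc1 += dHc * Vb.t();
  mat dV = w.Wc1.cols(0, d.vlen() - 1).t() * dHc;

  mat dF(d.nf, L, fill::zeros), dB(d.nb, L, fill::zeros);
  for (int t = 0; t < L; ++t) {
    for (int k = -d.cofb; k <= d.cofb; ++k) {
      int p = t + k;
      if (p < 0 || p >= L) continue;
      int base = (k + d.cofb) * fb;
      dF.col(p) += dV.col(t).subvec(base, base + d.nf - 1);
      dB.col(p) += dV.col(t).subvec(base + d.nf, base + fb - 1);
    }
    if (d.convin) {
      int base0 = span * fb;
      for (int k = -d.cofb; k <= d.cofb; ++k) {
        int p = t + k;
        if (p < 0 || p >= L) continue;
        int base = base0 + (k + d.cofb) * d.din;
        dX.col(p) += dV.col(t).subvec(base, base + d.din - 1);
      }
    }
  }

  // forward chain: gradient flows t -> t-1
  for (int t = L - 1; t >= 0; --t) {
    vec dA = dF.col(t) % (1.0 - square(c.F.col(t)));
    vec hb = join_cols(c.Hf.col(t), vec{1.0});
    g.Wf2 += dA * hb.t();
    vec dH = w.Wf2.cols(0, d.nhf - 1).t() * dA;
    dH %= (1.0 - square(c.Hf.col(t)));
    g.Wf1 += dH * c.Uf.col(t).t();
    vec du = w.Wf1.t() * dH;
    if (t > 0) dF.col(t - 1) += du.subvec(0, d.nf - 1);
    for (int k = -d.cc; k <= d.cc; ++k) {
      int p = t + k;
      if (p < 0 || p >= L) continue;
      int base = d.nf + (k + d.cc) * d.din;
      dX.col(p) += du.subvec(base, base + d.din - 1);
    }
  }
  // backward chain: gradient flows t -> t+1
  for (int t = 0; t < L; ++t) {
    vec dA = dB.col(t) % (1.0 - square(c.B.col(t)));
    vec hb = join_cols(c.Hb.col(t), vec{1.0});
    g.Wb2 += dA * hb.t();
    vec dH = w.Wb2.cols(0, d.nhb - 1).t() * dA;
    dH %= (1.0 - square(c.Hb.col(t)));
    g.Wb1 += dH * c.Ub.col(t).t();
    vec du = w.Wb1.t() * dH;
    if (t < L - 1) dB.col(t + 1) += du.subvec(0, d.nb - 1);
    for (int k = -d.cc; k <= d.cc; ++k) {
      int p = t + k;
      if (p < 0 || p >= L) continue;
      int base = d.nb + (k + d.cc) * d.din;
      dX.col(p) += du.subvec(base, base + d.din - 1);
    }
  }
  return dX;
}

// ------------------------------------------------------- segment average

// Cseg contiguous blocks of Cwin positions tiled around t (central block
// centred on t; for even Cseg the extra block sits to the right), each
// block the mean of the stage-1 output rows it covers; positions beyond
// the termini count as zero rows.
static mat segment_average_mat(const mat& P, int cseg, int cwin) {
  const int K = P.n_rows, L = P.n_cols;
  const int cblock = (cseg - 1) / 2;
  mat S(cseg * K, L, fill::zeros);
  for (int t = 0; t < L; ++t) {
    for (int j = 0; j < cseg; ++j) {
      int start = t + (j - cblock) * cwin - cwin / 2;
      vec acc(K, fill::zeros);
      for (int s = start; s < start + cwin; ++s)
        if (s >= 0 && s < L) acc += P.col(s);
      S.col(t).subvec(j * K, (j + 1) * K - 1) = acc / cwin;
    }
  }
  return S;
}

static mat segment_average_back(const mat& dS, int cseg, int cwin, int K, int L) {
  const int cblock = (cseg - 1) / 2;
  mat dP(K, L, fill::zeros);
  for (int t = 0; t < L; ++t) {
    for (int j = 0; j < cseg; ++j) {
      int start = t + (j - cblock) * cwin - cwin / 2;
      vec d = dS.col(t).subvec(j * K, (j + 1) * K - 1) / cwin;
      for (int s = start; s < start + cwin; ++s)
        if (s >= 0 && s < L) dP.col(s) += d;
    }
  }
  return dP;
}

// [[Rcpp::export(name = ".segment_average_cpp")]]
arma::mat segment_average_cpp(const arma::mat& P, int cseg, int cwin) {
  return segment_average_mat(P, cseg, cwin);
}

// ------------------------------------------------------------- cbrcnn

struct CbrcnnCfg {
  StageDims s1, s2;
  int cseg, cwin;
};

static CbrcnnCfg cbrcnn_cfg(const Rcpp::List& cfg) {
  CbrcnnCfg c;
  c.s1 = stage_dims(cfg["stage1"]);
  c.s2 = stage_dims(cfg["stage2"]);
  c.cseg = cfg["cseg"];
  c.cwin = cfg["cwin"];
  return c;
}

static void check_theta(const vec& theta, int need) {
  if ((int)theta.n_elem != need)
    Rcpp::stop("parameter vector has %d elements, configuration requires %d",
               (int)theta.n_elem, need);
}

// [[Rcpp::export(name = ".cbrcnn_forward_cpp")]]
Rcpp::List cbrcnn_forward_cpp(const arma::mat& X, const arma::vec& theta,
                              const Rcpp::List& cfg) {
  CbrcnnCfg c = cbrcnn_cfg(cfg);
  if ((int)X.n_rows != c.s1.din)
    Rcpp::stop("input has %d rows, configuration expects %d", (int)X.n_rows, c.s1.din);
  check_theta(theta, c.s1.n_params() + c.s2.n_params());
  int off = 0;
  StageW w1 = unpack_stage(theta, off, c.s1);
  StageW w2 = unpack_stage(theta, off, c.s2);
  StageCache c1, c2;
  mat P1 = stage_forward(c.s1, w1, X, c1);
  mat X2 = segment_average_mat(P1, c.cseg, c.cwin);
  mat P2 = stage_forward(c.s2, w2, X2, c2);
  return Rcpp::List::create(Rcpp::Named("p1") = P1.t(),
                            Rcpp::Named("p2") = P2.t());
}

// summed cross-entropy over a batch of proteins, with gradient;
// labels are 1-based class indices. The reported loss is the stage-2
// cross-entropy; stage 1 is itself a class predictor and its
// cross-entropy is added to the training objective with weight
// `stage1_weight` (0 recovers a pure stage-2 objective).
// [[Rcpp::export(name = ".cbrcnn_loss_grad_cpp")]]
Rcpp::List cbrcnn_loss_grad_cpp(const Rcpp::List& Xs, const Rcpp::List& ys,
                                const arma::vec& theta, const Rcpp::List& cfg,
                                double stage1_weight = 1.0) {
  CbrcnnCfg c = cbrcnn_cfg(cfg);
  const int np = c.s1.n_params() + c.s2.n_params();
  check_theta(theta, np);
  vec grad(np, fill::zeros);
  double loss = 0.0;
  int nres = 0;

  for (int i = 0; i < Xs.size(); ++i) {
    mat X = Rcpp::as<mat>(Xs[i]);
    Rcpp::IntegerVector y = ys[i];
    const int L = X.n_cols;
    if ((int)y.size() != L) Rcpp::stop("labels/input length mismatch");
    int off = 0;
    StageW w1 = unpack_stage(theta, off, c.s1);
    StageW w2 = unpack_stage(theta, off, c.s2);
    StageCache c1, c2;
    mat P1 = stage_forward(c.s1, w1, X, c1);
    mat X2 = segment_average_mat(P1, c.cseg, c.cwin);
    mat P2 = stage_forward(c.s2, w2, X2, c2);

    mat dZ2 = P2;
    for (int t = 0; t < L; ++t) {
      int k = y[t] - 1;
      if (k < 0 || k >= c.s2.K) Rcpp::stop("label out of range");
      loss -= std::log(std::max(P2(k, t), 1e-300));
      dZ2(k, t) -= 1.0;
    }
    nres += L;

    StageW g1, g2;
    g1.Wf1.zeros(size(w1.Wf1)); g1.Wf2.zeros(size(w1.Wf2));
    g1.Wb1.zeros(size(w1.Wb1)); g1.Wb2.zeros(size(w1.Wb2));
    g1.Wc1.zeros(size(w1.Wc1)); g1.Wc2.zeros(size(w1.Wc2));
    g2.Wf1.zeros(size(w2.Wf1)); g2.Wf2.zeros(size(w2.Wf2));
    g2.Wb1.zeros(size(w2.Wb1)); g2.Wb2.zeros(size(w2.Wb2));
    g2.Wc1.zeros(size(w2.Wc1)); g2.Wc2.zeros(size(w2.Wc2));

    mat dX2 = stage_backward(c.s2, w2, X2, c2, dZ2, g2);
    mat dP1 = segment_average_back(dX2, c.cseg, c.cwin, c.s1.K, L);
    // through the stage-1 softmax: dz = p .* (dp - <p, dp>)
    mat dZ1 = P1 % (dP1 - repmat(sum(P1 % dP1, 0), c.s1.K, 1));
    if (stage1_weight != 0.0) {
      mat dZaux = P1;
      for (int t = 0; t < L; ++t) dZaux(y[t] - 1, t) -= 1.0;
      dZ1 += stage1_weight * dZaux;
    }
    stage_backward(c.s1, w1, X, c1, dZ1, g1);

    int goff = 0;
    pack_stage(grad, goff, g1);
    pack_stage(grad, goff, g2);
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad,
                            Rcpp::Named("n") = nres);
}

// --------------------------------------------------------------- ffnn

struct FfnnCfg {
  int din, K, l;
  std::vector<int> hidden;
  int win() const { return (2 * l + 1) * din; }
  int n_params() const {
    int in = win(), n = 0;
    for (int h : hidden) { n += h * (in + 1); in = h; }
    n += K * (in + 1);
    return n;
  }
};

static FfnnCfg ffnn_cfg(const Rcpp::List& cfg) {
  FfnnCfg c;
  c.din = cfg["din"]; c.K = cfg["k"]; c.l = cfg["l"];
  c.hidden = Rcpp::as<std::vector<int>>(cfg["hidden"]);
  return c;
}

// window matrix: column t = concatenated X cols t-l..t+l (zero padded)
static mat window_matrix(const mat& X, int l) {
  const int D = X.n_rows, L = X.n_cols;
  mat W((2 * l + 1) * D, L, fill::zeros);
  for (int t = 0; t < L; ++t)
    W.col(t) = input_window(X, t, l);
  return W;
}

static std::vector<mat> unpack_ffnn(const vec& theta, const FfnnCfg& c) {
  std::vector<mat> Ws;
  int off = 0, in = c.win();
  for (int h : c.hidden) {
    Ws.emplace_back(theta.memptr() + off, h, in + 1);
    off += h * (in + 1);
    in = h;
  }
  Ws.emplace_back(theta.memptr() + off, c.K, in + 1);
  return Ws;
}

// [[Rcpp::export(name = ".ffnn_forward_cpp")]]
arma::mat ffnn_forward_cpp(const arma::mat& X, const arma::vec& theta,
                           const Rcpp::List& cfg) {
  FfnnCfg c = ffnn_cfg(cfg);
  if ((int)X.n_rows != c.din)
    Rcpp::stop("input has %d rows, configuration expects %d", (int)X.n_rows, c.din);
  check_theta(theta, c.n_params());
  std::vector<mat> Ws = unpack_ffnn(theta, c);
  mat A = window_matrix(X, c.l);
  for (size_t i = 0; i + 1 < Ws.size(); ++i)
    A = tanh(Ws[i] * join_cols(A, ones<rowvec>(A.n_cols)));
  mat Z = Ws.back() * join_cols(A, ones<rowvec>(A.n_cols));
  return softmax_cols(Z).t();
}

// [[Rcpp::export(name = ".ffnn_loss_grad_cpp")]]
Rcpp::List ffnn_loss_grad_cpp(const Rcpp::List& Xs, const Rcpp::List& ys,
                              const arma::vec& theta, const Rcpp::List& cfg) {
  FfnnCfg c = ffnn_cfg(cfg);
  const int np = c.n_params();
  check_theta(theta, np);
  std::vector<mat> Ws = unpack_ffnn(theta, c);
  vec grad(np, fill::zeros);
  double loss = 0.0;
  int nres = 0;

  for (int i = 0; i < Xs.size(); ++i) {
    mat X = Rcpp::as<mat>(Xs[i]);
    Rcpp::IntegerVector y = ys[i];
    const int L = X.n_cols;
    if ((int)y.size() != L) Rcpp::stop("labels/input length mismatch");
    std::vector<mat> acts; // layer inputs (pre-bias)
    mat A = window_matrix(X, c.l);
    acts.push_back(A);
    for (size_t li = 0; li + 1 < Ws.size(); ++li) {
      A = tanh(Ws[li] * join_cols(A, ones<rowvec>(L)));
      acts.push_back(A);
    }
    mat Z = Ws.back() * join_cols(A, ones<rowvec>(L));
    mat P = softmax_cols(Z);
    mat dZ = P;
    for (int t = 0; t < L; ++t) {
      int k = y[t] - 1;
      if (k < 0 || k >= c.K) Rcpp::stop("label out of range");
      loss -= std::log(std::max(P(k, t), 1e-300));
      dZ(k, t) -= 1.0;
    }
    nres += L;

    // backprop
    std::vector<mat> gW(Ws.size());
    mat d = dZ;
    for (int li = (int)Ws.size() - 1; li >= 0; --li) {
      mat Ab = join_cols(acts[li], ones<rowvec>(L));
      gW[li] = d * Ab.t();
      if (li > 0) {
        d = Ws[li].cols(0, acts[li].n_rows - 1).t() * d;
        d %= (1.0 - square(acts[li]));
      }
    }
    int off = 0;
    for (size_t li = 0; li < Ws.size(); ++li) {
      grad.subvec(off, off + gW[li].n_elem - 1) += vectorise(gW[li]);
      off += gW[li].n_elem;
    }
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad,
                            Rcpp::Named("n") = nres);
}
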