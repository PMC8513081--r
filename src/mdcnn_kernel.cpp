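// Forward/backward passes of the multi-domain convolutional network.
//
// One branch = ShallowConvNet-style stack:
//   temporal conv (F1 kernels 1 x K, shared across channels, valid)
//   -> spatial conv (F2 kernels over F1 maps x N channels, valid)
//   -> batch norm -> square -> average pool (1 x pool, stride)
//   -> log(max(., eps)) -> dropout -> FC to D features.
// Each branch has its own softmax head; branch features are concatenated and
// fused by one more FC + softmax (the "multi" head). Total loss is the
// weighted sum of the heads' cross-entropies, averaged over the batch.
//
// All dense algebra is expressed as BLAS-3 calls on matrices aliased over
// cube memory (columns ordered (t, b)), so the same code serves tiny unit
// tests and full 40-filter models.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::cube;
using arma::vec;
using arma::rowvec;
using arma::uword;

namespace {

struct BranchCache {
  mat Hb;   // K x (T1*N*B)     batched Hankel view of the input
  mat U;    // (F1*N) x (T1*B)  temporal-conv output (+bias)
  mat Vn;   // F2 x (T1*B)      batch-normalized pre-square
  mat Y;    // F2 x (T1*B)      gamma*Vn + beta (input to square)
  mat P;    // F2 x (T2*B)      pooled squares
  mat Fl;   // (F2*T2) x B      log features after dropout (FC input)
  mat H;    // D x B            branch feature vector
  vec mu, istd;  // BN batch statistics
};

void softmax_cols(mat& z) {
  z.each_row() -= arma::max(z, 0);
  z = arma::exp(z);
  z.each_row() /= arma::sum(z, 0);
}

} // namespace

// Single forward (and optional backward) pass over one mini-batch.
//
// X:        list, one (N x T x B) cube per branch
// y:        1-based labels (length B) or empty (predict)
// params:   list(branches = list(list(Wt, bt, Ws, gamma, beta, W1, b1,
//                                     Wh, bh), ...), fusion = list(Wf, bf))
// bn_state: list(branches = list(list(rmean, rvar), ...))
// masks:    list of (F2*T2 x B) 0/1 matrices (may be empty when !train)
// dims:     list(K, pool, stride, log_eps, bn_eps, bn_momentum, dropout)
// loss_w:   length nb + 1, branch weights then multi weight
// [[Rcpp::export]]
List mdcnn_pass(List X, IntegerVector y, List params, List bn_state,
                List masks, List dims, NumericVector loss_w,
                bool train, bool want_grad) {
  List brp = params["branches"];
  List fus = params["fusion"];
  List bns = bn_state["branches"];
  const int nb = brp.size();
  const int K = as<int>(dims["K"]);
  const int pool = as<int>(dims["pool"]);
  const int stride = as<int>(dims["stride"]);
  const double log_eps = as<double>(dims["log_eps"]);
  const double bn_eps = as<double>(dims["bn_eps"]);
  const double bn_mom = as<double>(dims["bn_momentum"]);
  const double dropout = as<double>(dims["dropout"]);
  const bool use_mask = train && masks.size() == nb && dropout > 0;

  std::vector<BranchCache> cache(nb);
  std::vector<cube> Xc(nb);
  mat Hcat;
  List head_probs(nb + 1);
  List bn_new(nb);

  int B = 0, N = 0, T = 0, T1 = 0, T2 = 0, M = 0, D = 0;

  for (int br = 0; br < nb; ++br) {
    Xc[br] = as<cube>(X[br]);
    const cube& Xb = Xc[br];
    List p = brp[br];
    mat Wt = as<mat>(p["Wt"]);        vec bt = as<vec>(p["bt"]);
    mat Ws = as<mat>(p["Ws"]);
    vec gamma = as<vec>(p["gamma"]);  vec beta = as<vec>(p["beta"]);
    mat W1 = as<mat>(p["W1"]);        vec b1 = as<vec>(p["b1"]);
    mat Wh = as<mat>(p["Wh"]);        vec bh = as<vec>(p["bh"]);

    N = Xb.n_rows; T = Xb.n_cols; B = Xb.n_slices;
    const int F1 = Wt.n_rows;
    const int F2 = Ws.n_rows;
    T1 = T - K + 1;
    T2 = (T1 - pool) / stride + 1;
    D = W1.n_rows;
    M = Wh.n_rows;
    if ((int)Ws.n_cols != F1 * N)
      stop("spatial filter width (%d) != temporal_filters * channels (%d)",
           (int)Ws.n_cols, F1 * N);
    if ((int)W1.n_cols != F2 * T2)
      stop("FC width (%d) != spatial_filters * pooled length (%d)",
           (int)W1.n_cols, F2 * T2);

    BranchCache& C = cache[br];
    // batched Hankel: column t + T1*(c + N*b) holds X(c, t..t+K-1) of crop b,
    // so the whole temporal convolution is one BLAS-3 call
    C.Hb.set_size(K, (uword)T1 * N * B);
    arma::rowvec xr(T);
    for (int b = 0; b < B; ++b) {
      const mat& xb = Xb.slice(b);
      for (int c = 0; c < N; ++c) {
        xr = xb.row(c);                             // contiguous copy
        const double* xp = xr.memptr();
        double* col0 = C.Hb.colptr((uword)T1 * (c + (uword)N * b));
        for (int t = 0; t < T1; ++t)
          std::memcpy(col0 + (uword)t * K, xp + t, K * sizeof(double));
      }
    }
    mat Wtb = Wt * C.Hb;                            // F1 x (T1*N*B)
    C.U.set_size(F1 * N, (uword)T1 * B);
    for (int b = 0; b < B; ++b)
      for (int c = 0; c < N; ++c)
        C.U.submat(c * F1, (uword)b * T1, (c + 1) * F1 - 1,
                   (uword)(b + 1) * T1 - 1) =
          Wtb.cols((uword)T1 * (c + (uword)N * b),
                   (uword)T1 * (c + (uword)N * b) + T1 - 1);
    vec btfull = arma::repmat(bt, N, 1);
    C.U.each_col() += btfull;

    mat V = Ws * C.U;                               // F2 x (T1*B)

    // batch normalization per output map
    List st = bns[br];
    vec rmean = as<vec>(st["rmean"]);
    vec rvar = as<vec>(st["rvar"]);
    vec mu(F2), var(F2);
    if (train) {
      mu = arma::mean(V, 1);
      mat Vc0 = V.each_col() - mu;
      var = arma::mean(arma::square(Vc0), 1);
      rmean = (1.0 - bn_mom) * rmean + bn_mom * mu;
      rvar = (1.0 - bn_mom) * rvar + bn_mom * var;
    } else {
      mu = rmean;
      var = rvar;
    }
    bn_new[br] = List::create(_["rmean"] = rmean, _["rvar"] = rvar);
    C.istd = 1.0 / arma::sqrt(var + bn_eps);
    C.mu = mu;
    C.Vn = V.each_col() - mu;
    C.Vn.each_col() %= C.istd;
    C.Y = C.Vn.each_col() % gamma;
    C.Y.each_col() += beta;

    mat S = arma::square(C.Y);                      // square activation
    C.P.set_size(F2, (uword)T2 * B);
    for (int b = 0; b < B; ++b)
      for (int u = 0; u < T2; ++u) {
        uword a = (uword)b * T1 + (uword)u * stride;
        C.P.col((uword)b * T2 + u) =
          arma::sum(S.cols(a, a + pool - 1), 1) / pool;
      }

    mat Lg = arma::log(arma::clamp(C.P, log_eps,
                                   arma::datum::inf));   // F2 x (T2*B)
    // reinterpret as (F2*T2) x B without copying
    mat flat(Lg.memptr(), (uword)F2 * T2, B, false, true);
    if (use_mask) {
      mat mk = as<mat>(masks[br]);
      C.Fl = (flat % mk) / (1.0 - dropout);
    } else {
      C.Fl = flat;
    }

    C.H = W1 * C.Fl;
    C.H.each_col() += b1;

    mat zh = Wh * C.H;
    zh.each_col() += bh;
    softmax_cols(zh);
    head_probs[br] = zh;                            // M x B

    if (br == 0) Hcat.set_size((uword)D * nb, B);
    Hcat.rows((uword)br * D, (uword)(br + 1) * D - 1) = C.H;
  }

  mat Wf = as<mat>(fus["Wf"]);
  vec bf = as<vec>(fus["bf"]);
  mat zf = Wf * Hcat;
  zf.each_col() += bf;
  softmax_cols(zf);
  head_probs[nb] = zf;

  double loss = NA_REAL;
  if (y.size() == B) {
    loss = 0.0;
    for (int b = 0; b < B; ++b) {
      int cls = y[b] - 1;
      for (int br = 0; br < nb; ++br)
        loss -= loss_w[br] *
          std::log(std::max(as<mat>(head_probs[br])(cls, b), 1e-300));
      loss -= loss_w[nb] * std::log(std::max(zf(cls, b), 1e-300));
    }
    loss /= B;
  }

  List out = List::create(_["probs"] = head_probs, _["loss"] = loss,
                          _["bn_state"] = List::create(_["branches"] = bn_new));
  if (!want_grad) return out;
  if (y.size() != B) stop("gradients need labels");

  mat onehot(M, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) onehot(y[b] - 1, b) = 1.0;

  // fusion head
  mat dzf = (zf - onehot) * (loss_w[nb] / B);
  mat dWf = dzf * Hcat.t();
  vec dbf = arma::sum(dzf, 1);
  mat dHcat = Wf.t() * dzf;

  List gbr(nb);
  for (int br = 0; br < nb; ++br) {
    List p = brp[br];
    mat Wt = as<mat>(p["Wt"]);
    mat Ws = as<mat>(p["Ws"]);
    vec gamma = as<vec>(p["gamma"]);
    mat W1 = as<mat>(p["W1"]);
    mat Wh = as<mat>(p["Wh"]);
    BranchCache& C = cache[br];
    const int F1 = Wt.n_rows;
    const int F2 = Ws.n_rows;

    mat pb = as<mat>(head_probs[br]);
    mat dzh = (pb - onehot) * (loss_w[br] / B);
    mat dWh = dzh * C.H.t();
    vec dbh = arma::sum(dzh, 1);

    mat dH = Wh.t() * dzh +
      dHcat.rows((uword)br * D, (uword)(br + 1) * D - 1);
    mat dW1 = dH * C.Fl.t();
    vec db1 = arma::sum(dH, 1);
    mat dFl = W1.t() * dH;                          // (F2*T2) x B
    if (use_mask) {
      mat mk = as<mat>(masks[br]);
      dFl = (dFl % mk) / (1.0 - dropout);
    }
    // d log(clamp(P, eps)) / dP
    mat dP(dFl.memptr(), F2, (uword)T2 * B, false, true);
    mat dPP = dP / arma::clamp(C.P, log_eps, arma::datum::inf);
    dPP.elem(arma::find(C.P < log_eps)).zeros();

    mat dS(F2, (uword)T1 * B, arma::fill::zeros);
    for (int b = 0; b < B; ++b)
      for (int u = 0; u < T2; ++u) {
        uword a = (uword)b * T1 + (uword)u * stride;
        dS.cols(a, a + pool - 1).each_col() +=
          dPP.col((uword)b * T2 + u) / pool;
      }

    mat dY = 2.0 * (C.Y % dS);
    vec dgamma = arma::sum(dY % C.Vn, 1);
    vec dbeta = arma::sum(dY, 1);

    mat dV;
    if (train) {
      // standard batch-norm backward over T1*B elements per map
      const double ne = (double)C.Vn.n_cols;
      mat dVn = dY.each_col() % gamma;
      vec s1 = arma::sum(dVn, 1);
      vec s2 = arma::sum(dVn % C.Vn, 1);
      dV = dVn * ne;
      dV.each_col() -= s1;
      dV -= C.Vn.each_col() % s2;
      dV.each_col() %= C.istd / ne;
    } else {
      dV = dY.each_col() % (gamma % C.istd);
    }

    mat dWs = dV * C.U.t();
    mat dU = Ws.t() * dV;                           // (F1*N) x (T1*B)

    // gather dU back into the batched-Hankel column order, then one gemm
    mat dUb(F1, (uword)T1 * N * B);
    for (int b = 0; b < B; ++b)
      for (int c = 0; c < N; ++c)
        dUb.cols((uword)T1 * (c + (uword)N * b),
                 (uword)T1 * (c + (uword)N * b) + T1 - 1) =
          dU.submat(c * F1, (uword)b * T1, (c + 1) * F1 - 1,
                    (uword)(b + 1) * T1 - 1);
    mat dWt = dUb * C.Hb.t();
    vec dbt = arma::sum(dUb, 1);

    gbr[br] = List::create(
      _["Wt"] = dWt, _["bt"] = dbt, _["Ws"] = dWs,
      _["gamma"] = dgamma, _["beta"] = dbeta,
      _["W1"] = dW1, _["b1"] = db1, _["Wh"] = dWh, _["bh"] = dbh);
  }

  out["grads"] = List::create(
    _["branches"] = gbr,
    _["fusion"] = List::create(_["Wf"] = dWf, _["bf"] = dbf));
  return out;
}
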