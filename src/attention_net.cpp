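// Forward and backward passes for the grouped-attention model and the
// fully-connected baseline.  All randomness (initialization, shuffling,
// optimizer) lives on the R side; everything here is deterministic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;

static mat activate(const mat& z, const std::string& a) {
  if (a == "relu") return arma::clamp(z, 0.0, arma::datum::inf);
  if (a == "tanh") return arma::tanh(z);
  Rcpp::stop("unknown activation: " + a);
}

static mat activate_deriv(const mat& z, const std::string& a) {
  if (a == "relu") return conv_to<mat>::from(z > 0);
  if (a == "tanh") { mat t = arma::tanh(z); return 1.0 - t % t; }
  Rcpp::stop("unknown activation: " + a);
}

static mat out_activate(const mat& z, const std::string& mode) {
  if (mode == "sigmoid") return 1.0 / (1.0 + exp(-z));
  if (mode == "softmax") {
    mat e = exp(z.each_col() - max(z, 1));
    return e.each_col() / sum(e, 1);
  }
  Rcpp::stop("unknown output mode: " + mode);
}

struct DenseCache {
  std::vector<mat> A;  // activations, A[0] = input
  std::vector<mat> Z;  // pre-activations per layer
};

static mat dense_forward(const mat& X, const List& tW, const List& tb,
                         const std::string& act, const std::string& outmode,
                         DenseCache* cache) {
  int L = tW.size();
  mat A = X;
  if (cache) cache->A.push_back(A);
  for (int l = 0; l < L; ++l) {
    mat W = Rcpp::as<mat>(tW[l]);
    rowvec b = Rcpp::as<rowvec>(tb[l]);
    mat Z = A * W;
    Z.each_row() += b;
    if (cache) cache->Z.push_back(Z);
    if (l < L - 1) {
      A = activate(Z, act);
      if (cache) cache->A.push_back(A);
    } else {
      A = out_activate(Z, outmode);
    }
  }
  return A;
}

// returns gradient w.r.t. the dense input; fills per-layer weight/bias grads
static mat dense_backward(const DenseCache& cache, const List& tW,
                          const std::string& act, mat dZ,
                          std::vector<mat>& gW, std::vector<rowvec>& gb) {
  int L = tW.size();
  gW.resize(L);
  gb.resize(L);
  for (int l = L - 1; l >= 0; --l) {
    const mat& A_prev = cache.A[l];
    gW[l] = A_prev.t() * dZ;
    gb[l] = sum(dZ, 0);
    mat W = Rcpp::as<mat>(tW[l]);
    mat dA = dZ * W.t();
    if (l > 0) {
      dZ = dA % activate_deriv(cache.Z[l - 1], act);
    } else {
      return dA;
    }
  }
  return mat();
}

// mean loss over all m x K outputs, and gradient w.r.t. output pre-activations
static double loss_and_dz(const mat& P, const mat& Y, const std::string& loss,
                          const std::string& outmode, mat& dZ) {
  double denom = (double)(P.n_rows * P.n_cols);
  mat Pc = clamp(P, 1e-7, 1.0 - 1e-7);
  double L;
  mat dP;
  if (loss == "bce") {
    L = accu(-(Y % log(Pc) + (1.0 - Y) % log(1.0 - Pc))) / denom;
    dP = (Pc - Y) / (Pc % (1.0 - Pc)) / denom;
  } else if (loss == "mse") {
    L = accu(square(P - Y)) / denom;
    dP = 2.0 * (P - Y) / denom;
  } else {
    Rcpp::stop("unknown loss: " + loss);
  }
  if (outmode == "sigmoid") {
    dZ = dP % (Pc % (1.0 - Pc));
  } else {  // softmax Jacobian per row
    dZ.set_size(P.n_rows, P.n_cols);
    for (uword s = 0; s < P.n_rows; ++s) {
      rowvec p = P.row(s);
      rowvec g = dP.row(s);
      dZ.row(s) = p % (g - dot(g, p));
    }
  }
  return L;
}

static double score_scale_value(const std::string& score_scale, int d) {
  if (score_scale == "sqrt") return std::sqrt((double)d);
  if (score_scale == "linear") return (double)d;
  Rcpp::stop("unknown score_scale: " + score_scale);
}

// Per-sample token embedding + scaled dot-product attention + mean pooling.
// In grad mode (dPool non-null) accumulates gradients into gW/gB.
static mat group_attention_pooled(const mat& V, const mat& W, const mat& B,
                                  double scl, const mat* dPool,
                                  mat* gW, mat* gB) {
  const uword m = V.n_rows, n = V.n_cols, d = W.n_cols;
  mat pooled(m, d);
  for (uword s = 0; s < m; ++s) {
    vec v = V.row(s).t();
    mat X = W;
    X.each_col() %= v;
    X += B;
    mat S = X * X.t() / scl;
    vec mx = max(S, 1);
    mat A = exp(S.each_col() - mx);
    vec rs = sum(A, 1);
    A.each_col() /= rs;
    mat C = A * X;
    pooled.row(s) = mean(C, 0);
    if (dPool) {
      rowvec dp = dPool->row(s) / (double)n;
      mat dC = repmat(dp, n, 1);
      mat dX = A.t() * dC;
      mat dA = dC * X.t();
      mat dS(n, n);
      for (uword i = 0; i < n; ++i) {
        rowvec a = A.row(i);
        rowvec da = dA.row(i);
        dS.row(i) = a % (da - dot(da, a));
      }
      dX += (dS + dS.t()) * X / scl;
      *gB += dX;
      dX.each_col() %= v;
      *gW += dX;
    }
  }
  return pooled;
}

static mat modular_trunk_input(const List& Vg, const mat& direct,
                               const List& eW, const List& eB,
                               double scl) {
  int G = Vg.size();
  uword m = Rcpp::as<mat>(Vg[0]).n_rows;
  uword d = Rcpp::as<mat>(eW[0]).n_cols;
  mat trunk_in(m, G * d + direct.n_cols);
  for (int g = 0; g < G; ++g) {
    mat V = Rcpp::as<mat>(Vg[g]);
    mat W = Rcpp::as<mat>(eW[g]);
    mat B = Rcpp::as<mat>(eB[g]);
    trunk_in.cols(g * d, (g + 1) * d - 1) =
      group_attention_pooled(V, W, B, scl, nullptr, nullptr, nullptr);
  }
  if (direct.n_cols > 0) trunk_in.cols(G * d, trunk_in.n_cols - 1) = direct;
  return trunk_in;
}

// [[Rcpp::export]]
List cpp_modular_forward(List Vg, arma::mat direct, List eW, List eB,
                         List tW, List tb, std::string act,
                         std::string outmode, std::string score_scale) {
  uword d = Rcpp::as<mat>(eW[0]).n_cols;
  double scl = score_scale_value(score_scale, d);
  mat trunk_in = modular_trunk_input(Vg, direct, eW, eB, scl);
  mat P = dense_forward(trunk_in, tW, tb, act, outmode, nullptr);
  return List::create(Rcpp::Named("probs") = P,
                      Rcpp::Named("trunk_input") = trunk_in);
}

// [[Rcpp::export]]
List cpp_modular_grad(List Vg, arma::mat direct, List eW, List eB,
                      List tW, List tb, std::string act, std::string outmode,
                      std::string score_scale, arma::mat Y, std::string loss) {
  int G = Vg.size();
  uword d = Rcpp::as<mat>(eW[0]).n_cols;
  double scl = score_scale_value(score_scale, d);
  mat trunk_in = modular_trunk_input(Vg, direct, eW, eB, scl);
  DenseCache cache;
  mat P = dense_forward(trunk_in, tW, tb, act, outmode, &cache);
  mat dZ;
  double L = loss_and_dz(P, Y, loss, outmode, dZ);
  std::vector<mat> gW;
  std::vector<rowvec> gb;
  mat dIn = dense_backward(cache, tW, act, dZ, gW, gb);
  List geW(G), geB(G);
  for (int g = 0; g < G; ++g) {
    mat V = Rcpp::as<mat>(Vg[g]);
    mat W = Rcpp::as<mat>(eW[g]);
    mat B = Rcpp::as<mat>(eB[g]);
    mat gWg(W.n_rows, W.n_cols, fill::zeros);
    mat gBg(B.n_rows, B.n_cols, fill::zeros);
    mat dPool = dIn.cols(g * d, (g + 1) * d - 1);
    group_attention_pooled(V, W, B, scl, &dPool, &gWg, &gBg);
    geW[g] = gWg;
    geB[g] = gBg;
  }
  List gtW(gW.size()), gtb(gb.size());
  for (size_t l = 0; l < gW.size(); ++l) {
    gtW[l] = gW[l];
    gtb[l] = Rcpp::NumericVector(gb[l].begin(), gb[l].end());
  }
  return List::create(
    Rcpp::Named("loss") = L, Rcpp::Named("probs") = P,
    Rcpp::Named("geW") = geW, Rcpp::Named("geB") = geB,
    Rcpp::Named("gtW") = gtW, Rcpp::Named("gtb") = gtb);
}

// [[Rcpp::export]]
arma::mat cpp_mlp_forward(arma::mat X, List tW, List tb, std::string act,
                          std::string outmode) {
  return dense_forward(X, tW, tb, act, outmode, nullptr);
}

// [[Rcpp::export]]
List cpp_mlp_grad(arma::mat X, List tW, List tb, std::string act,
                  std::string outmode, arma::mat Y, std::string loss) {
  DenseCache cache;
  mat P = dense_forward(X, tW, tb, act, outmode, &cache);
  mat dZ;
  double L = loss_and_dz(P, Y, loss, outmode, dZ);
  std::vector<mat> gW;
  std::vector<rowvec> gb;
  dense_backward(cache, tW, act, dZ, gW, gb);
  List gtW(gW.size()), gtb(gb.size());
  for (size_t l = 0; l < gW.size(); ++l) {
    gtW[l] = gW[l];
    gtb[l] = Rcpp::NumericVector(gb[l].begin(), gb[l].end());
  }
  return List::create(Rcpp::Named("loss") = L, Rcpp::Named("probs") = P,
                      Rcpp::Named("gtW") = gtW, Rcpp::Named("gtb") = gtb);
}

// Attention weight matrices for every sample of one group (interpretability
// export): returns an n x n x m cube.
// [[Rcpp::export]]
arma::cube cpp_attention_weights(arma::mat V, arma::mat W, arma::mat B,
                                 std::string score_scale) {
  const uword m = V.n_rows, n = V.n_cols, d = W.n_cols;
  double scl = score_scale_value(score_scale, d);
  cube out(n, n, m);
  for (uword s = 0; s < m; ++s) {
    vec v = V.row(s).t();
    mat X = W;
    X.each_col() %= v;
    X += B;
    mat S = X * X.t() / scl;
    vec mx = max(S, 1);
    mat A = exp(S.each_col() - mx);
    vec rs = sum(A, 1);
    A.each_col() /= rs;
    out.slice(s) = A;
  }
  return out;
}
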