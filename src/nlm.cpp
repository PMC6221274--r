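// Feed-forward neural language-model classifier: forward pass, analytic
// gradients of the regularized cross-entropy error, and the minibatch SGD
// loop. All randomness (weight init, epoch shuffles) is generated on the R
// side and passed in, so results are reproducible bit-for-bit from a seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Hidden layers use tanh; the output layer is affine followed by softmax.
// Activations for every layer are kept for backpropagation.
static void forward_pass(const std::vector<mat>& Ws,
                         const std::vector<rowvec>& bs,
                         const mat& V, const rowvec& k,
                         const mat& X,
                         std::vector<mat>& acts, mat& logits) {
  acts.clear();
  acts.push_back(X);
  for (size_t l = 0; l < Ws.size(); ++l) {
    mat Z = acts.back() * Ws[l];
    Z.each_row() += bs[l];
    acts.push_back(tanh(Z));
  }
  logits = acts.back() * V;
  logits.each_row() += k;
}

static mat softmax_rows(const mat& logits) {
  mat P = logits;
  P.each_col() -= max(P, 1);
  P = exp(P);
  P.each_col() /= sum(P, 1);
  return P;
}

// Mean negative log-likelihood over the rows of X (stable log-sum-exp),
// plus L1 on all weight matrices and L2 on hidden + output weights.
static double loss_value(const std::vector<mat>& Ws, const mat& V,
                         const mat& logits, const uvec& y,
                         double l1, double l2) {
  vec m = max(logits, 1);
  vec lse = m + log(sum(exp(logits.each_col() - m), 1));
  double nll = 0.0;
  for (uword i = 0; i < logits.n_rows; ++i)
    nll += lse(i) - logits(i, y(i));
  nll /= logits.n_rows;
  double pen = 0.0;
  for (const mat& W : Ws)
    pen += l1 * accu(abs(W)) + l2 * accu(square(W));
  pen += l1 * accu(abs(V)) + l2 * accu(square(V));
  return nll + pen;
}

// Backpropagation of the mean cross-entropy + penalty through the stored
// activations. Returns gradients in the same shapes as the parameters.
static void backward_pass(const std::vector<mat>& Ws, const mat& V,
                          const std::vector<mat>& acts, const mat& P,
                          const mat& T, double l1, double l2,
                          std::vector<mat>& gW, std::vector<rowvec>& gb,
                          mat& gV, rowvec& gk) {
  const double m = static_cast<double>(P.n_rows);
  mat G = (P - T) / m;                      // d loss / d logits
  gV = acts.back().t() * G + l1 * sign(V) + 2.0 * l2 * V;
  gk = sum(G, 0);
  mat dA = G * V.t();
  gW.assign(Ws.size(), mat());
  gb.assign(Ws.size(), rowvec());
  for (int l = static_cast<int>(Ws.size()) - 1; l >= 0; --l) {
    mat dZ = dA % (1.0 - square(acts[l + 1]));   // tanh'
    gW[l] = acts[l].t() * dZ + l1 * sign(Ws[l]) + 2.0 * l2 * Ws[l];
    gb[l] = sum(dZ, 0);
    if (l > 0) dA = dZ * Ws[l].t();
  }
}

static std::vector<mat> as_mats(const Rcpp::List& L) {
  std::vector<mat> out;
  for (R_xlen_t i = 0; i < L.size(); ++i)
    out.push_back(Rcpp::as<mat>(L[i]));
  return out;
}

static std::vector<rowvec> as_rowvecs(const Rcpp::List& L) {
  std::vector<rowvec> out;
  for (R_xlen_t i = 0; i < L.size(); ++i)
    out.push_back(Rcpp::as<rowvec>(L[i]));
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_nlm_forward(Rcpp::List Ws_, Rcpp::List bs_,
                          arma::mat V, arma::rowvec k, arma::mat X) {
  std::vector<mat> Ws = as_mats(Ws_);
  std::vector<rowvec> bs = as_rowvecs(bs_);
  std::vector<mat> acts;
  mat logits;
  forward_pass(Ws, bs, V, k, X, acts, logits);
  return softmax_rows(logits);
}

// [[Rcpp::export]]
Rcpp::List cpp_nlm_loss_grad(Rcpp::List Ws_, Rcpp::List bs_,
                             arma::mat V, arma::rowvec k,
                             arma::mat X, arma::uvec y,
                             double l1, double l2) {
  std::vector<mat> Ws = as_mats(Ws_);
  std::vector<rowvec> bs = as_rowvecs(bs_);
  std::vector<mat> acts;
  mat logits;
  forward_pass(Ws, bs, V, k, X, acts, logits);
  mat P = softmax_rows(logits);
  mat T(P.n_rows, P.n_cols, fill::zeros);
  for (uword i = 0; i < y.n_elem; ++i) T(i, y(i)) = 1.0;
  std::vector<mat> gW;
  std::vector<rowvec> gb;
  mat gV;
  rowvec gk;
  backward_pass(Ws, V, acts, P, T, l1, l2, gW, gb, gV, gk);
  Rcpp::List gW_(gW.size()), gb_(gb.size());
  for (size_t l = 0; l < gW.size(); ++l) {
    gW_[l] = gW[l];
    gb_[l] = gb[l];
  }
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss_value(Ws, V, logits, y, l1, l2),
      Rcpp::Named("gW") = gW_, Rcpp::Named("gb") = gb_,
      Rcpp::Named("gV") = gV, Rcpp::Named("gk") = gk);
}

// Minibatch SGD. `order` is a 1-based n x epochs matrix of example
// permutations (one column per epoch, generated in R under the model seed).
// The last short minibatch of an epoch is kept. Per-epoch full-data
// training loss is recorded; if validation data are supplied, per-epoch
// validation percent error is recorded too. Training aborts (ok = false)
// as soon as the loss stops being finite.
// [[Rcpp::export]]
Rcpp::List cpp_nlm_sgd(Rcpp::List Ws_, Rcpp::List bs_,
                       arma::mat V, arma::rowvec k,
                       arma::mat X, arma::uvec y,
                       int epochs, int batch_size, double lr,
                       double l1, double l2,
                       arma::umat order,
                       Rcpp::Nullable<Rcpp::NumericMatrix> Xval_ = R_NilValue,
                       Rcpp::Nullable<Rcpp::IntegerVector> yval_ = R_NilValue) {
  std::vector<mat> Ws = as_mats(Ws_);
  std::vector<rowvec> bs = as_rowvecs(bs_);
  const uword n = X.n_rows;
  const uword C = V.n_cols;

  mat Xval;
  uvec yval;
  bool has_val = Xval_.isNotNull();
  if (has_val) {
    Xval = Rcpp::as<mat>(Xval_.get());
    Rcpp::IntegerVector yv(yval_.get());
    yval.set_size(yv.size());
    for (R_xlen_t i = 0; i < yv.size(); ++i) yval(i) = yv[i];
  }

  vec train_loss(epochs, fill::value(datum::nan));
  vec val_err(has_val ? epochs : 0, fill::value(datum::nan));
  bool ok = true;
  int stopped_at = epochs;

  std::vector<mat> acts;
  mat logits;
  for (int e = 0; e < epochs; ++e) {
    uvec perm = order.col(e) - 1;
    for (uword start = 0; start < n; start += batch_size) {
      uword stop = std::min<uword>(start + batch_size, n) - 1;
      uvec idx = perm.subvec(start, stop);
      mat Xb = X.rows(idx);
      uvec yb = y.elem(idx);
      forward_pass(Ws, bs, V, k, Xb, acts, logits);
      mat P = softmax_rows(logits);
      mat T(P.n_rows, C, fill::zeros);
      for (uword i = 0; i < yb.n_elem; ++i) T(i, yb(i)) = 1.0;
      std::vector<mat> gW;
      std::vector<rowvec> gb;
      mat gV;
      rowvec gk;
      backward_pass(Ws, V, acts, P, T, l1, l2, gW, gb, gV, gk);
      for (size_t l = 0; l < Ws.size(); ++l) {
        Ws[l] -= lr * gW[l];
        bs[l] -= lr * gb[l];
      }
      V -= lr * gV;
      k -= lr * gk;
    }
    forward_pass(Ws, bs, V, k, X, acts, logits);
    train_loss(e) = loss_value(Ws, V, logits, y, l1, l2);
    if (has_val) {
      forward_pass(Ws, bs, V, k, Xval, acts, logits);
      uvec pred = index_max(logits, 1);
      val_err(e) = 100.0 * accu(pred != yval) /
                   static_cast<double>(yval.n_elem);
    }
    if (!std::isfinite(train_loss(e))) {
      ok = false;
      stopped_at = e + 1;
      break;
    }
  }

  Rcpp::List Ws_out(Ws.size()), bs_out(bs.size());
  for (size_t l = 0; l < Ws.size(); ++l) {
    Ws_out[l] = Ws[l];
    bs_out[l] = bs[l];
  }
  return Rcpp::List::create(
      Rcpp::Named("Ws") = Ws_out, Rcpp::Named("bs") = bs_out,
      Rcpp::Named("V") = V, Rcpp::Named("k") = k,
      Rcpp::Named("train_loss") = train_loss,
      Rcpp::Named("val_error") = val_err,
      Rcpp::Named("ok") = ok,
      Rcpp::Named("stopped_at") = stopped_at);
}
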