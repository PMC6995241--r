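// Mini-batch SGD training of the small feed-forward classifier.
// Deliberately RNG-free: weight initialization and the per-epoch shuffles
// are drawn from R's RNG and passed in, so every run is reproducible from
// a single integer seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Net {
  std::vector<arma::mat> W;
  std::vector<arma::rowvec> b;
};

Net unpack(const List& weights, const List& biases) {
  Net net;
  const int L = weights.size();
  for (int l = 0; l < L; ++l) {
    net.W.push_back(as<arma::mat>(weights[l]));
    net.b.push_back(as<arma::rowvec>(biases[l]));
  }
  return net;
}

// forward pass keeping pre-activations; returns row-wise softmax output
arma::mat forward(const Net& net, const arma::mat& X,
                  std::vector<arma::mat>& A, std::vector<arma::mat>& Z) {
  const size_t L = net.W.size();
  A.assign(L, arma::mat());
  Z.assign(L, arma::mat());
  arma::mat a = X;
  for (size_t l = 0; l < L; ++l) {
    A[l] = a;  // input to layer l
    arma::mat z = a * net.W[l];
    z.each_row() += net.b[l];
    Z[l] = z;
    if (l + 1 < L) {
      a = arma::clamp(z, 0.0, arma::datum::inf);  // relu
    } else {
      arma::vec m = arma::max(z, 1);              // stable softmax
      z.each_col() -= m;
      arma::mat e = arma::exp(z);
      arma::vec s = arma::sum(e, 1);
      e.each_col() /= s;
      a = e;
    }
  }
  return a;
}

// backprop of the mean categorical cross-entropy over the batch;
// fills grads, returns the batch loss
double backward(const Net& net, const arma::mat& X, const arma::ivec& y,
                std::vector<arma::mat>& dW, std::vector<arma::rowvec>& db) {
  const size_t L = net.W.size();
  const arma::uword n = X.n_rows;
  std::vector<arma::mat> A, Z;
  arma::mat P = forward(net, X, A, Z);

  double loss = 0.0;
  arma::mat delta = P;  // (P - onehot) / n
  for (arma::uword i = 0; i < n; ++i) {
    const arma::uword cls = static_cast<arma::uword>(y[i]);
    loss -= std::log(P(i, cls));
    delta(i, cls) -= 1.0;
  }
  loss /= static_cast<double>(n);
  delta /= static_cast<double>(n);

  dW.assign(L, arma::mat());
  db.assign(L, arma::rowvec());
  for (size_t l = L; l-- > 0;) {
    dW[l] = A[l].t() * delta;
    db[l] = arma::sum(delta, 0);
    if (l > 0) {
      arma::mat da = delta * net.W[l].t();
      delta = da % arma::conv_to<arma::mat>::from(Z[l - 1] > 0);  // relu'
    }
  }
  return loss;
}

List pack(const Net& net) {
  const size_t L = net.W.size();
  List W(L), b(L);
  for (size_t l = 0; l < L; ++l) {
    W[l] = net.W[l];
    b[l] = NumericVector(net.b[l].begin(), net.b[l].end());
  }
  return List::create(Named("weights") = W, Named("biases") = b);
}

}  // namespace

// [[Rcpp::export]]
List cpp_mlp_gradient(const arma::mat& X, const arma::ivec& y,
                      const List& weights, const List& biases) {
  Net net = unpack(weights, biases);
  std::vector<arma::mat> dW;
  std::vector<arma::rowvec> db;
  double loss = backward(net, X, y, dW, db);
  const size_t L = dW.size();
  List gW(L), gb(L);
  for (size_t l = 0; l < L; ++l) {
    gW[l] = dW[l];
    gb[l] = NumericVector(db[l].begin(), db[l].end());
  }
  return List::create(Named("grad_weights") = gW,
                      Named("grad_biases") = gb,
                      Named("loss") = loss);
}

// [[Rcpp::export]]
List cpp_train_mlp(const arma::mat& X, const arma::ivec& y,
                   const List& weights, const List& biases,
                   const arma::imat& perms, double lr, int batch_size) {
  Net net = unpack(weights, biases);
  const int epochs = perms.n_rows;
  const arma::uword n = X.n_rows;
  if (perms.n_cols != n) stop("permutation matrix does not match sample count");
  if (batch_size < 1) stop("batch_size must be >= 1");

  NumericVector losses(epochs);
  std::vector<arma::mat> dW;
  std::vector<arma::rowvec> db;

  for (int e = 0; e < epochs; ++e) {
    double epoch_loss = 0.0;
    arma::uword start = 0;
    while (start < n) {
      const arma::uword stop_at = std::min<arma::uword>(start + batch_size, n);
      const arma::uword nb = stop_at - start;
      arma::uvec idx(nb);
      for (arma::uword k = 0; k < nb; ++k) {
        idx[k] = static_cast<arma::uword>(perms(e, start + k)) - 1;  // 1-based
      }
      arma::mat Xb = X.rows(idx);
      arma::ivec yb(nb);
      for (arma::uword k = 0; k < nb; ++k) yb[k] = y[idx[k]];

      double batch_loss = backward(net, Xb, yb, dW, db);
      epoch_loss += batch_loss * static_cast<double>(nb);
      for (size_t l = 0; l < net.W.size(); ++l) {
        net.W[l] -= lr * dW[l];
        net.b[l] -= lr * db[l];
      }
      start = stop_at;
    }
    epoch_loss /= static_cast<double>(n);
    if (!std::isfinite(epoch_loss)) {
      stop("non-finite training loss at epoch %d", e + 1);
    }
    losses[e] = epoch_loss;
  }

  List out = pack(net);
  out["losses"] = losses;
  return out;
}
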