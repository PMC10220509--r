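// Dense feed-forward network with ReLU hidden layers, softmax or linear
// output, elastic-net weight penalty, and mini-batch Adam.  Training runs
// in single precision (the customary precision for this kind of
// stochastic-gradient training) and returns double-precision weights.
// All random numbers (weight initialization, per-epoch shuffling) come
// from R's RNG so that set.seed() in R makes training fully reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

inline void relu(arma::fmat& z) {
  z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
}

// row-wise softmax with max-subtraction for stability
inline void softmax_rows(arma::fmat& z) {
  z.each_col() -= arma::max(z, 1);
  z = arma::exp(z);
  z.each_col() /= arma::sum(z, 1);
}

// Fisher-Yates shuffle driven by R's RNG
void shuffle_r(arma::uvec& idx) {
  const arma::uword n = idx.n_elem;
  for (arma::uword i = n - 1; i > 0; --i) {
    arma::uword j = static_cast<arma::uword>(R::unif_rand() * (i + 1));
    if (j > i) j = i;  // guard against unif_rand() returning 1.0
    std::swap(idx[i], idx[j]);
  }
}

template <typename MatT>
MatT forward_pass(const MatT& X, const std::vector<MatT>& W,
                  const std::vector<MatT>& b, bool classify,
                  std::vector<MatT>* acts) {
  const int nlayer = static_cast<int>(W.size());
  MatT a = X;
  if (acts) (*acts)[0] = a;
  for (int l = 0; l < nlayer; ++l) {
    MatT z = a * W[l];
    z.each_row() += b[l];
    if (l < nlayer - 1) {
      z.transform([](typename MatT::elem_type v) {
        return v > 0 ? v : static_cast<typename MatT::elem_type>(0);
      });
    } else if (classify) {
      z.each_col() -= arma::max(z, 1);
      z = arma::exp(z);
      z.each_col() /= arma::sum(z, 1);
    }
    a = std::move(z);
    if (acts) (*acts)[l + 1] = a;
  }
  return a;
}

}  // namespace

// [[Rcpp::export]]
List nn_train_cpp(const arma::mat& X_in, const arma::mat& Y_in,
                  const arma::uvec& hidden, bool classify, double lambda,
                  double gamma, double lr_in, double beta1_in,
                  double beta2_in, int batch_size, int epochs) {
  const arma::fmat X = arma::conv_to<arma::fmat>::from(X_in);
  const arma::fmat Y = arma::conv_to<arma::fmat>::from(Y_in);
  const arma::uword N = X.n_rows;
  const arma::uword p = X.n_cols;
  const arma::uword K = Y.n_cols;
  const float lam = static_cast<float>(lambda);
  const float gam = static_cast<float>(gamma);
  const float lr = static_cast<float>(lr_in);
  const float beta1 = static_cast<float>(beta1_in);
  const float beta2 = static_cast<float>(beta2_in);
  const float adam_eps = 1e-8f;

  std::vector<arma::uword> sizes;
  sizes.push_back(p);
  for (arma::uword l = 0; l < hidden.n_elem; ++l) sizes.push_back(hidden[l]);
  sizes.push_back(K);
  const int nlayer = static_cast<int>(sizes.size()) - 1;

  // Glorot-uniform weights, zero biases
  std::vector<arma::fmat> W(nlayer), b(nlayer), mW(nlayer), vW(nlayer),
      mb(nlayer), vb(nlayer);
  for (int l = 0; l < nlayer; ++l) {
    const double limit = std::sqrt(6.0 / (sizes[l] + sizes[l + 1]));
    W[l].set_size(sizes[l], sizes[l + 1]);
    for (arma::uword i = 0; i < W[l].n_elem; ++i)
      W[l][i] = static_cast<float>((2.0 * R::unif_rand() - 1.0) * limit);
    b[l].zeros(1, sizes[l + 1]);
    mW[l].zeros(arma::size(W[l]));
    vW[l].zeros(arma::size(W[l]));
    mb[l].zeros(arma::size(b[l]));
    vb[l].zeros(arma::size(b[l]));
  }

  arma::uvec idx = arma::regspace<arma::uvec>(0, N - 1);
  std::vector<arma::fmat> acts(nlayer + 1);
  arma::vec epoch_loss(epochs, arma::fill::zeros);
  long t = 0;  // Adam step counter

  for (int ep = 0; ep < epochs; ++ep) {
    shuffle_r(idx);
    double data_loss = 0.0;
    for (arma::uword start = 0; start < N; start += batch_size) {
      const arma::uword stop = std::min(N - 1, start + batch_size - 1);
      const arma::uvec batch = idx.subvec(start, stop);
      const arma::uword nb = batch.n_elem;
      const arma::fmat Xb = X.rows(batch);
      const arma::fmat Yb = Y.rows(batch);

      arma::fmat out = forward_pass(Xb, W, b, classify, &acts);

      // batch contribution to the (unpenalized) mean training loss
      if (classify) {
        data_loss += -arma::accu(Yb % arma::log(out + 1e-12f));
      } else {
        data_loss += arma::accu(arma::square(out - Yb)) / K;
      }

      // output-layer error for mean cross-entropy (softmax) or mean
      // squared error (linear, averaged over observations and outputs)
      arma::fmat delta = out - Yb;
      if (classify) delta /= static_cast<float>(nb);
      else delta *= 2.0f / static_cast<float>(nb * K);

      ++t;
      const float bc1 = 1.0f - std::pow(beta1, static_cast<float>(t));
      const float bc2 = 1.0f - std::pow(beta2, static_cast<float>(t));
      for (int l = nlayer - 1; l >= 0; --l) {
        arma::fmat gW = acts[l].t() * delta;
        if (lam > 0.0f)
          gW += lam * (2.0f * (1.0f - gam) * W[l] + gam * arma::sign(W[l]));
        arma::fmat gb = arma::sum(delta, 0);
        if (l > 0) {  // propagate through ReLU
          delta = delta * W[l].t();
          const arma::fmat& a = acts[l];
          for (arma::uword i = 0; i < delta.n_elem; ++i)
            if (a[i] <= 0.0f) delta[i] = 0.0f;
        }

        mW[l] = beta1 * mW[l] + (1.0f - beta1) * gW;
        vW[l] = beta2 * vW[l] + (1.0f - beta2) * arma::square(gW);
        W[l] -= lr * (mW[l] / bc1) / (arma::sqrt(vW[l] / bc2) + adam_eps);
        mb[l] = beta1 * mb[l] + (1.0f - beta1) * gb;
        vb[l] = beta2 * vb[l] + (1.0f - beta2) * arma::square(gb);
        b[l] -= lr * (mb[l] / bc1) / (arma::sqrt(vb[l] / bc2) + adam_eps);
      }
    }
    epoch_loss[ep] = data_loss / N;
    if (!std::isfinite(epoch_loss[ep]))
      stop("training diverged: non-finite loss at epoch %d", ep + 1);
    if ((ep & 31) == 0) Rcpp::checkUserInterrupt();
  }

  List Wout(nlayer), bout(nlayer);
  for (int l = 0; l < nlayer; ++l) {
    Wout[l] = arma::conv_to<arma::mat>::from(W[l]);
    bout[l] = arma::conv_to<arma::mat>::from(b[l]);
  }
  return List::create(Named("weights") = Wout, Named("biases") = bout,
                      Named("epoch_loss") = NumericVector(
                          epoch_loss.begin(), epoch_loss.end()));
}

// [[Rcpp::export]]
arma::mat nn_forward_cpp(const arma::mat& X, const List& weights,
                         const List& biases, bool classify) {
  std::vector<arma::mat> W, b;
  for (R_xlen_t i = 0; i < weights.size(); ++i) {
    W.push_back(as<arma::mat>(weights[i]));
    b.push_back(as<arma::mat>(biases[i]));
  }
  return forward_pass<arma::mat>(X, W, b, classify, nullptr);
}
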