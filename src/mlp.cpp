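// Multilayer-perceptron training core: mini-batch Adam on softmax
// cross-entropy with inverted dropout and patience-based early stopping.
// All randomness (weight init, batch order, dropout masks) comes from one
// std::mt19937 seeded by the caller, so training is deterministic given
// the seed and single-threaded by construction.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;

static arma::mat softmax_rows(const arma::mat& z) {
  arma::vec m = arma::max(z, 1);
  arma::mat e = arma::exp(z.each_col() - m);
  arma::vec s = arma::sum(e, 1);
  return e.each_col() / s;
}

// [[Rcpp::export]]
List mlp_train_cpp(const arma::mat& X, const arma::mat& target,
                   const IntegerVector& hidden, double dropout,
                   double learning_rate, int batch_size, int patience,
                   int max_epochs, int seed, double tol) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  std::vector<arma::uword> widths;
  widths.push_back(p);
  for (int h : hidden) widths.push_back((arma::uword)h);
  widths.push_back(target.n_cols);
  const size_t L = widths.size() - 1;

  std::mt19937 rng((uint32_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<arma::mat> W(L), mW(L), vW(L);
  std::vector<arma::rowvec> b(L), mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    W[l].set_size(widths[l], widths[l + 1]);
    double sd = std::sqrt(2.0 / (double)widths[l]);
    for (arma::uword j = 0; j < W[l].n_cols; ++j)     // column-major fill so
      for (arma::uword i = 0; i < W[l].n_rows; ++i)   // draws map to layout
        W[l](i, j) = gauss(rng) * sd;
    b[l] = arma::rowvec(widths[l + 1], arma::fill::zeros);
    mW[l] = arma::mat(widths[l], widths[l + 1], arma::fill::zeros);
    vW[l] = mW[l];
    mb[l] = b[l]; vb[l] = b[l];
  }

  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  double best = arma::datum::inf;
  int streak = 0, epoch = 0;
  long t_step = 0;
  std::vector<double> epoch_losses;
  std::vector<arma::uword> order(n);
  for (arma::uword i = 0; i < n; ++i) order[i] = i;

  std::vector<arma::mat> acts(L + 1), masks(L);

  while (epoch < max_epochs) {
    ++epoch;
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    for (arma::uword s = 0; s < n; s += batch_size) {
      arma::uword e = std::min<arma::uword>(s + batch_size, n) - 1;
      arma::uvec idx(e - s + 1);
      for (arma::uword i = s; i <= e; ++i) idx[i - s] = order[i];
      const arma::uword m = idx.n_elem;
      acts[0] = X.rows(idx);
      arma::mat tb = target.rows(idx);
      for (size_t l = 0; l < L; ++l) {
        arma::mat z = acts[l] * W[l];
        z.each_row() += b[l];
        if (l + 1 < L) {
          z.transform([](double v) { return v > 0.0 ? v : 0.0; });
          if (dropout > 0.0) {
            arma::mat mask(z.n_rows, z.n_cols);
            const double keep = 1.0 - dropout;
            for (arma::uword j = 0; j < mask.n_cols; ++j)
              for (arma::uword i = 0; i < mask.n_rows; ++i)
                mask(i, j) = (unif(rng) >= dropout) ? 1.0 / keep : 0.0;
            z %= mask;
            masks[l] = mask;
          } else {
            masks[l].reset();
          }
        }
        acts[l + 1] = z;
      }
      arma::mat prob = softmax_rows(acts[L]);
      double loss = -arma::accu(tb % arma::log(arma::clamp(prob, 1e-12, 1.0))) / m;
      if (!std::isfinite(loss)) {
        stop("MLP training aborted: non-finite loss at epoch %d", epoch);
      }
      ep_loss += loss * m;
      arma::mat delta = (prob - tb) / (double)m;
      ++t_step;
      const double c1 = 1.0 - std::pow(b1, (double)t_step);
      const double c2 = 1.0 - std::pow(b2, (double)t_step);
      for (size_t li = L; li-- > 0;) {
        arma::mat gW = acts[li].t() * delta;
        arma::rowvec gb = arma::sum(delta, 0);
        if (li > 0) {
          delta = delta * W[li].t();
          if (masks[li - 1].n_elem) delta %= masks[li - 1];
          delta.elem(arma::find(acts[li] <= 0.0)).zeros();
        }
        mW[li] = b1 * mW[li] + (1.0 - b1) * gW;
        vW[li] = b2 * vW[li] + (1.0 - b2) * (gW % gW);
        mb[li] = b1 * mb[li] + (1.0 - b1) * gb;
        vb[li] = b2 * vb[li] + (1.0 - b2) * (gb % gb);
        W[li] -= learning_rate * (mW[li] / c1) / (arma::sqrt(vW[li] / c2) + eps);
        b[li] -= learning_rate * (mb[li] / c1) / (arma::sqrt(vb[li] / c2) + eps);
      }
    }
    ep_loss /= (double)n;
    epoch_losses.push_back(ep_loss);
    if (ep_loss < best - tol) {
      best = ep_loss;
      streak = 0;
    } else {
      ++streak;
      if (streak >= patience) break;
    }
  }

  List Wl(L), bl(L);
  for (size_t l = 0; l < L; ++l) {
    Wl[l] = W[l];
    bl[l] = NumericVector(b[l].begin(), b[l].end());
  }
  return List::create(_["W"] = Wl, _["b"] = bl, _["epochs"] = epoch,
                      _["best_loss"] = best,
                      _["epoch_loss"] = NumericVector(epoch_losses.begin(),
                                                      epoch_losses.end()));
}

// [[Rcpp::export]]
arma::mat mlp_forward_cpp(const arma::mat& X, const List& Wl, const List& bl) {
  arma::mat a = X;
  const size_t L = Wl.size();
  for (size_t l = 0; l < L; ++l) {
    arma::mat W = as<arma::mat>(Wl[l]);
    arma::rowvec b = as<arma::rowvec>(bl[l]);
    a = a * W;
    a.each_row() += b;
    if (l + 1 < L) a.transform([](double v) { return v > 0.0 ? v : 0.0; });
  }
  return softmax_rows(a);
}
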