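#include <Rcpp.h>
using namespace Rcpp;

// best-matching node: minimal squared Euclidean distance, ties -> lowest index
static int find_bmu(const NumericMatrix& W, const double* x, int K, int D) {
  int best = 0;
  double bestd = R_PosInf;
  for (int k = 0; k < K; ++k) {
    double d = 0.0;
    for (int j = 0; j < D; ++j) {
      double diff = W(k, j) - x[j];
      d += diff * diff;
      if (d >= bestd) break;
    }
    if (d < bestd) { bestd = d; best = k; }
  }
  return best;
}

// Sequential Kohonen training with Gaussian neighborhood and linearly
// decaying alpha/sigma per epoch. Fully deterministic: profiles are
// presented in input order, ties break to the lowest node index.
// [[Rcpp::export]]
List som_train_cpp(NumericMatrix X, NumericMatrix W0, IntegerMatrix coords,
                   int epochs, double alpha_start, double alpha_end,
                   double sigma_start, double sigma_end) {
  const int N = X.nrow(), D = X.ncol(), K = W0.nrow();
  NumericMatrix W = clone(W0);
  std::vector<double> row(K), col(K);
  for (int k = 0; k < K; ++k) {
    row[k] = coords(k, 0);
    col[k] = coords(k, 1);
  }
  std::vector<double> x(D);
  for (int e = 0; e < epochs; ++e) {
    double f = (epochs == 1) ? 0.0 : (double)e / (epochs - 1);
    double alpha = alpha_start + f * (alpha_end - alpha_start);
    double sigma = sigma_start + f * (sigma_end - sigma_start);
    double inv2s2 = 1.0 / (2.0 * sigma * sigma);
    for (int i = 0; i < N; ++i) {
      for (int j = 0; j < D; ++j) x[j] = X(i, j);
      int win = find_bmu(W, x.data(), K, D);
      double wr = row[win], wc = col[win];
      for (int k = 0; k < K; ++k) {
        double dr = row[k] - wr, dc = col[k] - wc;
        double h = std::exp(-(dr * dr + dc * dc) * inv2s2);
        double ah = alpha * h;
        for (int j = 0; j < D; ++j) W(k, j) += ah * (x[j] - W(k, j));
      }
    }
    if (e % 16 == 0) Rcpp::checkUserInterrupt();
  }
  IntegerVector assignment(N);
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < D; ++j) x[j] = X(i, j);
    assignment[i] = find_bmu(W, x.data(), K, D) + 1; // 1-based
  }
  return List::create(_["codebook"] = W, _["assignment"] = assignment);
}

// [[Rcpp::export]]
IntegerVector som_assign_cpp(NumericMatrix X, NumericMatrix W) {
  const int N = X.nrow(), D = X.ncol(), K = W.nrow();
  IntegerVector assignment(N);
  std::vector<double> x(D);
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < D; ++j) x[j] = X(i, j);
    assignment[i] = find_bmu(W, x.data(), K, D) + 1;
  }
  return assignment;
}
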