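#include <Rcpp.h>
using namespace Rcpp;

// Lloyd 2-means on an n x p matrix stored row-major in `x`.
// Returns the minimal within-cluster sum of squares found over `nstart`
// random initializations (pairs of distinct observation rows).
static double best_two_means_wss(const std::vector<double> &x, int n, int p,
                                 int nstart, int maxit) {
  std::vector<int> assign(n), newassign(n);
  std::vector<double> c1(p), c2(p);
  double best = R_PosInf;
  for (int s = 0; s < nstart; ++s) {
    int i1 = (int)(unif_rand() * n);
    int i2 = (int)(unif_rand() * (n - 1));
    if (i2 >= i1) ++i2;
    for (int j = 0; j < p; ++j) {
      c1[j] = x[i1 * p + j];
      c2[j] = x[i2 * p + j];
    }
    std::fill(assign.begin(), assign.end(), -1);
    for (int it = 0; it < maxit; ++it) {
      bool changed = false;
      int n1 = 0;
      for (int i = 0; i < n; ++i) {
        double d1 = 0.0, d2 = 0.0;
        const double *row = &x[i * p];
        for (int j = 0; j < p; ++j) {
          double a = row[j] - c1[j];
          double b = row[j] - c2[j];
          d1 += a * a;
          d2 += b * b;
        }
        int a = d1 <= d2 ? 0 : 1;
        newassign[i] = a;
        if (a != assign[i]) changed = true;
        if (a == 0) ++n1;
      }
      // keep both clusters non-empty: reassign farthest point if needed
      if (n1 == 0 || n1 == n) {
        int target = (n1 == 0) ? 0 : 1;
        double worst = -1.0;
        int worst_i = 0;
        const std::vector<double> &cc = (n1 == 0) ? c2 : c1;
        for (int i = 0; i < n; ++i) {
          double d = 0.0;
          const double *row = &x[i * p];
          for (int j = 0; j < p; ++j) {
            double a = row[j] - cc[j];
            d += a * a;
          }
          if (d > worst) { worst = d; worst_i = i; }
        }
        newassign[worst_i] = target;
        changed = true;
        n1 = (n1 == 0) ? 1 : n - 1;
      }
      assign.swap(newassign);
      // update centroids
      std::fill(c1.begin(), c1.end(), 0.0);
      std::fill(c2.begin(), c2.end(), 0.0);
      int m1 = 0, m2 = 0;
      for (int i = 0; i < n; ++i) {
        const double *row = &x[i * p];
        if (assign[i] == 0) {
          ++m1;
          for (int j = 0; j < p; ++j) c1[j] += row[j];
        } else {
          ++m2;
          for (int j = 0; j < p; ++j) c2[j] += row[j];
        }
      }
      for (int j = 0; j < p; ++j) {
        c1[j] /= m1 > 0 ? m1 : 1;
        c2[j] /= m2 > 0 ? m2 : 1;
      }
      if (!changed) break;
    }
    double wss = 0.0;
    for (int i = 0; i < n; ++i) {
      const double *row = &x[i * p];
      const std::vector<double> &cc = assign[i] == 0 ? c1 : c2;
      for (int j = 0; j < p; ++j) {
        double a = row[j] - cc[j];
        wss += a * a;
      }
    }
    if (wss < best) best = wss;
  }
  return best;
}

static double total_ss(const std::vector<double> &x, int n, int p) {
  std::vector<double> mean(p, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) mean[j] += x[i * p + j];
  for (int j = 0; j < p; ++j) mean[j] /= n;
  double tss = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) {
      double a = x[i * p + j] - mean[j];
      tss += a * a;
    }
  return tss;
}

// [[Rcpp::export(name = ".cpp_two_means_ci")]]
double cpp_two_means_ci(NumericMatrix X, int nstart = 5, int maxit = 50) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> x(n * p);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) x[i * p + j] = X(i, j);
  double tss = total_ss(x, n, p);
  if (tss <= 0.0) return 1.0;
  return best_two_means_wss(x, n, p, nstart, maxit) / tss;
}

// Null distribution of the 2-means cluster index under a single
// multivariate Gaussian with diagonal covariance `eigvals` (only the
// eigenvalue spectrum matters: the index is rotation invariant).
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export(name = ".cpp_null_cluster_indices")]]
NumericVector cpp_null_cluster_indices(int n, NumericVector eigvals,
                                       int nsim, int nstart = 3,
                                       int maxit = 50) {
  int p = eigvals.size();
  std::vector<double> sd(p);
  for (int j = 0; j < p; ++j) sd[j] = std::sqrt(eigvals[j]);
  NumericVector out(nsim);
  std::vector<double> x(n * p);
  for (int s = 0; s < nsim; ++s) {
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < p; ++j) x[i * p + j] = norm_rand() * sd[j];
    double tss = total_ss(x, n, p);
    out[s] = tss <= 0.0 ? 1.0 : best_two_means_wss(x, n, p, nstart, maxit) / tss;
  }
  return out;
}
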