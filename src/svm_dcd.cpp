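#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L1-hinge linear SVM
//   min_w 0.5 ||w||^2 + sum_i C_i max(0, 1 - y_i w.x_i)
// with the bias handled as an augmented constant feature (value 1),
// i.e. the liblinear "-B 1" formulation.  The visiting order is
// re-permuted every epoch (which is what makes coordinate descent
// converge quickly) using an internal fixed-seed xorshift generator,
// so identical inputs still give identical solutions bit for bit.
//
// X: n x d pattern matrix, y: +1/-1, Ci: per-sample cost (cost times
// the class weight).  Returns w (length d), b, epochs, converged.
// [[Rcpp::export]]
List svm_dcd(NumericMatrix X, IntegerVector y, NumericVector Ci,
             int max_epochs = 2000, double tol = 0.01) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> w(d + 1, 0.0), alpha(n, 0.0), qii(n);
  std::vector<int> order(n);

  for (int i = 0; i < n; ++i) {
    order[i] = i;
    double s = 1.0;  // augmented bias feature
    for (int j = 0; j < d; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }

  uint64_t rng = 88172645463325252ull;  // fixed-seed xorshift
  auto nextRand = [&rng]() {
    rng ^= rng << 13; rng ^= rng >> 7; rng ^= rng << 17;
    return rng;
  };

  // Projected-gradient descent over the dual box, with the standard
  // shrinking heuristic: samples whose alpha sits at a bound with a
  // safely-signed gradient leave the active set until convergence is
  // re-checked over all samples.
  const double INF = std::numeric_limits<double>::infinity();
  int active = n, epoch = 0;
  bool converged = false;
  double PGmax_old = INF, PGmin_old = -INF;
  for (; epoch < max_epochs; ++epoch) {
    double PGmax_new = -INF, PGmin_new = INF;
    for (int i = active - 1; i > 0; --i)
      std::swap(order[i], order[nextRand() % (i + 1)]);
    for (int k = 0; k < active; ++k) {
      int i = order[k];
      double wx = w[d];
      for (int j = 0; j < d; ++j) wx += w[j] * X(i, j);
      double G = y[i] * wx - 1.0;  // gradient of the dual objective

      double PG = 0.0;
      if (alpha[i] <= 0.0) {
        if (G > PGmax_old) {       // shrink: stuck at lower bound
          --active;
          std::swap(order[k], order[active]);
          --k;
          continue;
        }
        if (G < 0.0) PG = G;
      } else if (alpha[i] >= Ci[i]) {
        if (G < PGmin_old) {       // shrink: stuck at upper bound
          --active;
          std::swap(order[k], order[active]);
          --k;
          continue;
        }
        if (G > 0.0) PG = G;
      } else PG = G;
      if (PG > PGmax_new) PGmax_new = PG;
      if (PG < PGmin_new) PGmin_new = PG;

      if (std::fabs(PG) > 1e-12) {
        double a_old = alpha[i];
        double a_new = a_old - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > Ci[i]) a_new = Ci[i];
        double delta = (a_new - a_old) * y[i];
        if (delta != 0.0) {
          for (int j = 0; j < d; ++j) w[j] += delta * X(i, j);
          w[d] += delta;
          alpha[i] = a_new;
        }
      }
    }
    if (PGmax_new - PGmin_new <= tol) {
      if (active == n) { converged = true; break; }
      active = n;                  // re-check over the full set
      PGmax_old = INF; PGmin_old = -INF;
      continue;
    }
    PGmax_old = PGmax_new > 0.0 ? PGmax_new : INF;
    PGmin_old = PGmin_new < 0.0 ? PGmin_new : -INF;
  }

  NumericVector wv(d);
  for (int j = 0; j < d; ++j) wv[j] = w[j];
  return List::create(_["w"] = wv, _["b"] = w[d],
                      _["epochs"] = epoch + 1, _["converged"] = converged);
}

// Leave-one-run-out cross-validation accuracy for a binary contrast,
// entirely in compiled code: the permutation-null machinery calls this
// once per subject per shuffle, so the R-level overhead matters.
//
// X: n x d patterns (rows already restricted to the contrast classes),
// y: +1/-1, run: integer run id per pattern, balance: use class
// weights n/(2 n_c).  Ties on the decision boundary go to the positive
// class.  Returns c(correct, total, hits, misses, fa, cr).
// [[Rcpp::export]]
NumericVector cv_loro_accuracy(NumericMatrix X, IntegerVector y,
                               IntegerVector run, double cost = 1.0,
                               bool balance = true, int max_epochs = 2000,
                               double tol = 0.01) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<int> runs;
  for (int i = 0; i < n; ++i)
    if (std::find(runs.begin(), runs.end(), run[i]) == runs.end())
      runs.push_back(run[i]);

  double correct = 0, total = 0, hits = 0, misses = 0, fa = 0, cr = 0;

  for (size_t r = 0; r < runs.size(); ++r) {
    int test_run = runs[r];
    std::vector<int> tr, te;
    int npos = 0, nneg = 0;
    for (int i = 0; i < n; ++i) {
      if (run[i] == test_run) te.push_back(i);
      else {
        tr.push_back(i);
        if (y[i] > 0) ++npos; else ++nneg;
      }
    }
    if (npos == 0 || nneg == 0 || te.empty()) continue;  // degenerate fold

    int ntr = (int)tr.size();
    double wpos = 1.0, wneg = 1.0;
    if (balance) {
      wpos = ntr / (2.0 * npos);
      wneg = ntr / (2.0 * nneg);
    }
    NumericMatrix Xtr(ntr, d);
    IntegerVector ytr(ntr);
    NumericVector Ci(ntr);
    for (int a = 0; a < ntr; ++a) {
      int i = tr[a];
      for (int j = 0; j < d; ++j) Xtr(a, j) = X(i, j);
      ytr[a] = y[i];
      Ci[a] = cost * (y[i] > 0 ? wpos : wneg);
    }
    List fit = svm_dcd(Xtr, ytr, Ci, max_epochs, tol);
    NumericVector w = fit["w"];
    double b = fit["b"];

    for (size_t a = 0; a < te.size(); ++a) {
      int i = te[a];
      double f = b;
      for (int j = 0; j < d; ++j) f += w[j] * X(i, j);
      int pred = (f >= 0.0) ? 1 : -1;  // tie -> positive class
      if (y[i] > 0) { if (pred > 0) { ++hits; ++correct; } else ++misses; }
      else          { if (pred < 0) { ++cr;   ++correct; } else ++fa;     }
      ++total;
    }
  }
  return NumericVector::create(correct, total, hits, misses, fa, cr);
}
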