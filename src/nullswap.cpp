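// Margin-preserving binary matrix randomization.
//
// quasiswap_binarize: reduce a random integer matrix with the target
// margins to a 0/1 matrix by 2x2 "quasiswap" updates that never increase
// the sum of squares, then remove the constructive bias of that reduction
// with trial-swap mixing (pick a random 2x2 submatrix; if it is a
// checkerboard, swap it; every trial counts as a chain step).  The
// trial-swap chain has a symmetric transition kernel, so its stationary
// distribution over the margin class is uniform.
//
// curveball_trades: sequential pairwise row-trade randomization; each trade
// reshuffles the symmetric difference of two random rows.
//
// Both use R's RNG so results are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline int runif_int(int n) {
  int k;
  do {
    k = (int)(unif_rand() * n);
  } while (k >= n); // guard against unif_rand() == 1.0
  return k;
}

// [[Rcpp::export]]
IntegerMatrix quasiswap_binarize(IntegerMatrix x, int mix_trials) {
  IntegerMatrix m = clone(x);
  const int nr = m.nrow(), nc = m.ncol();
  if (nr < 2 || nc < 2) return m;
  // cells with value > 1, tracked lazily (entries may go stale)
  std::vector<int> over;
  long n_over = 0;
  for (int k = 0; k < nr * nc; k++)
    if (m[k] > 1) { over.push_back(k); n_over++; }
  // quasiswap reduction to binarity, targeting an excess cell directly;
  // any construction bias is removed by the trial-swap mixing below
  while (n_over > 0) {
    int pos = runif_int((int)over.size());
    int idx = over[pos];
    if (m[idx] <= 1) { // stale entry
      over[pos] = over.back();
      over.pop_back();
      continue;
    }
    int i1 = idx % nr, j1 = idx / nr;
    int i2 = runif_int(nr);
    if (i2 == i1) continue;
    int j2 = runif_int(nc);
    if (j2 == j1) continue;
    int a = m(i1, j1), b = m(i1, j2), c = m(i2, j1), d = m(i2, j2);
    if (d > 0 && a + d - b - c >= 2) {
      m(i1, j1) = a - 1; m(i2, j2) = d - 1;
      m(i1, j2) = b + 1; m(i2, j1) = c + 1;
      if (a == 2) n_over--;
      if (d == 2) n_over--;
      if (b == 1) { n_over++; over.push_back(i1 + nr * j2); }
      if (c == 1) { n_over++; over.push_back(i2 + nr * j1); }
    }
  }
  // trial-swap mixing on the binary matrix
  for (int t = 0; t < mix_trials; t++) {
    int i1 = runif_int(nr), i2 = runif_int(nr);
    if (i1 == i2) continue;
    int j1 = runif_int(nc), j2 = runif_int(nc);
    if (j1 == j2) continue;
    int a = m(i1, j1), b = m(i1, j2), c = m(i2, j1), d = m(i2, j2);
    if (a == 1 && d == 1 && b == 0 && c == 0) {
      m(i1, j1) = 0; m(i2, j2) = 0; m(i1, j2) = 1; m(i2, j1) = 1;
    } else if (a == 0 && d == 0 && b == 1 && c == 1) {
      m(i1, j1) = 1; m(i2, j2) = 1; m(i1, j2) = 0; m(i2, j1) = 0;
    }
  }
  return m;
}

// [[Rcpp::export]]
IntegerMatrix curveball_trades(IntegerMatrix x, int n_trades) {
  IntegerMatrix m = clone(x);
  const int nr = m.nrow(), nc = m.ncol();
  if (nr < 2 || nc < 2) return m;
  std::vector<int> pool(nc);
  for (int t = 0; t < n_trades; t++) {
    int r1 = runif_int(nr), r2 = runif_int(nr);
    if (r1 == r2) continue;
    int k = 0, n1 = 0;
    for (int j = 0; j < nc; j++) {
      int a = m(r1, j), b = m(r2, j);
      if (a == 1 && b == 0) { pool[k++] = j; n1++; }
      else if (a == 0 && b == 1) { pool[k++] = j; }
    }
    if (k < 2 || n1 == 0 || n1 == k) continue;
    // Fisher-Yates shuffle of the symmetric difference
    for (int i = k - 1; i > 0; i--) {
      int j = runif_int(i + 1);
      std::swap(pool[i], pool[j]);
    }
    for (int i = 0; i < k; i++) {
      int j = pool[i];
      if (i < n1) { m(r1, j) = 1; m(r2, j) = 0; }
      else        { m(r1, j) = 0; m(r2, j) = 1; }
    }
  }
  return m;
}
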