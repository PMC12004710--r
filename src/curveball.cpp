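#include <Rcpp.h>
using namespace Rcpp;

// Curveball trades on a binary matrix held as per-row sets of column
// indices. Each trade picks two rows and re-deals the columns private to
// either row; row and column sums are preserved exactly.

static void trade(std::vector<std::vector<int>>& rows, int r1, int r2) {
  std::vector<int>& a = rows[r1];
  std::vector<int>& b = rows[r2];
  std::vector<int> onlyA, onlyB, common;
  std::vector<char> inB(0);
  // rows are kept sorted; set operations by merge
  std::set_difference(a.begin(), a.end(), b.begin(), b.end(),
                      std::back_inserter(onlyA));
  std::set_difference(b.begin(), b.end(), a.begin(), a.end(),
                      std::back_inserter(onlyB));
  if (onlyA.empty() || onlyB.empty()) return;
  std::set_intersection(a.begin(), a.end(), b.begin(), b.end(),
                        std::back_inserter(common));
  std::vector<int> pool(onlyA);
  pool.insert(pool.end(), onlyB.begin(), onlyB.end());
  // Fisher-Yates shuffle with R's RNG
  for (int i = pool.size() - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    std::swap(pool[i], pool[j]);
  }
  std::vector<int> newA(pool.begin(), pool.begin() + onlyA.size());
  std::vector<int> newB(pool.begin() + onlyA.size(), pool.end());
  newA.insert(newA.end(), common.begin(), common.end());
  newB.insert(newB.end(), common.begin(), common.end());
  std::sort(newA.begin(), newA.end());
  std::sort(newB.begin(), newB.end());
  a.swap(newA);
  b.swap(newB);
}

static std::vector<std::vector<int>> toRows(const IntegerMatrix& m) {
  std::vector<std::vector<int>> rows(m.nrow());
  for (int i = 0; i < m.nrow(); ++i)
    for (int j = 0; j < m.ncol(); ++j)
      if (m(i, j) != 0) rows[i].push_back(j);
  return rows;
}

// [[Rcpp::export(name = ".curveballRandomizeCpp")]]
IntegerMatrix curveballRandomizeCpp(IntegerMatrix m, int steps) {
  std::vector<std::vector<int>> rows = toRows(m);
  int n = m.nrow();
  GetRNGstate();
  for (int s = 0; s < steps; ++s) {
    int r1 = (int)(unif_rand() * n);
    int r2 = (int)(unif_rand() * (n - 1));
    if (r2 >= r1) r2 += 1;
    trade(rows, r1, r2);
  }
  PutRNGstate();
  IntegerMatrix out(m.nrow(), m.ncol());
  for (int i = 0; i < n; ++i)
    for (size_t k = 0; k < rows[i].size(); ++k) out(i, rows[i][k]) = 1;
  out.attr("dimnames") = m.attr("dimnames");
  return out;
}

// Sample `n_perm` matrices (after `burnin` trades, `gap` trades between
// samples) and return the pairwise column overlap counts of each sample:
// a matrix n_perm x (p * (p - 1) / 2), pairs in column-major (i < j) order.
// [[Rcpp::export(name = ".curveballNullOverlapsCpp")]]
IntegerMatrix curveballNullOverlapsCpp(IntegerMatrix m, int n_perm,
                                       int burnin, int gap) {
  std::vector<std::vector<int>> rows = toRows(m);
  int n = m.nrow(), p = m.ncol();
  int npair = p * (p - 1) / 2;
  IntegerMatrix out(n_perm, npair);
  std::vector<int> colbuf(p);
  GetRNGstate();
  auto doTrades = [&](int k) {
    for (int s = 0; s < k; ++s) {
      int r1 = (int)(unif_rand() * n);
      int r2 = (int)(unif_rand() * (n - 1));
      if (r2 >= r1) r2 += 1;
      trade(rows, r1, r2);
    }
  };
  doTrades(burnin);
  std::vector<std::vector<char>> dense(n, std::vector<char>(p));
  for (int t = 0; t < n_perm; ++t) {
    doTrades(gap);
    for (int i = 0; i < n; ++i) {
      std::fill(dense[i].begin(), dense[i].end(), 0);
      for (size_t k = 0; k < rows[i].size(); ++k) dense[i][rows[i][k]] = 1;
    }
    int idx = 0;
    for (int i = 0; i < p; ++i) {
      for (int j = i + 1; j < p; ++j, ++idx) {
        int ov = 0;
        for (int r = 0; r < n; ++r) ov += dense[r][i] & dense[r][j];
        out(t, idx) = ov;
      }
    }
  }
  PutRNGstate();
  return out;
}
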