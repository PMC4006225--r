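#include <Rcpp.h>
#include <cmath>
#include <stack>
using namespace Rcpp;

// Quality-weighted interval score over z = x/sigma:
//   S(i,j) = |sum_{k=i..j} z_k| / sqrt(j - i + 1)
// Best interval within z[lo..hi] (0-based, inclusive) with at least
// min_probes probes. Ties broken by longer interval, then leftmost.
static void best_in_block(const std::vector<double>& cz,
                          const std::vector<double>& rsq,
                          int lo, int hi, int min_probes,
                          int& bi, int& bj, double& bs) {
  bi = -1; bj = -1; bs = -1.0;
  int blen = -1;
  for (int i = lo; i <= hi; ++i) {
    const double czi = cz[i];
    for (int j = i + min_probes - 1; j <= hi; ++j) {
      int len = j - i + 1;
      double s = std::fabs(cz[j + 1] - czi) * rsq[len];
      if (s > bs || (s == bs && (len > blen || (len == blen && i < bi)))) {
        bs = s; bi = i; bj = j; blen = len;
      }
    }
  }
}

static std::vector<double> inv_sqrt_table(int n) {
  std::vector<double> rsq(n + 1, 0.0);
  for (int k = 1; k <= n; ++k) rsq[k] = 1.0 / std::sqrt((double)k);
  return rsq;
}

// [[Rcpp::export(name = ".best_interval_cpp")]]
List best_interval_cpp(NumericVector z, int min_probes) {
  int n = z.size();
  if (n < min_probes)
    return List::create(_["i"] = NA_INTEGER, _["j"] = NA_INTEGER,
                        _["score"] = NA_REAL);
  std::vector<double> cz(n + 1, 0.0);
  for (int k = 0; k < n; ++k) cz[k + 1] = cz[k] + z[k];
  std::vector<double> rsq = inv_sqrt_table(n);
  int bi, bj; double bs;
  best_in_block(cz, rsq, 0, n - 1, min_probes, bi, bj, bs);
  return List::create(_["i"] = bi + 1, _["j"] = bj + 1, _["score"] = bs);
}

// Greedy maximal-score extraction: repeatedly take the best-scoring
// interval with S >= threshold, mask its probes (splitting the block),
// and recurse into the flanks. Returns matrix with rows (i, j, score),
// 1-based probe indices, unordered.
// [[Rcpp::export(name = ".greedy_calls_cpp")]]
NumericMatrix greedy_calls_cpp(NumericVector z, double threshold,
                               int min_probes) {
  int n = z.size();
  std::vector<double> cz(n + 1, 0.0);
  for (int k = 0; k < n; ++k) cz[k + 1] = cz[k] + z[k];
  std::vector<double> rsq = inv_sqrt_table(n);
  std::vector<double> out;
  std::stack<std::pair<int, int> > blocks;
  if (n >= min_probes) blocks.push(std::make_pair(0, n - 1));
  while (!blocks.empty()) {
    std::pair<int, int> b = blocks.top(); blocks.pop();
    if (b.second - b.first + 1 < min_probes) continue;
    int bi, bj; double bs;
    best_in_block(cz, rsq, b.first, b.second, min_probes, bi, bj, bs);
    if (bi < 0 || bs < threshold) continue;
    out.push_back(bi + 1); out.push_back(bj + 1); out.push_back(bs);
    blocks.push(std::make_pair(b.first, bi - 1));
    blocks.push(std::make_pair(bj + 1, b.second));
  }
  int m = out.size() / 3;
  NumericMatrix res(m, 3);
  for (int r = 0; r < m; ++r) {
    res(r, 0) = out[3 * r];
    res(r, 1) = out[3 * r + 1];
    res(r, 2) = out[3 * r + 2];
  }
  colnames(res) = CharacterVector::create("i", "j", "score");
  return res;
}
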