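#include <Rcpp.h>
using namespace Rcpp;

static inline double pt_dist(const NumericMatrix& A, int i,
                             const NumericMatrix& B, int j) {
  double dx = A(i, 0) - B(j, 0);
  double dy = A(i, 1) - B(j, 1);
  return std::sqrt(dx * dx + dy * dy);
}

// Full (m+1) x (n+1) accumulation grid; row/column 0 are the +Inf borders,
// D(0,0) = 0.  Kept for path backtracking on the R side.
// [[Rcpp::export]]
NumericMatrix cpp_dtw_matrix(NumericMatrix A, NumericMatrix B) {
  int m = A.nrow(), n = B.nrow();
  NumericMatrix D(m + 1, n + 1);
  std::fill(D.begin(), D.end(), R_PosInf);
  D(0, 0) = 0.0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double best = std::min(D(i - 1, j - 1), std::min(D(i - 1, j), D(i, j - 1)));
      D(i, j) = pt_dist(A, i - 1, B, j - 1) + best;
    }
  }
  return D;
}

// Distance only, two rolling rows.
// [[Rcpp::export]]
double cpp_dtw_dist(NumericMatrix A, NumericMatrix B) {
  int m = A.nrow(), n = B.nrow();
  std::vector<double> prev(n + 1, R_PosInf), cur(n + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= m; ++i) {
    cur[0] = R_PosInf;
    for (int j = 1; j <= n; ++j) {
      double best = std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
      cur[j] = pt_dist(A, i - 1, B, j - 1) + best;
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// Mean DTW distance from one candidate coordinate sequence to every
// sequence in a list (each an n x 2 matrix).  Hot loop of the heuristic
// enumeration.
// [[Rcpp::export]]
double cpp_avg_dtw(NumericMatrix cand, List seqs) {
  int k = seqs.size();
  double acc = 0.0;
  for (int s = 0; s < k; ++s) {
    NumericMatrix B = seqs[s];
    acc += cpp_dtw_dist(cand, B);
  }
  return acc / k;
}
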