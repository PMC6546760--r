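#include <Rcpp.h>
using namespace Rcpp;

// Base encoding used throughout: A=0, C=1, G=2, T=3, N=4.
// Canonical pairs: A-T, G-C, G-T (wobble). N pairs with nothing.
static inline bool can_pair(int a, int b) {
  if (a > b) std::swap(a, b);
  return (a == 0 && b == 3) || (a == 1 && b == 2) || (a == 2 && b == 3);
}

struct FoldTables {
  int n;
  std::vector<double> Z;   // Z(i,j): partition fn over [i, j], empty interval = 1
  std::vector<double> Zb;  // Zb(i,j): [i, j] with (i,j) paired; 0 if pair disallowed
  double Ztot;
  double at(const std::vector<double>& M, int i, int j) const {
    if (i > j) return 1.0;           // empty interval
    return M[(size_t)i * n + j];
  }
  double atb(int i, int j) const {
    if (i < 0 || j >= n || i >= j) return 0.0;
    return Zb[(size_t)i * n + j];
  }
};

// Pair (i,j) admissible under hairpin and span constraints?
// span convention: j - i + 1 <= max_span; loop: j - i - 1 >= min_hairpin.
static inline bool pair_ok(const std::vector<int>& s, int i, int j,
                           int min_hairpin, int max_span) {
  if (j - i - 1 < min_hairpin) return false;
  if (j - i + 1 > max_span) return false;
  return can_pair(s[i], s[j]);
}

// Inside recursion.
// Z(i,j)  = Z(i+1,j) + sum_k Zb(i,k) * Z(k+1,j)
// Zb(i,j) = w * ( Z(i+1,j-1) + (stack-1) * Zb(i+1,j-1) )
// The stacking bonus multiplies a pair whose inner neighbour is also paired.
static FoldTables inside(const std::vector<int>& s, int min_hairpin,
                         int max_span, double w, double stack) {
  int n = (int)s.size();
  FoldTables T;
  T.n = n;
  T.Z.assign((size_t)n * n, 1.0);
  T.Zb.assign((size_t)n * n, 0.0);
  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      if (pair_ok(s, i, j, min_hairpin, max_span)) {
        double inner = T.at(T.Z, i + 1, j - 1);
        double zb = w * (inner + (stack - 1.0) * T.atb(i + 1, j - 1));
        T.Zb[(size_t)i * n + j] = zb;
      }
      double z = T.at(T.Z, i + 1, j);  // i unpaired
      int kmax = std::min(j, i + max_span - 1);
      for (int k = i + min_hairpin + 1; k <= kmax; ++k) {
        double zb = T.atb(i, k);
        if (zb > 0.0) z += zb * T.at(T.Z, k + 1, j);
      }
      T.Z[(size_t)i * n + j] = z;
    }
  }
  T.Ztot = n > 0 ? T.at(T.Z, 0, n - 1) : 1.0;
  return T;
}

// Outside value O(i,j): total weight of structures on positions outside
// [i,j] compatible with (i,j) paired, decomposed on the innermost pair
// (p,q) enclosing (i,j):
//   O(i,j) = Z(0,i-1) * Z(j+1,n-1)
//          + sum_{(p,q) superset (i,j)} w * O(p,q) * Z(p+1,i-1) * Z(j+1,q-1)
//          + w * O(i-1,j+1) * (stack-1)            [adjacent enclosing pair]
// Then P(i,j) = O(i,j) * Zb(i,j) / Ztot.
static void pair_probs(const std::vector<int>& s, int min_hairpin,
                       int max_span, double w, double stack,
                       NumericMatrix& P) {
  int n = (int)s.size();
  FoldTables T = inside(s, min_hairpin, max_span, w, stack);
  if (!R_finite(T.Ztot))
    stop("partition function overflowed; reduce window/span or pair weight");
  std::vector<double> O((size_t)n * n, 0.0);
  // process pairs from widest to narrowest so enclosing O values are ready
  for (int len = n; len >= min_hairpin + 2; --len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      if (T.atb(i, j) <= 0.0) continue;
      double o = T.at(T.Z, 0, i - 1) * T.at(T.Z, j + 1, n - 1);
      // innermost enclosing pair (p,q), q - p + 1 <= max_span
      int pmin = std::max(0, j + 2 - max_span);
      for (int p = i - 1; p >= pmin; --p) {
        int qmax = std::min(n - 1, p + max_span - 1);
        for (int q = j + 1; q <= qmax; ++q) {
          double opq_zb = T.atb(p, q);
          if (opq_zb <= 0.0) continue;
          double opq = O[(size_t)p * n + q];
          if (opq <= 0.0) continue;
          double term = w * opq * T.at(T.Z, p + 1, i - 1) * T.at(T.Z, j + 1, q - 1);
          if (p == i - 1 && q == j + 1) term += w * opq * (stack - 1.0);
          o += term;
        }
      }
      O[(size_t)i * n + j] = o;
      P(i, j) = o * T.atb(i, j) / T.Ztot;
      P(j, i) = P(i, j);
    }
  }
}

// [[Rcpp::export(name = ".fold_partition_cpp")]]
double fold_partition_cpp(IntegerVector seq, int min_hairpin, int max_span,
                          double pair_weight, double stack_bonus) {
  std::vector<int> s(seq.begin(), seq.end());
  FoldTables T = inside(s, min_hairpin, max_span, pair_weight, stack_bonus);
  return T.Ztot;
}

// [[Rcpp::export(name = ".fold_pair_probs_cpp")]]
NumericMatrix fold_pair_probs_cpp(IntegerVector seq, int min_hairpin,
                                  int max_span, double pair_weight,
                                  double stack_bonus) {
  int n = seq.size();
  std::vector<int> s(seq.begin(), seq.end());
  NumericMatrix P(n, n);
  pair_probs(s, min_hairpin, max_span, pair_weight, stack_bonus, P);
  return P;
}

// [[Rcpp::export(name = ".fold_bpp_cpp")]]
NumericVector fold_bpp_cpp(IntegerVector seq, int min_hairpin, int max_span,
                           double pair_weight, double stack_bonus) {
  int n = seq.size();
  std::vector<int> s(seq.begin(), seq.end());
  NumericMatrix P(n, n);
  pair_probs(s, min_hairpin, max_span, pair_weight, stack_bonus, P);
  NumericVector bpp(n);
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    for (int j = 0; j < n; ++j) tot += P(i, j);
    bpp[i] = tot;
  }
  return bpp;
}
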