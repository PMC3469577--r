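#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

// Base-pair energies of the folding model, kcal/mol-like model units.
// Sequences arrive in the DNA alphabet (U already mapped to T).
static inline double pair_e(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return -2.0;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return -1.0;
  return 1.0; // positive sentinel: not pairable
}

// Energy-minimizing secondary-structure DP (pair-sum model, no
// pseudoknots, minimum hairpin loop of `min_loop` unpaired bases).
// Traceback is deterministic: at equal energy the outermost base is
// paired rather than left unpaired, and the smallest pairing partner
// is taken first.
// [[Rcpp::export]]
List fold_cpp(std::string seq, int min_loop = 3) {
  const int n = (int) seq.size();
  const double eps = 1e-9;
  std::vector<double> E((size_t) n * (size_t) n, 0.0);
#define EAT(i, j) E[(size_t)(i) * (size_t)n + (size_t)(j)]
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      double best = EAT(i + 1, j); // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        const double e = pair_e(seq[i], seq[k]);
        if (e > 0.0) continue;
        double v = e;
        if (k - 1 >= i + 1) v += EAT(i + 1, k - 1);
        if (k + 1 <= j)     v += EAT(k + 1, j);
        if (v < best) best = v;
      }
      EAT(i, j) = best;
    }
  }
  std::string db(n, '.');
  std::vector<std::pair<int, int> > todo;
  if (n >= min_loop + 2) todo.push_back(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    const int i = todo.back().first, j = todo.back().second;
    todo.pop_back();
    if (j - i < min_loop + 1) continue;
    const double target = EAT(i, j);
    if (target >= -eps) continue; // nothing pairs in this interval
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      const double e = pair_e(seq[i], seq[k]);
      if (e > 0.0) continue;
      double v = e;
      if (k - 1 >= i + 1) v += EAT(i + 1, k - 1);
      if (k + 1 <= j)     v += EAT(k + 1, j);
      if (std::fabs(v - target) < eps) {
        db[(size_t) i] = '(';
        db[(size_t) k] = ')';
        if (k - 1 >= i + 1) todo.push_back(std::make_pair(i + 1, k - 1));
        if (k + 1 <= j)     todo.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) todo.push_back(std::make_pair(i + 1, j));
  }
  const double mfe = (n >= min_loop + 2) ? EAT(0, n - 1) : 0.0;
#undef EAT
  return List::create(_["structure"] = db, _["mfe"] = mfe);
}

// Elementwise Hamming distance between equal-length strings; `b` may be
// length 1 and is then recycled. Unequal string lengths give NA.
// [[Rcpp::export]]
IntegerVector hamming_cpp(CharacterVector a, CharacterVector b) {
  const R_xlen_t n = a.size();
  const bool recycle = (b.size() == 1);
  if (!recycle && b.size() != n) stop("length mismatch between 'a' and 'b'");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (a[i] == NA_STRING || (recycle ? b[0] : b[i]) == NA_STRING) {
      out[i] = NA_INTEGER;
      continue;
    }
    std::string x = as<std::string>(a[i]);
    std::string y = as<std::string>(recycle ? b[0] : b[i]);
    if (x.size() != y.size()) { out[i] = NA_INTEGER; continue; }
    int d = 0;
    for (size_t p = 0; p < x.size(); ++p) if (x[p] != y[p]) ++d;
    out[i] = d;
  }
  return out;
}

static inline int pair_class(char m, char t) {
  // 0 Watson-Crick, 1 G:T(U) wobble, 2 mismatch (DNA alphabet)
  if ((m == 'A' && t == 'T') || (m == 'T' && t == 'A') ||
      (m == 'G' && t == 'C') || (m == 'C' && t == 'G')) return 0;
  if ((m == 'G' && t == 'T') || (m == 'T' && t == 'G')) return 1;
  return 2;
}

// Expectation penalty of the miRNA against every window of a transcript.
// The miRNA (5'->3') is paired antiparallel against each window, i.e.
// miRNA position i (1-based) faces window position (w - i + 1).
// Penalties: Watson-Crick 0, wobble `wobble_pen`, mismatch `mm_pen`;
// doubled (`seed_mult`) at miRNA positions seed_start..seed_end.
// Returns one score per window start (1-based starts 1..nt-m+1).
// [[Rcpp::export]]
NumericVector expectation_scan_cpp(std::string mir, std::string tx,
                                   double mm_pen, double wobble_pen,
                                   int seed_start, int seed_end,
                                   double seed_mult) {
  const int m = (int) mir.size(), n = (int) tx.size();
  if (n < m) return NumericVector(0);
  NumericVector out(n - m + 1);
  for (int s = 0; s <= n - m; ++s) {
    double e = 0.0;
    for (int i = 0; i < m; ++i) {
      const int cls = pair_class(mir[(size_t) i], tx[(size_t)(s + m - 1 - i)]);
      double pen = (cls == 0) ? 0.0 : (cls == 1 ? wobble_pen : mm_pen);
      if (i + 1 >= seed_start && i + 1 <= seed_end) pen *= seed_mult;
      e += pen;
    }
    out[s] = e;
  }
  return out;
}
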