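#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Wraparound dynamic programming: align a segment against an unbounded
// cyclic repetition of a short motif. State (i, j) = i segment characters
// consumed, next expected motif phase j. Within-row deletion moves cycle
// through the phases; two relaxation passes per row suffice because a full
// cycle of deletions has strictly negative weight.
//
// Traceback moves:
//   1 = diagonal (segment char vs motif char: match or mismatch)
//   2 = up       (segment char unaligned: gap in motif)
//   3 = left     (motif char skipped: gap in segment)
//   0 = origin   (local-mode restart / free start phase at row 0)

static inline bool base_match(char a, char b) {
  // N never matches anything (single N scores as a mismatch)
  return a == b && a != 'N';
}

// [[Rcpp::export(name = ".wrap_align_cpp")]]
List wrap_align_cpp(std::string segment, std::string motif,
                    int match, int mismatch, int indel, bool local) {
  const int n = segment.size(), m = motif.size();
  if (m < 1) stop("motif must be non-empty");
  if (n < 1) stop("segment must be non-empty");

  const double NEG = -1e18;
  std::vector<double> D((size_t)(n + 1) * m, NEG);
  std::vector<unsigned char> trace((size_t)(n + 1) * m, 0);
  for (int j = 0; j < m; ++j) D[j] = 0.0;  // free start phase

  for (int i = 1; i <= n; ++i) {
    const char sc = segment[i - 1];
    for (int j = 0; j < m; ++j) {
      const int jp = (j - 1 + m) % m;
      const double sdiag = D[(size_t)(i - 1) * m + jp] +
        (base_match(sc, motif[jp]) ? (double)match : -(double)mismatch);
      const double sup = D[(size_t)(i - 1) * m + j] - indel;
      double v = sdiag; unsigned char mv = 1;
      if (sup > v) { v = sup; mv = 2; }
      if (local && 0.0 > v) { v = 0.0; mv = 0; }
      D[(size_t)i * m + j] = v; trace[(size_t)i * m + j] = mv;
    }
    for (int pass = 0; pass < 2; ++pass) {
      for (int j = 0; j < m; ++j) {
        const int jp = (j - 1 + m) % m;
        const double v = D[(size_t)i * m + jp] - indel;
        if (v > D[(size_t)i * m + j]) {
          D[(size_t)i * m + j] = v; trace[(size_t)i * m + j] = 3;
        }
      }
    }
  }

  double best = NEG; int best_i = n, best_j = 0;
  if (local) {
    best = 0.0; best_i = 0;
    for (int i = 1; i <= n; ++i)
      for (int j = 0; j < m; ++j)
        if (D[(size_t)i * m + j] > best) {
          best = D[(size_t)i * m + j]; best_i = i; best_j = j;
        }
  } else {
    for (int j = 0; j < m; ++j)
      if (D[(size_t)n * m + j] > best) { best = D[(size_t)n * m + j]; best_j = j; }
  }

  int i = best_i, j = best_j;
  long matches = 0, mismatches = 0, gaps = 0;
  while (i > 0) {
    const unsigned char mv = trace[(size_t)i * m + j];
    if (mv == 1) {
      const int jp = (j - 1 + m) % m;
      if (base_match(segment[i - 1], motif[jp])) ++matches; else ++mismatches;
      i -= 1; j = jp;
    } else if (mv == 2) {
      ++gaps; i -= 1;
    } else if (mv == 3) {
      ++gaps; j = (j - 1 + m) % m;
    } else {
      break;  // origin: local restart or free start phase
    }
  }

  return List::create(
    _["score"] = best,
    _["start"] = i + 1,        // 1-based inclusive segment coords
    _["end"] = best_i,
    _["matches"] = (double)matches,
    _["mismatches"] = (double)mismatches,
    _["gaps"] = (double)gaps);
}

// Distance-d base-match indicator used by the candidate-period scan:
// out[i] = 1 iff segment[i] == segment[i+d] and neither is N.
// [[Rcpp::export(name = ".dist_match_cpp")]]
IntegerVector dist_match_cpp(std::string s, int d) {
  const int n = s.size();
  if (d >= n) return IntegerVector(0);
  IntegerVector out(n - d);
  for (int i = 0; i < n - d; ++i)
    out[i] = base_match(s[i], s[i + d]) ? 1 : 0;
  return out;
}
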