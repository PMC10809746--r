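#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Sequences arrive as integer matrices (one row per sequence, one column per
// nucleotide position, values 1..4); all kernels assume equal row lengths,
// which the callers guarantee by length-stratifying upstream.
//
// Internally each sequence is bit-packed, 2 bits per base, 32 bases per
// 64-bit word. The Hamming distance of two packed rows is the number of
// 2-bit fields in which they differ: xor the words, fold each field with
// (v | v >> 1) & 0x5555..., and popcount.

static inline int hd_packed(const uint64_t* a, const uint64_t* b, int words) {
  int d = 0;
  for (int w = 0; w < words; ++w) {
    uint64_t v = a[w] ^ b[w];
    v = (v | (v >> 1)) & 0x5555555555555555ULL;
#if defined(__GNUC__) || defined(__clang__)
    d += __builtin_popcountll(v);
#else
    while (v) { v &= v - 1; ++d; }
#endif
  }
  return d;
}

static std::vector<uint64_t> pack_rows(const IntegerMatrix& m, int& words) {
  const int n = m.nrow(), L = m.ncol();
  words = (L + 31) / 32;
  std::vector<uint64_t> packed((size_t)n * words, 0ULL);
  for (int i = 0; i < n; ++i) {
    uint64_t* row = &packed[(size_t)i * words];
    for (int p = 0; p < L; ++p) {
      // bases 1..4 -> 2-bit codes 0..3
      row[p / 32] |= ((uint64_t)(m(i, p) - 1) & 3ULL) << (2 * (p % 32));
    }
  }
  return packed;
}

// [[Rcpp::export]]
IntegerMatrix cpp_hamming_matrix(const IntegerMatrix& a, const IntegerMatrix& b) {
  if (b.ncol() != a.ncol()) stop("sequence length mismatch");
  const int n = a.nrow(), m = b.nrow();
  int words;
  std::vector<uint64_t> pa = pack_rows(a, words);
  std::vector<uint64_t> pb = pack_rows(b, words);
  IntegerMatrix out(n, m);
  for (int i = 0; i < n; ++i) {
    const uint64_t* ra = &pa[(size_t)i * words];
    for (int j = 0; j < m; ++j) {
      out(i, j) = hd_packed(ra, &pb[(size_t)j * words], words);
    }
  }
  return out;
}

// Greedy lexicode scan: accept a point iff its Hamming distance to every
// previously accepted point is >= d_min. Returns 1-based row indices of the
// accepted points, in acceptance order.
// [[Rcpp::export]]
IntegerVector cpp_lexicode(const IntegerMatrix& pts, const int d_min) {
  const int n = pts.nrow();
  int words;
  std::vector<uint64_t> pk = pack_rows(pts, words);
  std::vector<int> acc;
  for (int i = 0; i < n; ++i) {
    const uint64_t* ri = &pk[(size_t)i * words];
    bool ok = true;
    for (size_t k = 0; k < acc.size(); ++k) {
      if (hd_packed(ri, &pk[(size_t)acc[k] * words], words) < d_min) {
        ok = false;
        break;
      }
    }
    if (ok) acc.push_back(i);
  }
  IntegerVector out(acc.size());
  for (size_t k = 0; k < acc.size(); ++k) out[k] = acc[k] + 1;
  return out;
}

// Lexicode scans of the same point set under many orderings: orders is an
// n x r matrix of 1-based permutations; returns a list of r index vectors
// (1-based, referring to rows of pts). Avoids re-subsetting the encoded
// matrix in R for every population member.
// [[Rcpp::export]]
List cpp_lexicode_population(const IntegerMatrix& pts,
                             const IntegerMatrix& orders, const int d_min) {
  const int n = pts.nrow(), r = orders.ncol();
  if (orders.nrow() != n) stop("orders must have one row per point");
  int words;
  std::vector<uint64_t> pk = pack_rows(pts, words);
  List out(r);
  std::vector<int> acc;
  for (int s = 0; s < r; ++s) {
    acc.clear();
    for (int q = 0; q < n; ++q) {
      const int i = orders(q, s) - 1;
      const uint64_t* ri = &pk[(size_t)i * words];
      bool ok = true;
      for (size_t k = 0; k < acc.size(); ++k) {
        if (hd_packed(ri, &pk[(size_t)acc[k] * words], words) < d_min) {
          ok = false;
          break;
        }
      }
      if (ok) acc.push_back(i);
    }
    IntegerVector v(acc.size());
    for (size_t k = 0; k < acc.size(); ++k) v[k] = acc[k] + 1;
    out[s] = v;
  }
  return out;
}

// All unordered pairs (i, j), i < j, with Hamming distance <= max_d.
// Returns a 2-column matrix of 1-based indices.
// [[Rcpp::export]]
IntegerMatrix cpp_pair_edges(const IntegerMatrix& m, const int max_d) {
  const int n = m.nrow();
  int words;
  std::vector<uint64_t> pk = pack_rows(m, words);
  std::vector<int> ii, jj;
  for (int i = 0; i < n; ++i) {
    const uint64_t* ri = &pk[(size_t)i * words];
    for (int j = i + 1; j < n; ++j) {
      if (hd_packed(ri, &pk[(size_t)j * words], words) <= max_d) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
      }
    }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) { out(k, 0) = ii[k]; out(k, 1) = jj[k]; }
  return out;
}

// Minimum Hamming distance between any row of a and any row of b
// (diagnostic helper for cross-leaf audits); returns L+1 when either side is
// empty.
// [[Rcpp::export]]
int cpp_min_cross_distance(const IntegerMatrix& a, const IntegerMatrix& b) {
  const int n = a.nrow(), m = b.nrow(), L = a.ncol();
  int words;
  std::vector<uint64_t> pa = pack_rows(a, words);
  std::vector<uint64_t> pb = pack_rows(b, words);
  int best = L + 1;
  for (int i = 0; i < n; ++i) {
    const uint64_t* ra = &pa[(size_t)i * words];
    for (int j = 0; j < m; ++j) {
      int d = hd_packed(ra, &pb[(size_t)j * words], words);
      if (d < best) best = d;
    }
  }
  return best;
}
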