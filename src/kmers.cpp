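#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Walk one sequence, calling f(canonical_kmer) for every k-mer window made of
// ACGT only.  Windows containing any other character are skipped.
template <typename F>
static void for_each_canonical(const char* s, R_xlen_t len, int k, F f) {
  if (len < k) return;
  const uint64_t mask = (k == 32) ? ~uint64_t(0) : ((uint64_t(1) << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  for (R_xlen_t i = 0; i < len; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | uint64_t(b)) & mask;
    rev = (rev >> 2) | (uint64_t(3 - b) << shift);
    if (++run >= k) f(fwd < rev ? fwd : rev);
  }
}

// [[Rcpp::export(name = ".count_kmers_cpp")]]
List count_kmers_cpp(CharacterVector seqs, int k) {
  if (k < 3 || k > 31 || k % 2 == 0)
    stop("k must be an odd integer in [3, 31]");
  std::unordered_map<uint64_t, uint32_t> tab;
  tab.reserve(1 << 20);
  double total_windows = 0, counted = 0;
  for (R_xlen_t j = 0; j < seqs.size(); ++j) {
    SEXP el = seqs[j];
    const char* s = CHAR(el);
    R_xlen_t len = LENGTH(el);
    if (len >= k) total_windows += double(len - k + 1);
    for_each_canonical(s, len, k, [&](uint64_t km) { ++tab[km]; ++counted; });
  }
  // histogram multiplicity -> number of distinct k-mers
  std::unordered_map<uint32_t, double> hist;
  for (auto& kv : tab) hist[kv.second] += 1.0;
  size_t nb = hist.size();
  IntegerVector mult(nb);
  NumericVector cnt(nb);
  size_t i = 0;
  for (auto& kv : hist) { mult[i] = int(kv.first); cnt[i] = kv.second; ++i; }
  return List::create(
    _["multiplicity"] = mult,
    _["count"] = cnt,
    _["total_kmers"] = counted,
    _["n_skipped"] = total_windows - counted,
    _["n_distinct"] = double(tab.size()));
}

// Fraction of each query sequence's canonical k-mer occurrences present in
// the reference k-mer set.  unique_only drops reference k-mers seen more
// than once (a crude repeat mask).
// [[Rcpp::export(name = ".kmer_containment_cpp")]]
NumericVector kmer_containment_cpp(CharacterVector query_seqs,
                                   CharacterVector ref_seqs,
                                   int k, bool unique_only) {
  if (k < 3 || k > 31 || k % 2 == 0)
    stop("k must be an odd integer in [3, 31]");
  std::unordered_map<uint64_t, uint32_t> ref;
  ref.reserve(1 << 20);
  for (R_xlen_t j = 0; j < ref_seqs.size(); ++j) {
    SEXP el = ref_seqs[j];
    for_each_canonical(CHAR(el), LENGTH(el), k, [&](uint64_t km) { ++ref[km]; });
  }
  NumericVector out(query_seqs.size());
  NumericVector denom(query_seqs.size());
  for (R_xlen_t j = 0; j < query_seqs.size(); ++j) {
    SEXP el = query_seqs[j];
    double hit = 0, tot = 0;
    for_each_canonical(CHAR(el), LENGTH(el), k, [&](uint64_t km) {
      ++tot;
      auto it = ref.find(km);
      if (it != ref.end() && (!unique_only || it->second == 1)) ++hit;
    });
    out[j] = tot > 0 ? hit / tot : NA_REAL;
    denom[j] = tot;
  }
  out.attr("n_kmers") = denom;
  return out;
}
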