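#include <Rcpp.h>
#include <cstring>
#include <string>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <unordered_set>

using namespace Rcpp;

// DNA helpers. Sequences are uppercase-folded; any window containing a
// character outside {A,C,G,T} is skipped.

static inline char norm_base(char c) {
  if (c >= 'a' && c <= 'z') c -= 32;
  return c;
}

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// Canonical form of the window s[i .. i+k-1] given the full reverse
// complement rc of s (rc[j] = comp(s[n-1-j])). The reverse complement of the
// window starts at rc[n - i - k]. Returns the lexicographically smaller of
// the two as a std::string.
static inline std::string canonical_window(const std::string &s,
                                           const std::string &rc,
                                           size_t i, size_t k) {
  size_t n = s.size();
  const char *f = s.data() + i;
  const char *r = rc.data() + (n - i - k);
  int cmp = 0;
  for (size_t j = 0; j < k; ++j) {
    if (f[j] != r[j]) { cmp = (f[j] < r[j]) ? -1 : 1; break; }
  }
  return (cmp <= 0) ? std::string(f, k) : std::string(r, k);
}

static std::string normalize_seq(const char *raw, size_t n) {
  std::string s(n, 'N');
  for (size_t i = 0; i < n; ++i) s[i] = norm_base(raw[i]);
  return s;
}

static std::string revcomp_str(const std::string &s) {
  size_t n = s.size();
  std::string rc(n, 'N');
  for (size_t i = 0; i < n; ++i) rc[i] = comp_base(s[n - 1 - i]);
  return rc;
}

// Visit every valid window of every sequence, calling fn(canonical kmer).
template <typename F>
static void for_each_canonical(const CharacterVector &seqs, int k, F fn) {
  size_t kk = (size_t)k;
  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    if (seqs[si] == NA_STRING) continue;
    const char *raw = CHAR(seqs[si]);
    size_t n = std::strlen(raw);
    if (n < kk) continue;
    std::string s = normalize_seq(raw, n);
    std::string rc = revcomp_str(s);
    // last_bad: index of most recent non-ACGT char, or -1
    long last_bad = -1;
    for (size_t i = 0; i < n; ++i) {
      if (!is_acgt(s[i])) last_bad = (long)i;
      if (i + 1 >= kk) {
        size_t start = i + 1 - kk;
        if (last_bad < (long)start) fn(canonical_window(s, rc, start, kk));
      }
    }
  }
}

// [[Rcpp::export]]
CharacterVector cpp_extract_kmers(CharacterVector seqs, int k) {
  std::unordered_set<std::string> seen;
  for_each_canonical(seqs, k, [&](const std::string &km) { seen.insert(km); });
  std::vector<std::string> out(seen.begin(), seen.end());
  std::sort(out.begin(), out.end());
  return wrap(out);
}

// Counts occurrences of canonical windows that belong to `query`; result is
// aligned to the order of `query` (k-mers absent from the reads get 0).
// [[Rcpp::export]]
IntegerVector cpp_count_kmers(CharacterVector seqs, int k, CharacterVector query) {
  std::unordered_map<std::string, int> idx;
  idx.reserve(query.size() * 2);
  for (R_xlen_t i = 0; i < query.size(); ++i)
    idx.emplace(std::string(CHAR(query[i])), (int)i);
  std::vector<int> counts(query.size(), 0);
  for_each_canonical(seqs, k, [&](const std::string &km) {
    auto it = idx.find(km);
    if (it != idx.end()) ++counts[it->second];
  });
  return wrap(counts);
}

// Canonicalize full-length k-mers; NA for any string containing non-ACGT.
// [[Rcpp::export]]
CharacterVector cpp_canonicalize(CharacterVector kmers) {
  CharacterVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    if (kmers[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    const char *raw = CHAR(kmers[i]);
    size_t n = std::strlen(raw);
    std::string s = normalize_seq(raw, n);
    bool ok = true;
    for (size_t j = 0; j < n; ++j) if (!is_acgt(s[j])) { ok = false; break; }
    if (!ok || n == 0) { out[i] = NA_STRING; continue; }
    std::string rc = revcomp_str(s);
    out[i] = (s <= rc) ? s : rc;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    const char *raw = CHAR(seqs[i]);
    size_t n = std::strlen(raw);
    std::string s = normalize_seq(raw, n);
    out[i] = revcomp_str(s);
  }
  return out;
}
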