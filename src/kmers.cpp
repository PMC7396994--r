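#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <string_view>
#include <vector>

using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string seq) {
  return revcomp_str(seq);
}

namespace {

// window key: pointer into the stable read store plus a precomputed rolling
// hash, so the hot loop neither allocates nor rehashes k bytes per window
struct WinKey {
  const char *p;
  int len;
  uint64_t h;
  bool operator==(const WinKey &o) const {
    return len == o.len && std::memcmp(p, o.p, (size_t)len) == 0;
  }
};

struct WinKeyHash {
  size_t operator()(const WinKey &k) const { return (size_t)k.h; }
};

} // namespace

// Count every k-length window of every read and of its reverse complement.
// Windows containing non-ACGT characters are skipped; reads shorter than k
// contribute nothing.
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector reads, int k) {
  std::vector<std::string> store;
  store.reserve(2 * (size_t)reads.size());
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    if ((int)s.size() < k) continue;
    store.push_back(s);
    store.push_back(revcomp_str(s));
  }
  const uint64_t B = 1099511628211ULL; // polynomial base (FNV prime)
  uint64_t Bk = 1;                     // B^(k-1), implicit mod 2^64
  for (int i = 1; i < k; ++i) Bk *= B;
  std::unordered_map<WinKey, int, WinKeyHash> tab;
  tab.reserve(1 << 18);
  for (const std::string &seq : store) {
    const int n = (int)seq.size();
    int bad = -1;
    uint64_t h = 0;
    for (int i = 0; i < n; ++i) {
      char c = seq[i];
      if (c != 'A' && c != 'C' && c != 'G' && c != 'T') bad = i;
      h = (i >= k) ? (h - (uint64_t)(unsigned char)seq[i - k] * Bk) * B +
                         (uint64_t)(unsigned char)c
                   : h * B + (uint64_t)(unsigned char)c;
      if (i >= k - 1 && bad <= i - k)
        tab[WinKey{seq.data() + i - k + 1, k, h}]++;
    }
  }
  CharacterVector kmers(tab.size());
  IntegerVector counts(tab.size());
  R_xlen_t i = 0;
  for (auto &kv : tab) {
    kmers[i] = String(std::string(kv.first.p, (size_t)kv.first.len));
    counts[i] = kv.second;
    ++i;
  }
  return List::create(_["kmer"] = kmers, _["count"] = counts);
}
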