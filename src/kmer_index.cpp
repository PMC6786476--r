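// Exact k-mer position index over a (circular) subject sequence, reusable
// across many query lookups: classification anchors every reference CDS on
// the same target genome, so the subject hash is built once.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline int code_of(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  default: return -1;
  }
}

struct KmerIndex {
  int n;      // subject length
  int k;
  bool circular;
  std::unordered_map<uint64_t, std::vector<int>> map;
};

static bool pack_kmer(const char* s, int k, uint64_t& key) {
  key = 0;
  for (int i = 0; i < k; ++i) {
    int c = code_of(s[i]);
    if (c < 0) return false;
    key = (key << 2) | (uint64_t)c;
  }
  return true;
}

// [[Rcpp::export(name = ".kmer_index_build_cpp")]]
SEXP kmer_index_build_cpp(std::string subject, int k, bool circular) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  KmerIndex* idx = new KmerIndex();
  idx->n = (int)subject.size();
  idx->k = k;
  idx->circular = circular;
  std::string s = circular ? subject + subject.substr(0, std::min((int)subject.size(), k - 1))
                           : subject;
  int last = (int)s.size() - k;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t key = 0; int valid = 0;
  for (int i = 0; i < (int)s.size(); ++i) {
    int c = code_of(s[i]);
    if (c < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++valid < k) continue;
    int start = i - k + 1;
    if (start <= last && start < idx->n) idx->map[key].push_back(start);
  }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".kmer_index_lookup_cpp")]]
List kmer_index_lookup_cpp(SEXP xptr, CharacterVector queries) {
  XPtr<KmerIndex> idx(xptr);
  List out(queries.size());
  for (int q = 0; q < queries.size(); ++q) {
    const char* s = CHAR(STRING_ELT(queries, q));
    uint64_t key;
    if ((int)strlen(s) != idx->k || !pack_kmer(s, idx->k, key)) {
      out[q] = IntegerVector(0);
      continue;
    }
    auto it = idx->map.find(key);
    if (it == idx->map.end()) out[q] = IntegerVector(0);
    else out[q] = IntegerVector(it->second.begin(), it->second.end());
  }
  return out;
}
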