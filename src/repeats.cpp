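// Maximal repeat enumeration on circular sequences.
//
// A repeat pair is a maximal window along a "diagonal" of the comparison
// between the sequence A and a transformed copy T (identity / reversed /
// complemented / reverse-complemented), carrying at most k mismatches and
// not extendable in either direction without exceeding k. Windows are found
// by exact-seed anchoring (pigeonhole: seed length <= floor(min_len/(k+1)))
// followed by mismatch-bounded extension along the circular diagonal.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  default: return -1;
  }
}

struct Win { int d, start, len, mism; };

// [[Rcpp::export(name = ".find_repeat_windows_cpp")]]
IntegerMatrix find_repeat_windows_cpp(std::string A, std::string T,
                                      int min_len, int max_k, int seed_len) {
  const int n = (int)A.size();
  if ((int)T.size() != n) stop("sequences differ in length");
  if (seed_len < 1 || seed_len > 31) stop("invalid seed length");
  std::vector<int> a(n), t(n);
  for (int i = 0; i < n; ++i) { a[i] = base_code(A[i]); t[i] = base_code(T[i]); }

  auto match_at = [&](int p, int d) -> bool {
    int i = p % n; if (i < 0) i += n;
    int j = (p + d) % n; if (j < 0) j += n;
    return a[i] >= 0 && a[i] == t[j];
  };

  // hash all seed_len-mers of T (circular)
  std::unordered_map<uint64_t, std::vector<int>> seed_map;
  seed_map.reserve(n * 2);
  const uint64_t mask = (seed_len == 32) ? ~0ULL : ((1ULL << (2 * seed_len)) - 1);
  {
    uint64_t key = 0; int valid = 0;
    for (int q = 0; q < n + seed_len - 1; ++q) {
      int c = t[q % n];
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++valid >= seed_len && q >= seed_len - 1) {
        int start = q - seed_len + 1;
        if (start < n) seed_map[key].push_back(start);
      }
    }
  }

  std::vector<Win> out;
  std::unordered_set<uint64_t> seen;     // dedup windows: (d, start, len)
  std::unordered_map<int, std::pair<int,int>> run_memo; // d -> last exact run
  std::vector<bool> full_circle_done(1, false);
  std::unordered_set<int> full_circle_diags;

  auto emit = [&](int d, int start, int len, int mism) {
    int s = start % n; if (s < 0) s += n;
    uint64_t key = ((uint64_t)d << 42) | ((uint64_t)s << 21) | (uint64_t)len;
    if (seen.insert(key).second) out.push_back({d, s, len, mism});
  };

  // enumerate maximal windows containing the exact run [rs, re)
  auto extend_run = [&](int d, int rs, int re) {
    int run_len = re - rs;
    if (run_len >= n) {                      // whole circle matches
      if (full_circle_diags.insert(d).second) emit(d, 0, n, 0);
      return;
    }
    int avail = n - run_len;                 // positions outside the run
    // distances (1-based) of the 1st..(k+1)th mismatch left of rs / right of re
    std::vector<int> L(max_k + 2, avail + 1), R(max_k + 2, avail + 1);
    int found = 0;
    for (int s = 1; s <= avail && found <= max_k; ++s) {
      if (!match_at(rs - s, d)) L[found++] = s;
    }
    // L[j] for j beyond found stays avail+1 (walked the whole way round)
    found = 0;
    for (int s = 1; s <= avail && found <= max_k; ++s) {
      if (!match_at(re - 1 + s, d)) R[found++] = s;
    }
    for (int aa = 0; aa <= max_k; ++aa) {
      int bb = max_k - aa;
      int lext = L[aa] - 1;                 // L[aa] = (aa+1)-th mismatch dist
      int rext = R[bb] - 1;
      long len = (long)run_len + lext + rext;
      if (len > n) len = n;
      if (len < min_len) continue;
      // count mismatches actually inside the window
      int ml = 0, mr = 0;
      for (int j = 0; j < aa; ++j) if (L[j] <= lext) ++ml;
      for (int j = 0; j < bb; ++j) if (R[j] <= rext) ++mr;
      emit(d, rs - lext, (int)len, ml + mr);
    }
  };

  // scan A's seeds against the hash
  uint64_t key = 0; int valid = 0;
  for (int p = 0; p < n + seed_len - 1; ++p) {
    int c = a[p % n];
    if (c < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++valid < seed_len) continue;
    int ps = p - seed_len + 1;
    if (ps < 0 || ps >= n) continue;
    auto it = seed_map.find(key);
    if (it == seed_map.end()) continue;
    for (int q : it->second) {
      int d = q - ps; d %= n; if (d < 0) d += n;
      // exact run around the seed
      auto memo = run_memo.find(d);
      // extend the exact run containing [ps, ps+seed_len)
      int rs = ps, re = ps + seed_len;
      if (memo != run_memo.end()) {
        int mrs = memo->second.first, mre = memo->second.second;
        // run coordinates are canonical mod n only per extension; compare
        // on the unnormalized line: accept also shifted by n
        if ((rs >= mrs && re <= mre) ||
            (rs + n >= mrs && re + n <= mre) ||
            (rs - n >= mrs && re - n <= mre)) continue;
      }
      int steps = 0, limit = n - seed_len;
      while (steps < limit && match_at(rs - 1, d)) { --rs; ++steps; }
      while (steps < limit && match_at(re, d)) { ++re; ++steps; }
      run_memo[d] = std::make_pair(rs, re);
      extend_run(d, rs, re);
    }
  }

  IntegerMatrix m(out.size(), 4);
  for (size_t i = 0; i < out.size(); ++i) {
    m(i, 0) = out[i].start;                    // start in A (0-based)
    int q = (out[i].start + out[i].d) % n;     // start in T (0-based)
    m(i, 1) = q;
    m(i, 2) = out[i].len;
    m(i, 3) = out[i].mism;
  }
  colnames(m) = CharacterVector::create("start_a", "start_t", "length",
                                        "mismatches");
  return m;
}

// Perfect tandem arrays on a circular sequence: maximal runs of positions i
// with s[i] == s[i+u], reported when total length >= min_total, at least
// two full copies, and a primitive unit.

static bool unit_primitive(const std::vector<int>& a, int start, int u, int n) {
  for (int d = 1; d <= u / 2; ++d) {
    if (u % d != 0) continue;
    bool per = true;
    for (int i = d; i < u && per; ++i) {
      if (a[(start + i) % n] != a[(start + i - d) % n]) per = false;
    }
    if (per) return true;   // unit has a proper period -> not primitive
  }
  return false;
}

// [[Rcpp::export(name = ".find_tandem_cpp")]]
IntegerMatrix find_tandem_cpp(std::string A, int min_total, int umin, int umax) {
  const int n = (int)A.size();
  std::vector<int> a(n);
  for (int i = 0; i < n; ++i) a[i] = base_code(A[i]);
  std::vector<std::array<int,3>> hits;  // start, unit_len, total
  for (int u = umin; u <= std::min(umax, n / 2); ++u) {
    // circular boolean: t[i] = (a[i] == a[(i+u)%n]), a[i] >= 0
    // find circular runs of true
    std::vector<char> t(n);
    bool all_true = true;
    for (int i = 0; i < n; ++i) {
      t[i] = (a[i] >= 0 && a[i] == a[(i + u) % n]);
      if (!t[i]) all_true = false;
    }
    if (all_true) {
      if (n % u == 0 && n >= min_total && n / u >= 2 &&
          !unit_primitive(a, 0, u, n)) {
        hits.push_back({0, u, n});
      }
      continue;
    }
    // start scanning right after a false position
    int anchor = 0;
    while (t[anchor]) ++anchor;   // exists since !all_true
    int i = (anchor + 1) % n, run = 0, run_start = (anchor + 1) % n;
    for (int cnt = 0; cnt < n; ++cnt) {
      if (t[i]) {
        if (run == 0) run_start = i;
        ++run;
      }
      if (!t[i] || cnt == n - 1) {
        if (run > 0) {
          int total = run + u;
          if (total >= min_total && run >= u &&
              !unit_primitive(a, run_start, u, n)) {
            hits.push_back({run_start, u, total});
          }
          run = 0;
        }
      }
      i = (i + 1) % n;
    }
  }
  IntegerMatrix m(hits.size(), 3);
  for (size_t i = 0; i < hits.size(); ++i) {
    m(i, 0) = hits[i][0]; m(i, 1) = hits[i][1]; m(i, 2) = hits[i][2];
  }
  colnames(m) = CharacterVector::create("start", "unit_len", "total");
  return m;
}
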