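// Signed reversal distance on permutations (linear framing with end caps).
//
// Exact distance: IDA* with the breakpoint-graph cycle lower bound
// n + 1 - c(pi), which changes by at most one per reversal and is therefore
// an admissible, consistent heuristic. An uninformed breadth-first search
// from the identity (used as an independent oracle in the tests) is also
// exported; it enumerates the full distance table for n <= 8.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstdint>
using namespace Rcpp;

// cycle lower bound: n + 1 - (number of cycles in the breakpoint graph)
static int cycle_lower_bound(const std::vector<int>& p) {
  const int n = (int)p.size();
  // unsigned doubling: +e -> (2e-1, 2e); -e -> (2e, 2e-1); frame 0 .. 2n+1
  std::vector<int> u(2 * n + 2);
  u[0] = 0; u[2 * n + 1] = 2 * n + 1;
  for (int i = 0; i < n; ++i) {
    int e = p[i];
    if (e > 0) { u[2 * i + 1] = 2 * e - 1; u[2 * i + 2] = 2 * e; }
    else       { u[2 * i + 1] = -2 * e;    u[2 * i + 2] = -2 * e - 1; }
  }
  // black edges pair positions (2i, 2i+1); gray edges pair values (2i, 2i+1)
  std::vector<int> pos(2 * n + 2);
  for (int i = 0; i < 2 * n + 2; ++i) pos[u[i]] = i;
  std::vector<bool> vis(2 * n + 2, false);
  int cycles = 0;
  for (int start = 0; start < 2 * n + 2; ++start) {
    if (vis[start]) continue;
    ++cycles;
    int idx = start;
    while (!vis[idx]) {
      vis[idx] = true;
      int idx2 = idx ^ 1;                       // traverse black edge
      vis[idx2] = true;
      int val = u[idx2];
      int gval = (val % 2 == 0) ? val + 1 : val - 1;
      idx = pos[gval];                          // traverse gray edge
    }
  }
  return n + 1 - cycles;
}

static void apply_reversal(std::vector<int>& p, int i, int j) {
  while (i < j) { int t = p[i]; p[i] = -p[j]; p[j] = -t; ++i; --j; }
  if (i == j) p[i] = -p[i];
}

static bool is_identity(const std::vector<int>& p) {
  for (int i = 0; i < (int)p.size(); ++i) if (p[i] != i + 1) return false;
  return true;
}

static bool dfs(std::vector<int>& p, int g, int limit, int& nodes) {
  int h = cycle_lower_bound(p);
  if (g + h > limit) return false;
  if (h == 0 && is_identity(p)) return true;
  if (++nodes > 50000000) stop("reversal search exceeded node budget");
  const int n = (int)p.size();
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      apply_reversal(p, i, j);
      bool found = dfs(p, g + 1, limit, nodes);
      apply_reversal(p, i, j);
      if (found) return true;
    }
  }
  return false;
}

// [[Rcpp::export(name = ".reversal_distance_cpp")]]
int reversal_distance_cpp(IntegerVector perm) {
  std::vector<int> p(perm.begin(), perm.end());
  if (is_identity(p)) return 0;
  int nodes = 0;
  for (int limit = cycle_lower_bound(p); ; ++limit) {
    std::vector<int> q = p;
    if (dfs(q, 0, limit, nodes)) return limit;
    if (limit > 3 * (int)p.size() + 3) stop("reversal search failed to converge");
  }
}

// [[Rcpp::export(name = ".cycle_lower_bound_cpp")]]
int cycle_lower_bound_rcpp(IntegerVector perm) {
  std::vector<int> p(perm.begin(), perm.end());
  return cycle_lower_bound(p);
}

// ---- independent BFS oracle ----------------------------------------------

// Lehmer rank of a signed permutation: (perm rank) * 2^n + sign bits.
static uint32_t rank_signed(const std::vector<int>& p) {
  const int n = (int)p.size();
  uint32_t signs = 0;
  std::vector<int> ap(n);
  for (int i = 0; i < n; ++i) {
    ap[i] = std::abs(p[i]);
    if (p[i] < 0) signs |= (1u << i);
  }
  uint32_t r = 0;
  for (int i = 0; i < n; ++i) {
    int smaller = 0;
    for (int j = i + 1; j < n; ++j) if (ap[j] < ap[i]) ++smaller;
    r = r * (n - i) + smaller;
  }
  return (r << n) | signs;
}

static void unrank_signed(uint32_t code, int n, std::vector<int>& p) {
  uint32_t signs = code & ((1u << n) - 1);
  uint32_t r = code >> n;
  std::vector<int> digits(n);
  for (int i = n - 1; i >= 0; --i) { digits[i] = r % (n - i); r /= (n - i); }
  std::vector<int> avail(n);
  for (int i = 0; i < n; ++i) avail[i] = i + 1;
  for (int i = 0; i < n; ++i) {
    p[i] = avail[digits[i]];
    avail.erase(avail.begin() + digits[i]);
  }
  for (int i = 0; i < n; ++i) if (signs & (1u << i)) p[i] = -p[i];
}

// Full BFS distance table from the identity over all signed permutations
// of size n (n <= 8). Entry index = rank_signed; value = reversal distance.
// [[Rcpp::export(name = ".reversal_bfs_table_cpp")]]
IntegerVector reversal_bfs_table_cpp(int n) {
  if (n < 1 || n > 8) stop("BFS table limited to n <= 8");
  uint64_t fact = 1;
  for (int i = 2; i <= n; ++i) fact *= i;
  uint64_t total = fact << n;
  std::vector<uint8_t> dist(total, 255);
  std::vector<int> p(n), q(n);
  for (int i = 0; i < n; ++i) p[i] = i + 1;
  std::queue<uint32_t> bfs;
  uint32_t id = rank_signed(p);
  dist[id] = 0;
  bfs.push(id);
  while (!bfs.empty()) {
    uint32_t code = bfs.front(); bfs.pop();
    unrank_signed(code, n, p);
    uint8_t d = dist[code];
    for (int i = 0; i < n; ++i) {
      for (int j = i; j < n; ++j) {
        q = p;
        apply_reversal(q, i, j);
        uint32_t c2 = rank_signed(q);
        if (dist[c2] == 255) { dist[c2] = d + 1; bfs.push(c2); }
      }
    }
  }
  IntegerVector out(total);
  for (uint64_t i = 0; i < total; ++i) out[i] = dist[i];
  return out;
}

// [[Rcpp::export(name = ".rank_signed_cpp")]]
int rank_signed_rcpp(IntegerVector perm) {
  std::vector<int> p(perm.begin(), perm.end());
  return (int)rank_signed(p);
}
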