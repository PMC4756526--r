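#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Control-pool construction for the diagonal-walk (DiagWalks) design.
//
// The cohort is laid out column-major in an m x ceil(n/m) matrix whose
// columns are the main pools. Starting from (1,1) (and (2,1) when both
// exist), patients are replicated into control pools of capacity m while
// walking diagonally up-right. A failed diagonal step (outside the matrix,
// empty cell, or already-replicated patient) triggers a row-major rescan
// from the cell just after the failure position; a full control pool
// triggers a global column-major restart into a fresh pool. When the
// remaining unreplicated patients fit into one fresh pool they are placed
// there in column-major order.
//
// [[Rcpp::export]]
List cpp_diagwalks_controls(int n, int m) {
  if (n < 1 || m < 1 || m > n) stop("invalid n or m");
  const int p_m = (n + m - 1) / m;
  std::vector<char> rep(n + 1, 0);
  std::vector<std::vector<int> > pools;
  std::vector<int> open;
  open.reserve(m);

  // patient index at (r, c), 0 when outside or empty
  auto pat = [&](int r, int c) -> int {
    if (r < 1 || r > m || c < 1 || c > p_m) return 0;
    long k = (long)(c - 1) * m + r;
    return k <= n ? (int)k : 0;
  };

  int nrep = 0;
  int nextg = 1;  // global column-major scan pointer (== patient order)
  auto replicate = [&](int k) { rep[k] = 1; open.push_back(k); ++nrep; };

  int r = 1, c = 1;
  replicate(1);
  if (n >= 2 && m >= 2) { r = 2; replicate(2); }

  while (nrep < n) {
    if ((int)open.size() == m) {
      // condition 1: control pool full
      pools.push_back(open);
      open.clear();
      while (nextg <= n && rep[nextg]) ++nextg;
      if (nextg > n) break;
      if (n - nrep <= m) {
        // leftover rule: remaining patients fit the fresh pool
        for (int k = nextg; k <= n; ++k) if (!rep[k]) replicate(k);
        break;
      }
      int k = nextg;
      r = (k - 1) % m + 1;
      c = (k - 1) / m + 1;
      replicate(k);
      continue;
    }
    // diagonal step up-right
    int tr = r - 1, tc = c + 1;
    int k = pat(tr, tc);
    if (k && !rep[k]) {
      r = tr; c = tc;
      replicate(k);
      continue;
    }
    // condition 2: rescan row-major after the failure position (the failed
    // target when it addresses a patient, else the current cell)
    int sr, sc;
    if (k) { sr = tr; sc = tc; } else { sr = r; sc = c; }
    ++sc;
    int fk = 0;
    for (int rr = sr; rr <= m && !fk; ++rr) {
      for (int cc = (rr == sr ? sc : 1); cc <= p_m; ++cc) {
        int kk = pat(rr, cc);
        if (kk && !rep[kk]) { fk = kk; r = rr; c = cc; break; }
      }
    }
    if (fk) {
      replicate(fk);
    } else {
      // scan exhausted: fall back to the global scan, same pool
      while (nextg <= n && rep[nextg]) ++nextg;
      if (nextg > n) break;
      int kk = nextg;
      r = (kk - 1) % m + 1;
      c = (kk - 1) / m + 1;
      replicate(kk);
    }
  }
  if (!open.empty()) pools.push_back(open);

  List out(pools.size());
  for (size_t i = 0; i < pools.size(); ++i)
    out[i] = IntegerVector(pools[i].begin(), pools[i].end());
  return out;
}

// OptReplica: every patient enters two distinct pools of an interleaved
// pool list pre-sized to 2*ceil(n/m): rule A picks the first pool with
// fewer than m members, rule B the lowest-index minimum-count pool that is
// distinct from A's and shares no member with it (so no two pools ever
// share more than one patient). A new pool is appended only when rule B is
// blocked everywhere (always the case for m = 1).
//
// [[Rcpp::export]]
List cpp_optreplica_pools(int n, int m) {
  if (n < 1 || m < 1 || m > n) stop("invalid n or m");
  int P = 2 * ((n + m - 1) / m);
  std::vector<std::vector<int> > pools(P);
  std::vector<int> cnt(P, 0);
  std::vector<int> stamp(P, 0);
  std::vector<int> pa(n + 1, -1), pb(n + 1, -1);
  int afirst = 0;

  for (int k = 1; k <= n; ++k) {
    while (afirst < (int)pools.size() && cnt[afirst] >= m) ++afirst;
    if (afirst == (int)pools.size()) {
      pools.push_back(std::vector<int>());
      cnt.push_back(0);
      stamp.push_back(0);
    }
    int a = afirst;
    pools[a].push_back(k);
    ++cnt[a];
    pa[k] = a;
    // pools already sharing a member with pool a are barred for rule B
    for (size_t t = 0; t < pools[a].size(); ++t) {
      int x = pools[a][t];
      if (pa[x] >= 0) stamp[pa[x]] = k;
      if (pb[x] >= 0) stamp[pb[x]] = k;
    }
    // pools before afirst are full, so the scan starts there; the first
    // empty pool encountered is the global minimum and ends the scan
    int b = -1, best = INT_MAX;
    for (int i = afirst; i < (int)pools.size(); ++i) {
      if (i == a || cnt[i] >= m || stamp[i] == k) continue;
      if (cnt[i] < best) {
        best = cnt[i];
        b = i;
        if (best == 0) break;
      }
    }
    if (b < 0) {
      pools.push_back(std::vector<int>(1, k));
      cnt.push_back(1);
      stamp.push_back(0);
      pb[k] = (int)pools.size() - 1;
    } else {
      pools[b].push_back(k);
      ++cnt[b];
      pb[k] = b;
    }
  }

  List out(pools.size());
  for (size_t i = 0; i < pools.size(); ++i)
    out[i] = IntegerVector(pools[i].begin(), pools[i].end());
  return out;
}
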