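#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

// Affine-gap overlap (ends-free) alignment, Gotoh three-state DP with full
// traceback. Gap of length L costs gap_open + L * gap_extend. Terminal gap
// runs (one run per end) are free. Tie preference everywhere: aligned pair
// (diagonal) first, then gap in the query row, then gap in the ref row.

static const float NEG_INF = -std::numeric_limits<float>::infinity();

// state codes: 0 = M (aligned pair), 1 = IY (gap in query row, consumes ref),
// 2 = IX (gap in ref row, consumes query)

// [[Rcpp::export]]
List cpp_global_align(std::string query, std::string ref,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const int n = (int)query.size(); // rows, query
  const int m = (int)ref.size();   // cols, ref
  const size_t sz = (size_t)(n + 1) * (size_t)(m + 1);
  std::vector<float> M(sz, NEG_INF), IY(sz, NEG_INF), IX(sz, NEG_INF);
  std::vector<signed char> pM(sz, -1), pIY(sz, -1), pIX(sz, -1);
  const float go = (float)gap_open, ge = (float)gap_extend;
  const float ma = (float)match, mi = (float)mismatch;
  auto at = [m](int i, int j) { return (size_t)i * (size_t)(m + 1) + (size_t)j; };

  M[at(0, 0)] = 0.0f;
  for (int i = 1; i <= n; ++i) { IX[at(i, 0)] = 0.0f; pIX[at(i, 0)] = 9; } // free lead
  for (int j = 1; j <= m; ++j) { IY[at(0, j)] = 0.0f; pIY[at(0, j)] = 9; }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = at(i, j), d = at(i - 1, j - 1),
                   u = at(i - 1, j), l = at(i, j - 1);
      // M: preference M > IY > IX on ties
      float best = M[d]; signed char arg = 0;
      if (IY[d] > best) { best = IY[d]; arg = 1; }
      if (IX[d] > best) { best = IX[d]; arg = 2; }
      float s = (query[i - 1] == ref[j - 1]) ? ma : mi;
      M[c] = best + s; pM[c] = arg;
      // IY consumes ref char j (gap in query row)
      best = M[l] + go + ge; arg = 0;
      if (IY[l] + ge > best) { best = IY[l] + ge; arg = 1; }
      if (IX[l] + go + ge > best) { best = IX[l] + go + ge; arg = 2; }
      IY[c] = best; pIY[c] = arg;
      // IX consumes query char i (gap in ref row)
      best = M[u] + go + ge; arg = 0;
      if (IY[u] + go + ge > best) { best = IY[u] + go + ge; arg = 1; }
      if (IX[u] + ge > best) { best = IX[u] + ge; arg = 2; }
      IX[c] = best; pIX[c] = arg;
    }
  }

  // terminal: free trailing run on whichever side remains; candidates in
  // preference order (corner first, then last column bottom-up, then last row
  // right-to-left), strict improvement only -> deterministic
  float bestScore = NEG_INF;
  int bi = -1, bj = -1; signed char bstate = -1;
  auto consider = [&](int i, int j) {
    const size_t c = at(i, j);
    const float v[3] = { M[c], IY[c], IX[c] };
    for (int s = 0; s < 3; ++s) {
      if (v[s] > bestScore) { bestScore = v[s]; bi = i; bj = j; bstate = (signed char)s; }
    }
  };
  consider(n, m);
  for (int i = n - 1; i >= 0; --i) consider(i, m);
  for (int j = m - 1; j >= 0; --j) consider(n, j);

  // traceback
  std::string qrow, rrow;
  // trailing free gaps
  for (int j = m; j > bj; --j) { rrow.push_back(ref[j - 1]); qrow.push_back('-'); }
  for (int i = n; i > bi; --i) { qrow.push_back(query[i - 1]); rrow.push_back('-'); }
  int i = bi, j = bj; signed char st = bstate;
  while (true) {
    if (st == 0) { // M
      if (i == 0 && j == 0) break;
      signed char pr = pM[at(i, j)];
      qrow.push_back(query[i - 1]); rrow.push_back(ref[j - 1]);
      --i; --j; st = pr;
      if (i == 0 && j == 0) break;
    } else if (st == 1) { // IY
      signed char pr = pIY[at(i, j)];
      if (pr == 9) { // free leading ref run
        for (; j > 0; --j) { rrow.push_back(ref[j - 1]); qrow.push_back('-'); }
        break;
      }
      qrow.push_back('-'); rrow.push_back(ref[j - 1]);
      --j; st = pr;
      if (i == 0 && j == 0) break;
    } else { // IX
      signed char pr = pIX[at(i, j)];
      if (pr == 9) { // free leading query run
        for (; i > 0; --i) { qrow.push_back(query[i - 1]); rrow.push_back('-'); }
        break;
      }
      qrow.push_back(query[i - 1]); rrow.push_back('-');
      --i; st = pr;
      if (i == 0 && j == 0) break;
    }
  }
  std::string q(qrow.rbegin(), qrow.rend()), r(rrow.rbegin(), rrow.rend());
  return List::create(_["query_row"] = q, _["ref_row"] = r,
                      _["score"] = (double)bestScore);
}

// Exhaustive enumeration oracle: scores every gapped alignment of a vs b under
// the same convention (affine gap_open + L*gap_extend; the single gap run
// touching each end is free) and returns the optimum. Shares no logic with the
// DP above. Intended for short strings only.
namespace {

struct BF {
  const std::string *a, *b;
  double ma, mi, go, ge;
  double best;
  char ops[64];
};

static double bf_score(BF &bf, int len) {
  const std::string &a = *bf.a, &b = *bf.b;
  double sc = 0.0;
  int i = 0, j = 0, t = 0;
  while (t < len) {
    char op = bf.ops[t];
    if (op == 'M') {
      sc += (a[i] == b[j]) ? bf.ma : bf.mi;
      ++i; ++j; ++t;
    } else {
      int start = t;
      while (t < len && bf.ops[t] == op) ++t;
      int L = t - start;
      bool at_end = (start == 0) || (t == len);
      if (!at_end) sc += bf.go + L * bf.ge;
      if (op == 'X') i += L; else j += L;
    }
  }
  return sc;
}

static void bf_rec(BF &bf, int i, int j, int t) {
  const int n = (int)bf.a->size(), m = (int)bf.b->size();
  if (i == n && j == m) {
    double s = bf_score(bf, t);
    if (s > bf.best) bf.best = s;
    return;
  }
  if (i < n && j < m) { bf.ops[t] = 'M'; bf_rec(bf, i + 1, j + 1, t + 1); }
  if (i < n) { bf.ops[t] = 'X'; bf_rec(bf, i + 1, j, t + 1); }
  if (j < m) { bf.ops[t] = 'Y'; bf_rec(bf, i, j + 1, t + 1); }
}

} // namespace

// [[Rcpp::export]]
double cpp_bruteforce_align_score(std::string a, std::string b,
                                  double match, double mismatch,
                                  double gap_open, double gap_extend) {
  if (a.size() > 14 || b.size() > 14)
    stop("brute-force enumeration is limited to strings of length <= 14");
  BF bf; bf.a = &a; bf.b = &b;
  bf.ma = match; bf.mi = mismatch; bf.go = gap_open; bf.ge = gap_extend;
  bf.best = -std::numeric_limits<double>::infinity();
  bf_rec(bf, 0, 0, 0);
  return bf.best;
}
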