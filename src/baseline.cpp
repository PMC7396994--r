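#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

// Minimal seed-and-extend placement: exact k-mer seeds vote for a diagonal
// (both strands), the best diagonal defines a reference window, and the read
// is aligned to the window with an affine-gap semi-global DP (read global,
// window ends free). This deliberately emulates the behaviour class of a
// standard mapping pipeline, not any specific tool.

static const double NEG = -std::numeric_limits<double>::infinity();

static std::string rc(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r)
    c = (c == 'A') ? 'T' : (c == 'C') ? 'G' : (c == 'G') ? 'C' : (c == 'T') ? 'A' : 'N';
  return r;
}

struct Placement {
  bool placed = false;
  int start = 0;        // 1-based ref position of first consumed ref base
  bool fwd = true;
  double score = 0.0;
  std::string ops;      // one char per alignment column: M/X/I/D
  std::string read;     // oriented read actually aligned
};

typedef std::unordered_map<std::string, std::vector<int> > SeedIndex;

static SeedIndex build_index(const std::string &ref, int k) {
  SeedIndex idx;
  int n = (int)ref.size();
  for (int i = 0; i + k <= n; ++i) idx[ref.substr(i, k)].push_back(i); // 0-based
  return idx;
}

// Anchor on the first exact seed (leftmost read k-mer with a hit, leftmost
// reference occurrence) — the naive anchoring a minimal mapper performs, and
// the reason reads crossing an in-repeat indel junction drag their far side
// into shifted, mismatching alignment columns. Returns the total number of
// seed hits on the anchored diagonal (0 when the read has no seed at all),
// which also serves strand selection and the exact-match fast path.
static int best_diagonal(const std::string &read, const SeedIndex &idx, int k,
                         int &diag_out) {
  int L = (int)read.size();
  int first_diag = 0;
  bool anchored = false;
  std::map<int, int> votes;
  for (int o = 0; o + k <= L; ++o) {
    auto it = idx.find(read.substr(o, k));
    if (it == idx.end()) continue;
    if (!anchored) {
      first_diag = it->second.front() - o;
      anchored = true;
    }
    for (int p : it->second) votes[p - o]++;
  }
  if (!anchored) { diag_out = 0; return 0; }
  diag_out = first_diag;
  return votes[first_diag];
}

// semi-global: read fully aligned, leading/trailing window gaps free.
// gap of length L costs go + L*ge. Returns ops + window offset of first ref base.
static void extend(const std::string &read, const std::string &win,
                   double ma, double mi, double go, double ge,
                   double &score, std::string &ops, int &first_ref) {
  const int n = (int)read.size(), m = (int)win.size();
  std::vector<double> M((n + 1) * (m + 1), NEG), IX((n + 1) * (m + 1), NEG),
      IY((n + 1) * (m + 1), NEG);
  std::vector<signed char> pM((n + 1) * (m + 1), -1), pIX((n + 1) * (m + 1), -1),
      pIY((n + 1) * (m + 1), -1);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) { IY[at(0, j)] = 0.0; pIY[at(0, j)] = 9; }
  for (int i = 1; i <= n; ++i) { // leading read overhang is NOT free (penalized)
    IX[at(i, 0)] = go + i * ge;
    pIX[at(i, 0)] = (i == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int c = at(i, j), d = at(i - 1, j - 1), u = at(i - 1, j), l = at(i, j - 1);
      double best = M[d]; signed char arg = 0;
      if (IY[d] > best) { best = IY[d]; arg = 1; }
      if (IX[d] > best) { best = IX[d]; arg = 2; }
      M[c] = best + ((read[i - 1] == win[j - 1]) ? ma : mi); pM[c] = arg;
      best = M[l] + go + ge; arg = 0;
      if (IY[l] + ge > best) { best = IY[l] + ge; arg = 1; }
      if (IX[l] + go + ge > best) { best = IX[l] + go + ge; arg = 2; }
      IY[c] = best; pIY[c] = arg;
      best = M[u] + go + ge; arg = 0;
      if (IY[u] + go + ge > best) { best = IY[u] + go + ge; arg = 1; }
      if (IX[u] + ge > best) { best = IX[u] + ge; arg = 2; }
      IX[c] = best; pIX[c] = arg;
    }
  }
  // read must be consumed; trailing window free: max over last row
  double bs = NEG; int bj = m; signed char bstate = 0;
  for (int j = m; j >= 0; --j) {
    int c = at(n, j);
    double v[3] = { M[c], IY[c], IX[c] };
    for (int s = 0; s < 3; ++s)
      if (v[s] > bs) { bs = v[s]; bj = j; bstate = (signed char)s; }
  }
  score = bs;
  std::string rops;
  int i = n, j = bj; signed char st = bstate;
  while (!(i == 0 && j == 0)) {
    if (st == 0) {
      signed char pr = pM[at(i, j)];
      rops.push_back(read[i - 1] == win[j - 1] ? 'M' : 'X');
      --i; --j; st = pr;
    } else if (st == 1) {
      signed char pr = pIY[at(i, j)];
      if (pr == 9) break; // free leading window run; j = window offset
      rops.push_back('D'); --j; st = pr;
    } else {
      signed char pr = pIX[at(i, j)];
      rops.push_back('I'); --i; st = pr;
    }
  }
  first_ref = j; // 0-based window offset of first column's ref base
  ops.assign(rops.rbegin(), rops.rend());
}

static Placement place_one(const std::string &read, const std::string &ref,
                           const SeedIndex &idx, int seed_k, int band,
                           double ma, double mi, double go, double ge) {
  Placement pl;
  int L = (int)read.size();
  if (L < seed_k) return pl;
  std::string rcread = rc(read);
  int df = 0, dr = 0;
  int vf = best_diagonal(read, idx, seed_k, df);
  int vr = best_diagonal(rcread, idx, seed_k, dr);
  if (vf == 0 && vr == 0) return pl;
  bool fwd = vf >= vr;
  const std::string &r = fwd ? read : rcread;
  int d = fwd ? df : dr;
  // fast path: every k-mer voted one diagonal and the read matches exactly
  if ((fwd ? vf : vr) == L - seed_k + 1 && d >= 0 &&
      d + L <= (int)ref.size() && ref.compare(d, L, r) == 0) {
    pl.placed = true;
    pl.start = d + 1;
    pl.fwd = fwd;
    pl.score = ma * L;
    pl.ops.assign((size_t)L, 'M');
    pl.read = r;
    return pl;
  }
  int ws = std::max(0, d - band);
  int we = std::min((int)ref.size(), d + L + band);
  if (we <= ws) return pl;
  std::string win = ref.substr(ws, we - ws);
  double sc; std::string ops; int fr;
  extend(r, win, ma, mi, go, ge, sc, ops, fr);
  pl.placed = true;
  pl.start = ws + fr + 1; // 1-based
  pl.fwd = fwd;
  pl.score = sc;
  pl.ops = ops;
  pl.read = r;
  return pl;
}

// [[Rcpp::export]]
List cpp_place_read(std::string read, std::string ref, int seed_k, int band,
                    double match, double mismatch, double gap_open,
                    double gap_extend) {
  SeedIndex idx = build_index(ref, seed_k);
  Placement pl = place_one(read, ref, idx, seed_k, band, match, mismatch,
                           gap_open, gap_extend);
  return List::create(_["placed"] = pl.placed, _["start"] = pl.start,
                      _["strand"] = std::string(pl.fwd ? "+" : "-"),
                      _["score"] = pl.score, _["ops"] = pl.ops,
                      _["read_oriented"] = pl.read);
}

// Pileup over all reads: per-position A/C/G/T and deletion counts plus
// insertion strings keyed by the reference position they follow.
// [[Rcpp::export]]
List cpp_pileup(CharacterVector reads, std::string ref, int seed_k, int band,
                double match, double mismatch, double gap_open,
                double gap_extend) {
  SeedIndex idx = build_index(ref, seed_k);
  int n = (int)ref.size();
  IntegerMatrix acgt(4, n);
  IntegerVector del(n);
  std::map<std::pair<int, std::string>, int> ins;
  int placed_n = 0;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string rd = as<std::string>(reads[r]);
    Placement pl = place_one(rd, ref, idx, seed_k, band, match, mismatch,
                             gap_open, gap_extend);
    if (!pl.placed) continue;
    ++placed_n;
    int pos = pl.start - 1; // 0-based next ref base
    size_t qi = 0;
    std::string cur_ins;
    for (char op : pl.ops) {
      if (op == 'I') { cur_ins.push_back(pl.read[qi++]); continue; }
      if (!cur_ins.empty()) {
        if (pos > 0) ins[std::make_pair(pos, cur_ins)]++; // after ref pos (1-based)
        cur_ins.clear();
      }
      if (op == 'M' || op == 'X') {
        char c = pl.read[qi++];
        int b = (c == 'A') ? 0 : (c == 'C') ? 1 : (c == 'G') ? 2 : (c == 'T') ? 3 : -1;
        if (b >= 0 && pos < n) acgt(b, pos)++;
        ++pos;
      } else if (op == 'D') {
        if (pos < n) del[pos]++;
        ++pos;
      }
    }
    // trailing insertion (read overhang past window) ignored
  }
  IntegerVector ins_pos((int)ins.size());
  CharacterVector ins_seq((int)ins.size());
  IntegerVector ins_count((int)ins.size());
  int i = 0;
  for (auto &kv : ins) {
    ins_pos[i] = kv.first.first;     // 1-based position the insertion follows
    ins_seq[i] = kv.first.second;
    ins_count[i] = kv.second;
    ++i;
  }
  return List::create(_["acgt"] = acgt, _["del"] = del,
                      _["ins_pos"] = ins_pos, _["ins_seq"] = ins_seq,
                      _["ins_count"] = ins_count, _["n_placed"] = placed_n);
}
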