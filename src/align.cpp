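#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <string>
#include <vector>
#include <cstdint>
#include <climits>

using namespace Rcpp;

// Scoring for the banded aligner. Long accurate reads need nothing fancier
// than linear gap costs; identity is recomputed from the traceback anyway.
static const int SC_MATCH = 2;
static const int SC_MISMATCH = -4;
static const int SC_GAP = -3;
static const int NEG = INT_MIN / 4;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// All k-mer hits shared between q and s (forward strand only; the caller
// reverse-complements for the other strand). k <= 31. Positions 0-based.
// [[Rcpp::export]]
IntegerMatrix c_seed_hits(std::string q, std::string s, int k) {
  const int nq = (int)q.size(), ns = (int)s.size();
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  if (nq < k || ns < k) return IntegerMatrix(0, 2);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  std::unordered_multimap<uint64_t, int> tab;
  tab.reserve(ns);
  {
    uint64_t v = 0; int run = 0;
    for (int i = 0; i < ns; ++i) {
      int c = base_code(s[i]);
      if (c < 0) { run = 0; v = 0; continue; }
      v = ((v << 2) | (uint64_t)c) & mask;
      if (++run >= k) tab.emplace(v, i - k + 1);
    }
  }
  std::vector<int> qpos, spos;
  {
    uint64_t v = 0; int run = 0;
    for (int i = 0; i < nq; ++i) {
      int c = base_code(q[i]);
      if (c < 0) { run = 0; v = 0; continue; }
      v = ((v << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        auto rng = tab.equal_range(v);
        for (auto it = rng.first; it != rng.second; ++it) {
          qpos.push_back(i - k + 1);
          spos.push_back(it->second);
          if (qpos.size() > 5000000) stop("seed hit count exceeded 5e6; sequences too repetitive");
        }
      }
    }
  }
  IntegerMatrix out((int)qpos.size(), 2);
  for (int i = 0; i < (int)qpos.size(); ++i) { out(i, 0) = qpos[i]; out(i, 1) = spos[i]; }
  return out;
}

// Banded pairwise alignment of a (query, always fully aligned) against b
// (subject). The band is centred on the corridor of diagonals joining
// (0,0) to (n,m), widened by `band` on each side. Optionally the subject's
// leading/trailing overhangs are free (semi-global). Returns traceback
// statistics and a CIGAR-style run encoding (ops: 0 = M, 1 = I insertion
// in query, 2 = D deletion from query / gap to subject).
// [[Rcpp::export]]
List c_banded_align(std::string a, std::string b, int band,
                    bool free_b_start, bool free_b_end) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence in alignment");
  const int lo = std::min(0, m - n) - band;
  const int hi = std::max(0, m - n) + band;
  const int w = hi - lo + 1;
  if ((double)(n + 1) * (double)w > 4e8) stop("alignment band too large");

  std::vector<int> prev(w, NEG), cur(w, NEG);
  std::vector<uint8_t> trace((size_t)(n + 1) * (size_t)w, 0);

  // row 0
  for (int j = std::max(0, 0 + lo); j <= std::min(m, 0 + hi); ++j) {
    int idx = j - 0 - lo;
    prev[idx] = free_b_start ? 0 : SC_GAP * j;
    trace[idx] = (j == 0) ? 0 : 3; // 3 = left
  }
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), NEG);
    const int jlo = std::max(0, i + lo), jhi = std::min(m, i + hi);
    const char ai = a[i - 1];
    uint8_t *trow = &trace[(size_t)i * w];
    for (int j = jlo; j <= jhi; ++j) {
      const int idx = j - i - lo;
      int best = NEG; uint8_t mv = 0;
      if (j > 0) { // diag
        int p = prev[idx];
        if (p > NEG) {
          int sc = p + (ai == b[j - 1] ? SC_MATCH : SC_MISMATCH);
          if (sc > best) { best = sc; mv = 1; }
        }
      }
      if (idx + 1 < w) { // up: gap in b (I)
        int p = prev[idx + 1];
        if (p > NEG) { int sc = p + SC_GAP; if (sc > best) { best = sc; mv = 2; } }
      }
      if (j > 0 && idx - 1 >= 0) { // left: gap in a (D)
        int p = cur[idx - 1];
        if (p > NEG) { int sc = p + SC_GAP; if (sc > best) { best = sc; mv = 3; } }
      }
      if (mv == 0 && !(i == 0 && j == 0)) { cur[idx] = NEG; trow[idx] = 0; continue; }
      cur[idx] = best; trow[idx] = mv;
    }
    std::swap(prev, cur);
  }

  // end cell
  int jend = m, best = NEG;
  const int jlo_n = std::max(0, n + lo), jhi_n = std::min(m, n + hi);
  if (free_b_end) {
    for (int j = jlo_n; j <= jhi_n; ++j) {
      int v = prev[j - n - lo];
      if (v > best || (v == best && j < jend)) { best = v; jend = j; }
    }
  } else {
    if (m < jlo_n || m > jhi_n) stop("global end cell outside band");
    best = prev[m - n - lo];
  }
  if (best <= NEG) stop("no alignment within band");

  // traceback
  std::vector<int> r_ops, r_lens;
  int i = n, j = jend, matches = 0, columns = 0;
  int max_ins = 0, max_del = 0;
  int cur_op = -1, cur_len = 0;
  auto push = [&](int op) {
    if (op == cur_op) { ++cur_len; return; }
    if (cur_op >= 0) {
      r_ops.push_back(cur_op); r_lens.push_back(cur_len);
      if (cur_op == 1 && cur_len > max_ins) max_ins = cur_len;
      if (cur_op == 2 && cur_len > max_del) max_del = cur_len;
    }
    cur_op = op; cur_len = 1;
  };
  while (i > 0) {
    uint8_t mv = trace[(size_t)i * w + (j - i - lo)];
    if (mv == 1) { if (a[i - 1] == b[j - 1]) ++matches; ++columns; push(0); --i; --j; }
    else if (mv == 2) { ++columns; push(1); --i; }
    else if (mv == 3) { ++columns; push(2); --j; }
    else stop("corrupt traceback");
  }
  int b_start = j;
  if (!free_b_start) { while (j > 0) { ++columns; push(2); --j; } b_start = 0; }
  push(-2); // flush
  std::reverse(r_ops.begin(), r_ops.end());
  std::reverse(r_lens.begin(), r_lens.end());

  return List::create(
    _["score"] = best, _["matches"] = matches, _["columns"] = columns,
    _["b_start"] = b_start, _["b_end"] = jend,
    _["ops"] = IntegerVector(r_ops.begin(), r_ops.end()),
    _["lens"] = IntegerVector(r_lens.begin(), r_lens.end()),
    _["max_ins"] = max_ins, _["max_del"] = max_del);
}

// Majority-vote polish of a backbone string from read alignments.
// starts: 0-based backbone position where each read's alignment begins;
// seqs: the aligned (oriented, clipped) read substrings; ops/lens: the
// CIGAR runs from c_banded_align for read-vs-backbone. Ties are broken
// toward the vote cast by the earliest read in the layout (input order).
// [[Rcpp::export]]
std::string c_pileup_consensus(std::string backbone, IntegerVector starts,
                               CharacterVector seqs, List ops_list, List lens_list) {
  const int L = (int)backbone.size();
  const int nr = starts.size();
  // counts: A C G T del
  std::vector<std::array<int, 5>> cnt((size_t)L, {0, 0, 0, 0, 0});
  std::vector<std::array<int, 5>> first((size_t)L, {INT_MAX, INT_MAX, INT_MAX, INT_MAX, INT_MAX});
  // insertions keyed by backbone position they precede
  std::map<int, std::map<std::string, std::pair<int, int>>> ins;

  for (int r = 0; r < nr; ++r) {
    std::string sq = as<std::string>(seqs[r]);
    IntegerVector ops = ops_list[r], lens = lens_list[r];
    int pos = starts[r], qi = 0;
    for (int t = 0; t < ops.size(); ++t) {
      int op = ops[t], len = lens[t];
      if (op == 0) {
        for (int x = 0; x < len; ++x) {
          if (pos >= 0 && pos < L) {
            int c = base_code(sq[qi]);
            if (c >= 0) {
              cnt[pos][c]++;
              if (r < first[pos][c]) first[pos][c] = r;
            }
          }
          ++pos; ++qi;
        }
      } else if (op == 1) { // insertion relative to backbone, before `pos`
        std::string piece = sq.substr(qi, len);
        auto &slot = ins[pos][piece];
        if (slot.first == 0) slot.second = r;
        slot.first++;
        qi += len;
      } else { // deletion: reads vote to remove backbone bases
        for (int x = 0; x < len; ++x) {
          if (pos >= 0 && pos < L) {
            cnt[pos][4]++;
            if (r < first[pos][4]) first[pos][4] = r;
          }
          ++pos;
        }
      }
    }
  }

  std::string out;
  out.reserve((size_t)L + 64);
  for (int pos = 0; pos <= L; ++pos) {
    int depth_here = 0;
    {
      int p = std::min(pos, L - 1);
      for (int c = 0; c < 5; ++c) depth_here += cnt[p][c];
    }
    auto it = ins.find(pos);
    if (it != ins.end() && depth_here > 0) {
      // majority-supported insertion before pos
      int bc = 0, br = INT_MAX; const std::string *bs = nullptr;
      for (auto &kv : it->second) {
        if (kv.second.first > bc ||
            (kv.second.first == bc && kv.second.second < br)) {
          bc = kv.second.first; br = kv.second.second; bs = &kv.first;
        }
      }
      if (bs && 2 * bc > depth_here) out += *bs;
    }
    if (pos == L) break;
    int depth = 0;
    for (int c = 0; c < 5; ++c) depth += cnt[pos][c];
    if (depth == 0) { out += backbone[pos]; continue; }
    int win = -1, wc = -1, wf = INT_MAX;
    for (int c = 0; c < 5; ++c) {
      if (cnt[pos][c] > wc || (cnt[pos][c] == wc && first[pos][c] < wf)) {
        win = c; wc = cnt[pos][c]; wf = first[pos][c];
      }
    }
    if (win < 4) out += "ACGT"[win];
    // win == 4: majority deletion, base dropped
  }
  return out;
}
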