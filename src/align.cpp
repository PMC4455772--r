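// Local alignment kernels: an exhaustive Smith-Waterman scan (test oracle)
// and a word-seeded, band-limited Smith-Waterman (the production aligner).
// Both emit the same hit records; statistics (bitscore, e-value) are applied
// by the R layer. Affine gaps: a length-L gap costs gap_open + L * gap_extend.

#include <Rcpp.h>
#include <unordered_map>
#include <set>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

// A,C,G,T -> 0..3; anything else -> 4 (mismatches everything, incl. itself)
inline uint8_t base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default:            return 4;
  }
}

std::vector<uint8_t> encode(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

struct Hit {
  int sstart, send;   // subject, 0-based half-open
  int qstart, qend;   // query, 0-based half-open
  int score;
  std::string qaln, saln;
  int dmin, dmax;     // diagonal range (subject - query) spanned by the path
};

// Direction codes for the H (match) state
enum { DIR_STOP = 0, DIR_DIAG = 1, DIR_E = 2, DIR_F = 3 };

// Greedy resolution of overlapping hits: keep the highest-scoring hit in any
// overlapping same-diagonal-band cluster. Ties broken by (sstart, send).
std::vector<Hit> dedupe_hits(std::vector<Hit>& hits, int band) {
  std::vector<int> idx(hits.size());
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = (int)i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (hits[a].score != hits[b].score) return hits[a].score > hits[b].score;
    if (hits[a].sstart != hits[b].sstart) return hits[a].sstart < hits[b].sstart;
    return hits[a].send < hits[b].send;
  });
  std::vector<Hit> kept;
  for (int i : idx) {
    const Hit& h = hits[i];
    bool clash = false;
    for (const Hit& a : kept) {
      bool overlap = h.sstart < a.send && a.sstart < h.send;
      bool diag_close = (h.dmin - band) <= a.dmax && a.dmin <= (h.dmax + band);
      if (overlap && diag_close) { clash = true; break; }
    }
    if (!clash) kept.push_back(h);
  }
  std::sort(kept.begin(), kept.end(), [](const Hit& a, const Hit& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.sstart != b.sstart) return a.sstart < b.sstart;
    return a.send < b.send;
  });
  return kept;
}

DataFrame hits_to_df(const std::vector<Hit>& hits) {
  int n = (int)hits.size();
  IntegerVector sstart(n), send(n), qstart(n), qend(n), score(n);
  CharacterVector qaln(n), saln(n);
  for (int i = 0; i < n; ++i) {
    sstart[i] = hits[i].sstart; send[i] = hits[i].send;
    qstart[i] = hits[i].qstart; qend[i] = hits[i].qend;
    score[i] = hits[i].score;
    qaln[i] = hits[i].qaln; saln[i] = hits[i].saln;
  }
  return DataFrame::create(
    _["sstart"] = sstart, _["send"] = send,
    _["qstart"] = qstart, _["qend"] = qend,
    _["score"] = score, _["qaln"] = qaln, _["saln"] = saln,
    _["stringsAsFactors"] = false);
}

} // namespace

// Exhaustive Smith-Waterman over the whole subject. Every cell scoring at
// least min_score seeds a traceback; overlapping paths in the same diagonal
// band collapse to the highest-scoring one.
// [[Rcpp::export(name = ".cpp_sw_hits")]]
DataFrame cpp_sw_hits(std::string query, std::string subject,
                      int reward, int penalty, int gap_open, int gap_extend,
                      int min_score, int band) {
  std::vector<uint8_t> q = encode(query), s = encode(subject);
  const int m = (int)q.size(), n = (int)s.size();
  if (min_score < 1) min_score = 1;
  const int NEG = -1000000000;
  const int open_cost = gap_open + gap_extend;

  // rolling rows for H/E/F; full byte matrices for traceback
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), Fprev(n + 1, NEG), Fcur(n + 1, NEG);
  std::vector<uint8_t> dirH((size_t)(m + 1) * (n + 1), DIR_STOP);
  std::vector<uint8_t> extE((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> extF((size_t)(m + 1) * (n + 1), 0);

  struct Cell { int i, j, h; };
  std::vector<Cell> cand;

  for (int i = 1; i <= m; ++i) {
    int E = NEG;
    Hcur[0] = 0; Fcur[0] = NEG;
    size_t row = (size_t)i * (n + 1);
    for (int j = 1; j <= n; ++j) {
      int e_open = Hcur[j - 1] - open_cost;
      int e_ext  = E - gap_extend;
      E = std::max(e_open, e_ext);
      extE[row + j] = (uint8_t)(e_ext >= e_open ? 1 : 0);
      int f_open = Hprev[j] - open_cost;
      int f_ext  = Fprev[j] - gap_extend;
      int F = std::max(f_open, f_ext);
      extF[row + j] = (uint8_t)(f_ext >= f_open ? 1 : 0);
      Fcur[j] = F;
      int sub = (q[i - 1] == s[j - 1] && q[i - 1] < 4) ? reward : penalty;
      int diag = Hprev[j - 1] + sub;
      int best = 0; uint8_t dir = DIR_STOP;
      if (diag > best) { best = diag; dir = DIR_DIAG; }
      if (E > best)    { best = E;    dir = DIR_E; }
      if (F > best)    { best = F;    dir = DIR_F; }
      Hcur[j] = best; dirH[row + j] = dir;
      if (best >= min_score) cand.push_back({i, j, best});
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }

  std::sort(cand.begin(), cand.end(), [](const Cell& a, const Cell& b) {
    if (a.h != b.h) return a.h > b.h;
    if (a.j != b.j) return a.j < b.j;
    return a.i < b.i;
  });

  std::vector<Hit> kept;
  for (const Cell& c : cand) {
    int d_end = c.j - c.i;
    bool skip = false;
    for (const Hit& a : kept) {
      bool diag_close = (d_end - band) <= a.dmax && a.dmin <= (d_end + band);
      if (diag_close && c.j > a.sstart && c.j <= a.send + m + 2 * band) { skip = true; break; }
    }
    if (skip) continue;
    // traceback
    std::string qa, sa;
    int i = c.i, j = c.j;
    int dmin = j - i, dmax = j - i;
    while (i > 0 && j > 0) {
      size_t row = (size_t)i * (n + 1);
      uint8_t dir = dirH[row + j];
      if (dir == DIR_STOP) break;
      if (dir == DIR_DIAG) {
        qa.push_back(query[i - 1]); sa.push_back(subject[j - 1]);
        --i; --j;
      } else if (dir == DIR_E) { // gap in query, subject consumed
        bool ext = true;
        while (ext && j > 0) {
          ext = extE[(size_t)i * (n + 1) + j] != 0;
          qa.push_back('-'); sa.push_back(subject[j - 1]);
          --j;
        }
      } else { // DIR_F: gap in subject, query consumed
        bool ext = true;
        while (ext && i > 0) {
          ext = extF[(size_t)i * (n + 1) + j] != 0;
          qa.push_back(query[i - 1]); sa.push_back('-');
          --i;
        }
      }
      int d = j - i;
      if (d < dmin) dmin = d;
      if (d > dmax) dmax = d;
    }
    std::reverse(qa.begin(), qa.end());
    std::reverse(sa.begin(), sa.end());
    Hit h{j, c.j, i, c.i, c.h, qa, sa, dmin, dmax};
    bool clash = false;
    for (const Hit& a : kept) {
      bool overlap = h.sstart < a.send && a.sstart < h.send;
      bool diag_close = (h.dmin - band) <= a.dmax && a.dmin <= (h.dmax + band);
      if (overlap && diag_close) { clash = true; break; }
    }
    if (!clash) kept.push_back(h);
  }

  std::vector<Hit> out = kept;
  out = dedupe_hits(out, band);
  return hits_to_df(out);
}

// Band-limited local DP around one diagonal. Returns best-scoring hit in the
// band, or score 0 if nothing reaches min_score.
static bool banded_sw(const std::string& query, const std::string& subject,
                      const std::vector<uint8_t>& q, const std::vector<uint8_t>& s,
                      int diag, int band,
                      int reward, int penalty, int gap_open, int gap_extend,
                      int min_score, Hit& out) {
  const int m = (int)q.size(), n = (int)s.size();
  const int W = 2 * band + 1;
  const int NEG = -1000000000;
  const int open_cost = gap_open + gap_extend;

  // H[i][k] with k = j - i - diag + band, j = diag + i + k - band
  std::vector<int> Hmat((size_t)(m + 1) * W, NEG), Fmat((size_t)(m + 1) * W, NEG);
  std::vector<uint8_t> dirH((size_t)(m + 1) * W, DIR_STOP);
  std::vector<uint8_t> extE((size_t)(m + 1) * W, 0), extF((size_t)(m + 1) * W, 0);

  for (int k = 0; k < W; ++k) {
    int j = diag + 0 + k - band;
    if (j >= 0 && j <= n) Hmat[k] = 0;
  }
  int best = 0, bi = -1, bk = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    size_t row = (size_t)i * W, prow = (size_t)(i - 1) * W;
    int E = NEG;
    for (int k = 0; k < W; ++k) {
      int j = diag + i + k - band;
      if (j < 1 || j > n) { Hmat[row + k] = (j == 0) ? 0 : NEG; Fmat[row + k] = NEG; E = NEG; continue; }
      // E from (i, j-1) = k-1 in same row; F from (i-1, j) = k+1 in prev row
      int e_open = (k >= 1 && Hmat[row + k - 1] > NEG / 2) ? Hmat[row + k - 1] - open_cost : NEG;
      int e_ext  = (E > NEG / 2) ? E - gap_extend : NEG;
      E = std::max(e_open, e_ext);
      extE[row + k] = (uint8_t)(e_ext >= e_open ? 1 : 0);
      int f_open = (k + 1 < W && Hmat[prow + k + 1] > NEG / 2) ? Hmat[prow + k + 1] - open_cost : NEG;
      int f_ext  = (k + 1 < W && Fmat[prow + k + 1] > NEG / 2) ? Fmat[prow + k + 1] - gap_extend : NEG;
      int F = std::max(f_open, f_ext);
      extF[row + k] = (uint8_t)(f_ext >= f_open ? 1 : 0);
      Fmat[row + k] = F;
      int diag_h = Hmat[prow + k];  // (i-1, j-1) has same k
      int sub = (q[i - 1] == s[j - 1] && q[i - 1] < 4) ? reward : penalty;
      int dval = (diag_h > NEG / 2) ? diag_h + sub : NEG;
      int h = 0; uint8_t dir = DIR_STOP;
      if (dval > h) { h = dval; dir = DIR_DIAG; }
      if (E > h)    { h = E;    dir = DIR_E; }
      if (F > h)    { h = F;    dir = DIR_F; }
      Hmat[row + k] = h; dirH[row + k] = dir;
      if (h > best) { best = h; bi = i; bk = k; bj = j; }
      else if (h == best && h > 0 && (j < bj || (j == bj && i < bi))) {
        bi = i; bk = k; bj = j;
      }
    }
  }
  if (best < min_score || bi < 0) return false;

  std::string qa, sa;
  int i = bi, k = bk;
  int j = diag + i + k - band;
  int endi = i, endj = j;
  int dmin = j - i, dmax = j - i;
  while (i > 0 && j > 0) {
    size_t row = (size_t)i * W;
    k = j - i - diag + band;
    if (k < 0 || k >= W) break;
    uint8_t dir = dirH[row + k];
    if (dir == DIR_STOP) break;
    if (dir == DIR_DIAG) {
      qa.push_back(query[i - 1]); sa.push_back(subject[j - 1]);
      --i; --j;
    } else if (dir == DIR_E) {
      bool ext = true;
      while (ext && j > 0) {
        int kk = j - i - diag + band;
        if (kk < 0 || kk >= W) break;
        ext = extE[(size_t)i * W + kk] != 0;
        qa.push_back('-'); sa.push_back(subject[j - 1]);
        --j;
      }
    } else {
      bool ext = true;
      while (ext && i > 0) {
        int kk = j - i - diag + band;
        if (kk < 0 || kk >= W) break;
        ext = extF[(size_t)i * W + kk] != 0;
        qa.push_back(query[i - 1]); sa.push_back('-');
        --i;
      }
    }
    int d = j - i;
    if (d < dmin) dmin = d;
    if (d > dmax) dmax = d;
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  out = Hit{j, endj, i, endi, best, qa, sa, dmin, dmax};
  return true;
}

// Seed-and-extend: exact word matches (word_size-mers) define candidate
// diagonals; each is extended with a banded local DP.
// [[Rcpp::export(name = ".cpp_seed_hits")]]
DataFrame cpp_seed_hits(std::string query, std::string subject,
                        int word_size, int reward, int penalty,
                        int gap_open, int gap_extend,
                        int min_score, int band) {
  std::vector<uint8_t> q = encode(query), s = encode(subject);
  const int m = (int)q.size(), n = (int)s.size();
  if (min_score < 1) min_score = 1;
  std::vector<Hit> hits;
  if (m >= word_size && n >= word_size) {
    // index query words
    std::unordered_multimap<uint32_t, int> words;
    uint32_t mask = (word_size >= 16) ? 0xFFFFFFFFu : ((1u << (2 * word_size)) - 1);
    uint32_t code = 0; int valid = 0;
    for (int i = 0; i < m; ++i) {
      if (q[i] < 4) { code = ((code << 2) | q[i]) & mask; ++valid; }
      else { code = 0; valid = 0; }
      if (valid >= word_size) words.insert({code, i - word_size + 1});
    }
    // scan subject
    std::set<int> diags;
    code = 0; valid = 0;
    for (int j = 0; j < n; ++j) {
      if (s[j] < 4) { code = ((code << 2) | s[j]) & mask; ++valid; }
      else { code = 0; valid = 0; }
      if (valid >= word_size) {
        auto range = words.equal_range(code);
        int spos = j - word_size + 1;
        for (auto it = range.first; it != range.second; ++it)
          diags.insert(spos - it->second);
      }
    }
    for (int d : diags) {
      Hit h;
      if (banded_sw(query, subject, q, s, d, band, reward, penalty,
                    gap_open, gap_extend, min_score, h))
        hits.push_back(h);
    }
  }
  std::vector<Hit> out = dedupe_hits(hits, band);
  return hits_to_df(out);
}
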