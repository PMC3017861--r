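#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// base encoding: A=0 C=1 G=2 T=3, anything else (incl. N) = 4.
static inline int enc_base(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'a': return 't';
  case 'C': return 'G'; case 'c': return 'g';
  case 'G': return 'C'; case 'g': return 'c';
  case 'T': return 'A'; case 't': return 'a';
  default: return 'N';
  }
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j)
      r[s.size() - 1 - j] = comp_base(s[j]);
    out[i] = r;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Smith-Waterman (Gotoh affine gaps) with traceback and iterative query
// masking so that additional non-overlapping (on the query) local alignments
// are reported.  A gap of length L costs gap_open + L * gap_extend.
// N never scores as a match (always the mismatch score).
// ---------------------------------------------------------------------------

struct SwHit {
  int qs, qe, ss, se, score, matches, mism, gapcols, alen;
  std::vector<int> qpath, spath; // per alignment column; -1 = gap
};

static bool sw_one(const std::string &q, const std::string &s,
                   int match, int mismatch, int gopen, int gext,
                   const std::vector<char> &qmask, bool want_path,
                   SwHit &hit) {
  const int m = (int)q.size(), n = (int)s.size();
  std::vector<int> qe_(m), se_(n);
  for (int i = 0; i < m; ++i) qe_[i] = enc_base(q[i]);
  for (int j = 0; j < n; ++j) se_[j] = enc_base(s[j]);

  // traceback byte: bits 0-1 H source (0 stop, 1 diag, 2 E, 3 F),
  // bit 2 E-extend, bit 3 F-extend
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  const int NEG = INT32_MIN / 4;
  std::vector<int> H(n + 1, 0), F(n + 1, NEG);

  int best = 0, bi = 0, bj = 0;
  const int goe = gopen + gext;

  for (int i = 1; i <= m; ++i) {
    if (qmask[i - 1]) {
      for (int j = 1; j <= n; ++j) { H[j] = 0; F[j] = NEG; }
      continue;
    }
    const int qc = qe_[i - 1];
    uint8_t *tbrow = &tb[(size_t)i * (n + 1)];
    int diag = H[0], E = NEG;
    for (int j = 1; j <= n; ++j) {
      uint8_t t = 0;
      const int hup = H[j];
      // E: gap in query (consumes subject); uses the current row
      int e_open = H[j - 1] + goe;
      int e_ext  = E + gext;
      if (e_ext > e_open) { E = e_ext; t |= 4; } else E = e_open;
      // F: gap in subject (consumes query); uses the previous row
      int f_open = hup + goe;
      int f_ext  = F[j] + gext;
      if (f_ext > f_open) { F[j] = f_ext; t |= 8; } else F[j] = f_open;
      const int sub = (qc == se_[j - 1] && qc != 4) ? match : mismatch;
      const int d = diag + sub;
      int h = 0; uint8_t dir = 0;
      if (d > h) { h = d; dir = 1; }
      if (E > h) { h = E; dir = 2; }
      if (F[j] > h) { h = F[j]; dir = 3; }
      diag = hup;
      H[j] = h;
      tbrow[j] = (uint8_t)(t | dir);
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (best <= 0) return false;

  // traceback
  int i = bi, j = bj;
  std::vector<int> qp, sp;
  int matches = 0, mism = 0, gapcols = 0;
  while (i > 0 && j > 0) {
    uint8_t t = tb[(size_t)i * (n + 1) + j];
    uint8_t dir = t & 3;
    if (dir == 0) break;
    if (dir == 1) {
      qp.push_back(i - 1); sp.push_back(j - 1);
      if (qe_[i - 1] == se_[j - 1] && qe_[i - 1] != 4) ++matches; else ++mism;
      --i; --j;
    } else if (dir == 2) { // gap in query, walk E chain
      for (;;) {
        uint8_t tt = tb[(size_t)i * (n + 1) + j];
        qp.push_back(-1); sp.push_back(j - 1); ++gapcols;
        --j;
        if (!(tt & 4)) break; // opened here
      }
    } else { // gap in subject, walk F chain
      for (;;) {
        uint8_t tt = tb[(size_t)i * (n + 1) + j];
        qp.push_back(i - 1); sp.push_back(-1); ++gapcols;
        --i;
        if (!(tt & 8)) break;
      }
    }
  }
  std::reverse(qp.begin(), qp.end());
  std::reverse(sp.begin(), sp.end());

  hit.qs = i; hit.qe = bi; hit.ss = j; hit.se = bj;
  hit.score = best; hit.matches = matches; hit.mism = mism;
  hit.gapcols = gapcols; hit.alen = (int)qp.size();
  if (want_path) { hit.qpath = qp; hit.spath = sp; }
  return true;
}

// [[Rcpp::export]]
List sw_align_cpp(std::string query, std::string subject,
                  int match, int mismatch, int gap_open, int gap_extend,
                  int min_score, int max_hits, bool with_path) {
  std::vector<char> qmask(query.size(), 0);
  List hits;
  for (int h = 0; h < max_hits; ++h) {
    SwHit hit;
    if (!sw_one(query, subject, match, mismatch, gap_open, gap_extend,
                qmask, with_path, hit))
      break;
    if (hit.score < min_score) break;
    List rec = List::create(
      _["q_start"] = hit.qs, _["q_end"] = hit.qe,
      _["s_start"] = hit.ss, _["s_end"] = hit.se,
      _["score"] = hit.score, _["matches"] = hit.matches,
      _["mismatches"] = hit.mism, _["gap_columns"] = hit.gapcols,
      _["aligned_length"] = hit.alen);
    if (with_path) {
      rec["qpath"] = IntegerVector(hit.qpath.begin(), hit.qpath.end());
      rec["spath"] = IntegerVector(hit.spath.begin(), hit.spath.end());
    }
    hits.push_back(rec);
    for (int p = hit.qs; p < hit.qe; ++p) qmask[p] = 1;
  }
  return hits;
}

// ---------------------------------------------------------------------------
// Inverted-repeat scan: gap-free opposite-strand arm pairs.  An arm pair
// (i, j, L) requires S[i+t] == complement(S[j+L-1-t]) up to a mismatch budget.
// All such pairs live on anti-diagonals c = u + v of the S x S comparison
// with match(u, v) := S[u] == complement(S[v]).  Per anti-diagonal the scan
// reports the longest window that starts and ends with a match and has
// mismatches <= floor(frac * len); arms never overlap because the window is
// confined to u < v.
// ---------------------------------------------------------------------------

// Per anti-diagonal the scan reports the valid window (endpoints matching,
// length >= min_arm, mismatches <= floor(frac * len)) with the highest
// match/mismatch score; ties prefer the shorter window, then the smaller
// start, so a perfect palindrome is reported exactly rather than extended
// by chance flanking matches.
// [[Rcpp::export]]
IntegerMatrix ir_scan_cpp(std::string seq, int min_arm,
                          double max_mismatch_frac, int match_score,
                          int mismatch_score) {
  int n = (int)seq.size();
  std::vector<int> e(n);
  for (int i = 0; i < n; ++i) e[i] = enc_base(seq[i]);
  std::vector<std::array<int, 5>> rows; // lstart, rstart, len, mism, score

  for (int c = 0; c <= 2 * n - 2; ++c) {
    int lo = std::max(0, c - n + 1);
    int hi = (c - 1) / 2; // ensure v = c - u > u
    int len = hi - lo + 1;
    if (len < min_arm) continue;
    // match vector on this anti-diagonal
    std::vector<char> mvec(len);
    bool any = false;
    for (int u = lo; u <= hi; ++u) {
      int v = c - u;
      bool mt = (e[u] != 4 && e[v] != 4 && e[u] == (3 - e[v]));
      mvec[u - lo] = mt ? 1 : 0;
      if (mt) any = true;
    }
    if (!any) continue;
    int bl = -1, bb = -1, blen = 0, bm = 0;
    long bscore = INT32_MIN;
    for (int a = 0; a < len; ++a) {
      if (!mvec[a]) continue;
      if (len - a < min_arm) break;
      int mism = 0;
      for (int b = a; b < len; ++b) {
        if (!mvec[b]) { ++mism; continue; }
        int L = b - a + 1;
        if (L < min_arm) continue;
        if (mism > (int)std::floor(max_mismatch_frac * L + 1e-9)) continue;
        long sc = (long)(L - mism) * match_score + (long)mism * mismatch_score;
        if (sc > bscore ||
            (sc == bscore && (L < blen || (L == blen && a < bl)))) {
          bscore = sc; blen = L; bl = a; bb = b; bm = mism;
        }
      }
    }
    if (blen >= min_arm) {
      int i0 = lo + bl;                 // left arm start (u coords)
      int j0 = c - (lo + bb);           // right arm start
      rows.push_back({i0, j0, blen, bm, (int)bscore});
    }
  }

  IntegerMatrix out((int)rows.size(), 5);
  for (size_t r = 0; r < rows.size(); ++r)
    for (int k = 0; k < 5; ++k) out((int)r, k) = rows[r][k];
  colnames(out) = CharacterVector::create("left_start", "right_start",
                                          "arm_length", "mismatches",
                                          "score");
  return out;
}

// ---------------------------------------------------------------------------
// Exact tandem-repeat (microsatellite) scan, periods 1..6.  Reports maximal
// runs s[k] == s[k-m]; copy-number thresholds applied on the R side use
// runlen / period.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix microsat_scan_cpp(std::string seq, IntegerVector min_copies) {
  int n = (int)seq.size();
  std::vector<std::array<int, 3>> rows; // start0, period, runlen
  for (int m = 1; m <= 6 && m <= (int)min_copies.size(); ++m) {
    int need = min_copies[m - 1] * m;
    int i = 0;
    while (i + 2 * m <= n) {
      int k = i + m;
      while (k < n && seq[k] == seq[k - m] && enc_base(seq[k]) != 4) ++k;
      int runlen = k - i;
      if (runlen >= need && runlen >= 2 * m) {
        rows.push_back({i, m, runlen});
        i = k - m + 1;
      } else {
        ++i;
      }
    }
  }
  IntegerMatrix out((int)rows.size(), 3);
  for (size_t r = 0; r < rows.size(); ++r)
    for (int k = 0; k < 3; ++k) out((int)r, k) = rows[r][k];
  colnames(out) = CharacterVector::create("start", "period", "run_length");
  return out;
}

// ---------------------------------------------------------------------------
// Slippage flag: TRUE iff some window of `window` bases is dominated by a
// single nucleotide (count >= dominance * window) or the read carries an
// exact 2-periodic (dinucleotide-unit) run of length >= dominance * window.
// Reads shorter than the window are tested as a single whole-read window.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
bool slippage_flag_cpp(std::string seq, int window, double dominance) {
  int n = (int)seq.size();
  if (n == 0) return false;
  int w = std::min(window, n);
  double need = dominance * w - 1e-9;
  int cnt[5] = {0, 0, 0, 0, 0};
  for (int i = 0; i < w; ++i) cnt[enc_base(seq[i])]++;
  for (int b = 0; b < 4; ++b) if (cnt[b] >= need) return true;
  for (int i = w; i < n; ++i) {
    cnt[enc_base(seq[i])]++;
    cnt[enc_base(seq[i - w])]--;
    for (int b = 0; b < 4; ++b) if (cnt[b] >= need) return true;
  }
  // exact period-2 runs (covers (XY)n dinucleotide slippage)
  double need2 = dominance * window - 1e-9;
  int run = std::min(2, n);
  for (int i = 2; i < n; ++i) {
    if (seq[i] == seq[i - 2] && enc_base(seq[i]) != 4) ++run; else run = 2;
    if (run >= need2) return true;
  }
  return false;
}

// ---------------------------------------------------------------------------
// Canonical k-mer utilities for candidate-pair prefiltering.
// k <= 31; k-mers containing non-ACGT letters are skipped.
// ---------------------------------------------------------------------------

static void canonical_kmers(const std::string &s, int k, int stride,
                            std::vector<uint64_t> &out) {
  int n = (int)s.size();
  if (n < k) return;
  uint64_t fwd = 0, rev = 0, maskbits = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = enc_base(s[i]);
    if (b == 4) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & maskbits;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++valid >= k) {
      uint64_t key = fwd < rev ? fwd : rev;
      // content-based subsampling so two reads sample identical k-mers
      if (stride <= 1 || ((key * 0x9E3779B97F4A7C15ULL) >> 32) % stride == 0)
        out.push_back(key);
    }
  }
}

// Pairs of sequences sharing >= min_shared sampled canonical k-mers.
// Returns a 3-column matrix (i, j, shared), 1-based indices, i < j.
// [[Rcpp::export]]
IntegerMatrix kmer_pair_counts_cpp(CharacterVector seqs, int k, int stride,
                                   int min_shared, int max_bucket) {
  int n = seqs.size();
  std::unordered_map<uint64_t, std::vector<int>> buckets;
  for (int i = 0; i < n; ++i) {
    std::vector<uint64_t> km;
    canonical_kmers(as<std::string>(seqs[i]), k, stride, km);
    std::sort(km.begin(), km.end());
    km.erase(std::unique(km.begin(), km.end()), km.end());
    for (uint64_t key : km) buckets[key].push_back(i);
  }
  std::unordered_map<uint64_t, int> pairs;
  for (auto &kv : buckets) {
    std::vector<int> &v = kv.second;
    if ((int)v.size() < 2 || (int)v.size() > max_bucket) continue;
    for (size_t a = 0; a + 1 < v.size(); ++a)
      for (size_t b = a + 1; b < v.size(); ++b)
        pairs[((uint64_t)v[a] << 32) | (uint64_t)v[b]]++;
  }
  std::vector<std::array<int, 3>> rows;
  for (auto &kv : pairs) {
    if (kv.second >= min_shared)
      rows.push_back({(int)(kv.first >> 32) + 1,
                      (int)(kv.first & 0xffffffffULL) + 1, kv.second});
  }
  std::sort(rows.begin(), rows.end(),
            [](const std::array<int, 3> &x, const std::array<int, 3> &y) {
              if (x[2] != y[2]) return x[2] > y[2];
              if (x[0] != y[0]) return x[0] < y[0];
              return x[1] < y[1];
            });
  IntegerMatrix out((int)rows.size(), 3);
  for (size_t r = 0; r < rows.size(); ++r)
    for (int c = 0; c < 3; ++c) out((int)r, c) = rows[r][c];
  colnames(out) = CharacterVector::create("i", "j", "shared");
  return out;
}

// For each query, the subject indices sharing >= min_shared canonical k-mers.
// [[Rcpp::export]]
List kmer_candidates_cpp(CharacterVector queries, CharacterVector subjects,
                         int k, int min_shared) {
  std::unordered_map<uint64_t, std::vector<int>> buckets;
  int ns = subjects.size();
  for (int i = 0; i < ns; ++i) {
    std::vector<uint64_t> km;
    canonical_kmers(as<std::string>(subjects[i]), k, 1, km);
    std::sort(km.begin(), km.end());
    km.erase(std::unique(km.begin(), km.end()), km.end());
    for (uint64_t key : km) buckets[key].push_back(i);
  }
  int nq = queries.size();
  List out(nq);
  std::vector<int> counts(ns, 0);
  for (int qi = 0; qi < nq; ++qi) {
    std::vector<uint64_t> km;
    canonical_kmers(as<std::string>(queries[qi]), k, 1, km);
    std::sort(km.begin(), km.end());
    km.erase(std::unique(km.begin(), km.end()), km.end());
    std::fill(counts.begin(), counts.end(), 0);
    for (uint64_t key : km) {
      auto it = buckets.find(key);
      if (it == buckets.end()) continue;
      for (int sidx : it->second) counts[sidx]++;
    }
    std::vector<int> hits;
    for (int sidx = 0; sidx < ns; ++sidx)
      if (counts[sidx] >= min_shared) hits.push_back(sidx + 1);
    out[qi] = IntegerVector(hits.begin(), hits.end());
  }
  return out;
}
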