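#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// 2-bit encode; -1 for anything not ACGT (Ns never anchor)
static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

// [[Rcpp::export]]
std::string revcomp_cpp(std::string s) {
  std::string out(s.rbegin(), s.rend());
  for (auto &c : out) c = comp(c);
  return out;
}

// map kmer hash -> position, or -2 when seen more than once
static void kmer_positions(const std::string &s, int k,
                           std::unordered_map<uint64_t, long> &map) {
  long n = (long)s.size();
  if (n < k) return;
  uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;
  for (long i = 0; i < n; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)b) & mask;
    if (++valid >= k) {
      long pos = i - k + 1;
      auto it = map.find(key);
      if (it == map.end()) map.emplace(key, pos);
      else it->second = -2;
    }
  }
}

// Anchors: k-mers unique in BOTH sequences, merged along diagonals into
// maximal runs. Returns 0-based ref_start, qry_start, length.
// [[Rcpp::export]]
DataFrame find_anchors_cpp(std::string ref, std::string qry, int k) {
  if (k < 2 || k > 32) stop("k must be in [2, 32]");
  std::unordered_map<uint64_t, long> rmap, qmap;
  rmap.reserve(ref.size() * 2); qmap.reserve(qry.size() * 2);
  kmer_positions(ref, k, rmap);
  kmer_positions(qry, k, qmap);

  std::vector<std::pair<long, long>> hits; // (rpos, qpos)
  for (auto &kv : qmap) {
    if (kv.second < 0) continue;
    auto it = rmap.find(kv.first);
    if (it != rmap.end() && it->second >= 0)
      hits.emplace_back(it->second, kv.second);
  }
  std::sort(hits.begin(), hits.end());

  std::vector<long> rs, qs, len;
  size_t i = 0;
  while (i < hits.size()) {
    long r0 = hits[i].first, q0 = hits[i].second;
    long run = 1;
    while (i + run < hits.size() &&
           hits[i + run].first == r0 + run &&
           hits[i + run].second == q0 + run)
      ++run;
    rs.push_back(r0); qs.push_back(q0); len.push_back(k + run - 1);
    i += run;
  }
  return DataFrame::create(_["ref_start"] = wrap(rs),
                           _["qry_start"] = wrap(qs),
                           _["length"] = wrap(len));
}

// Weighted longest-increasing-subsequence chaining over anchors sorted by
// ref_start: maximise total anchored length with both coordinates strictly
// increasing. Small overlaps between successive anchors (e.g. one-base
// junction ambiguity at an insertion boundary) are allowed but penalised;
// the caller trims them. Returns 1-based indices of the chosen chain.
// [[Rcpp::export]]
IntegerVector chain_anchors_cpp(IntegerVector ref_start, IntegerVector qry_start,
                                IntegerVector length) {
  int n = ref_start.size();
  if (n == 0) return IntegerVector(0);
  std::vector<double> score(n);
  std::vector<int> back(n, -1);
  double best = -1; int best_i = 0;
  for (int j = 0; j < n; ++j) {
    score[j] = length[j];
    long rj = ref_start[j], qj = qry_start[j];
    for (int i = 0; i < j; ++i) {
      if (ref_start[i] < rj && qry_start[i] < qj) {
        long ov_r = ref_start[i] + length[i] - rj;
        long ov_q = qry_start[i] + length[i] - qj;
        long ov = std::max(std::max(ov_r, ov_q), 0L);
        if (ov >= length[j]) continue; // nothing left after trimming
        double cand = score[i] + length[j] - ov;
        if (cand > score[j]) { score[j] = cand; back[j] = i; }
      }
    }
    if (score[j] > best) { best = score[j]; best_i = j; }
  }
  std::vector<int> idx;
  for (int i = best_i; i >= 0; i = back[i]) idx.push_back(i + 1);
  std::reverse(idx.begin(), idx.end());
  return wrap(idx);
}

// Global affine-gap alignment (Gotoh). Returns aligned strings with '-'.
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match = 1, double mismatch = -2,
                  double gap_open = -5, double gap_ext = -1) {
  int n = a.size(), m = b.size();
  const double NEG = -1e18;
  // three layers: M (match/mismatch), X (gap in b / consumes a), Y (gap in a)
  std::vector<double> M((n + 1) * (m + 1), NEG), X = M, Y = M;
  std::vector<int8_t> tM((n + 1) * (m + 1), 0), tX = tM, tY = tM;
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  M[at(0, 0)] = 0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = gap_open + gap_ext * (i - 1);
    tX[at(i, 0)] = (i == 1) ? 0 : 1; // 0: came from M, 1: from X
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = gap_open + gap_ext * (j - 1);
    tY[at(0, j)] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M layer
      double m0 = M[at(i - 1, j - 1)], m1 = X[at(i - 1, j - 1)], m2 = Y[at(i - 1, j - 1)];
      int8_t tm = 0; double mv = m0;
      if (m1 > mv) { mv = m1; tm = 1; }
      if (m2 > mv) { mv = m2; tm = 2; }
      M[at(i, j)] = mv + s; tM[at(i, j)] = tm;
      // X layer: gap in b, consume a[i-1]
      double x0 = M[at(i - 1, j)] + gap_open, x1 = X[at(i - 1, j)] + gap_ext;
      if (x0 >= x1) { X[at(i, j)] = x0; tX[at(i, j)] = 0; }
      else          { X[at(i, j)] = x1; tX[at(i, j)] = 1; }
      // Y layer: gap in a, consume b[j-1]
      double y0 = M[at(i, j - 1)] + gap_open, y1 = Y[at(i, j - 1)] + gap_ext;
      if (y0 >= y1) { Y[at(i, j)] = y0; tY[at(i, j)] = 0; }
      else          { Y[at(i, j)] = y1; tY[at(i, j)] = 1; }
    }
  }
  // traceback from best layer at (n, m)
  int layer = 0; double bv = M[at(n, m)];
  if (X[at(n, m)] > bv) { bv = X[at(n, m)]; layer = 1; }
  if (Y[at(n, m)] > bv) { bv = Y[at(n, m)]; layer = 2; }
  std::string oa, ob;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (layer == 0) {
      if (i == 0 || j == 0) { layer = (i == 0) ? 2 : 1; continue; }
      int8_t t = tM[at(i, j)];
      oa.push_back(a[i - 1]); ob.push_back(b[j - 1]);
      --i; --j; layer = t;
    } else if (layer == 1) {
      int8_t t = tX[at(i, j)];
      oa.push_back(a[i - 1]); ob.push_back('-');
      --i; layer = (t == 1) ? 1 : 0;
    } else {
      int8_t t = tY[at(i, j)];
      oa.push_back('-'); ob.push_back(b[j - 1]);
      --j; layer = (t == 1) ? 1 : 0;
    }
  }
  std::reverse(oa.begin(), oa.end());
  std::reverse(ob.begin(), ob.end());
  return List::create(_["a"] = oa, _["b"] = ob, _["score"] = bv);
}

// Walk an aligned pair of strings and emit raw SNP / indel events.
// r0, q0 are the 0-based offsets of the first aligned base on ref and qry.
// Indels are anchored on the ref base immediately left of the event
// (anchor position may be r0 - 1 when the gap run starts at column 0).
// [[Rcpp::export]]
List collect_diffs_cpp(std::string ar, std::string aq, long r0, long q0) {
  std::vector<long> spos; std::vector<std::string> sref, salt;
  std::vector<long> ipos; std::vector<std::string> irseq, iqseq;
  long ri = r0, qi = q0;
  size_t L = ar.size(), c = 0;
  while (c < L) {
    char rc = ar[c], qc = aq[c];
    if (rc != '-' && qc != '-') {
      if (rc != qc) {
        spos.push_back(ri);
        sref.push_back(std::string(1, rc));
        salt.push_back(std::string(1, qc));
      }
      ++ri; ++qi; ++c;
    } else {
      // gap run (may mix directions only across separate runs)
      long anchor = ri - 1;
      std::string rg, qg;
      while (c < L && (ar[c] == '-' || aq[c] == '-')) {
        if (ar[c] != '-') { rg.push_back(ar[c]); ++ri; }
        if (aq[c] != '-') { qg.push_back(aq[c]); ++qi; }
        ++c;
      }
      ipos.push_back(anchor);
      irseq.push_back(rg);
      iqseq.push_back(qg);
    }
  }
  return List::create(
    _["snp"] = DataFrame::create(_["pos0"] = wrap(spos), _["ref"] = wrap(sref),
                                 _["alt"] = wrap(salt),
                                 _["stringsAsFactors"] = false),
    _["indel"] = List::create(_["pos0"] = wrap(ipos), _["rseq"] = wrap(irseq),
                              _["qseq"] = wrap(iqseq)));
}
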