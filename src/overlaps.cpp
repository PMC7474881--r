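#include <Rcpp.h>
#include <string>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline char complement_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'T': return 'A';
  case 'C': return 'G';
  case 'G': return 'C';
  default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = complement_base(c);
  return r;
}

// Longest ungapped local alignment between a and b with at most max_mm
// mismatches, scanning every diagonal with a two-pointer window.
// 'N' never matches and hard-breaks a window.
static int scan_pair(const std::string& a, const std::string& b, int max_mm) {
  const int na = (int)a.size(), nb = (int)b.size();
  if (na == 0 || nb == 0) return 0;
  int best = 0;
  std::vector<int> mism; // mismatch offsets within the current diagonal
  for (int d = -(nb - 1); d <= na - 1; ++d) {
    const int i0 = std::max(0, d);
    const int j0 = i0 - d;
    const int len = std::min(na - i0, nb - j0);
    if (len <= best) continue;
    mism.clear();
    int start = 0;       // window start (offset along the diagonal)
    size_t drop = 0;     // index of first mismatch still inside the window
    for (int t = 0; t < len; ++t) {
      const char ca = a[i0 + t], cb = b[j0 + t];
      if (ca == 'N' || cb == 'N') {   // hard break
        start = t + 1;
        drop = mism.size();
        continue;
      }
      if (ca != cb) {
        mism.push_back(t);
        if ((int)(mism.size() - drop) > max_mm) {
          start = mism[drop] + 1;
          ++drop;
        }
      }
      if (t - start + 1 > best) best = t - start + 1;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".overlap_scan_cpp")]]
int overlap_scan_cpp(std::string a, std::string b, int max_mm) {
  return scan_pair(a, b, max_mm);
}

// Classic longest-common-substring dynamic programme (rolling row).
// Independent of the diagonal scan above; used by the brute-force detector.
// 'N' never matches.
// [[Rcpp::export(name = ".lcs_dp_cpp")]]
int lcs_dp_cpp(std::string a, std::string b) {
  const int na = (int)a.size(), nb = (int)b.size();
  if (na == 0 || nb == 0) return 0;
  std::vector<int> prev(nb + 1, 0), cur(nb + 1, 0);
  int best = 0;
  for (int i = 1; i <= na; ++i) {
    const char ca = a[i - 1];
    for (int j = 1; j <= nb; ++j) {
      const char cb = b[j - 1];
      if (ca == cb && ca != 'N') {
        cur[j] = prev[j - 1] + 1;
        if (cur[j] > best) best = cur[j];
      } else {
        cur[j] = 0;
      }
    }
    std::swap(prev, cur);
  }
  return best;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  const int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = revcomp_str(std::string(x[i]));
  }
  return out;
}

// Best ungapped window on one diagonal of (a, b): positions a[i0+t] vs
// b[j0+t] with diagonal d = i - j. Same two-pointer rule as scan_pair.
static int scan_diag(const std::string& a, const std::string& b, int d,
                     int max_mm) {
  const int na = (int)a.size(), nb = (int)b.size();
  const int i0 = std::max(0, d);
  const int j0 = i0 - d;
  if (i0 >= na || j0 >= nb) return 0;
  const int len = std::min(na - i0, nb - j0);
  int best = 0, start = 0;
  std::vector<int> mism;
  size_t drop = 0;
  for (int t = 0; t < len; ++t) {
    const char ca = a[i0 + t], cb = b[j0 + t];
    if (ca == 'N' || cb == 'N') {
      start = t + 1;
      drop = mism.size();
      continue;
    }
    if (ca != cb) {
      mism.push_back(t);
      if ((int)(mism.size() - drop) > max_mm) {
        start = mism[drop] + 1;
        ++drop;
      }
    }
    if (t - start + 1 > best) best = t - start + 1;
  }
  return best;
}

struct SeedHit {
  int read;
  int pos;    // kmer start in the read's forward sequence (0-based)
  int orient; // 1 when the forward kmer equals the canonical kmer
};

// All-vs-all overlap detection via a canonical seed-kmer index followed by
// verification restricted to seeded diagonals. For max_mm = 0 the seed
// length equals b, so a shared substring of length >= b implies a shared
// seed on the alignment's own diagonal and the search is complete; for
// max_mm > 0 seeds of length floor((b - mm)/(mm + 1)) keep the guarantee
// by pigeonhole. Returns one row per unordered read pair (0-based indices
// i < j) whose best alignment on either strand reaches b, with the maximal
// length and its strand.
// [[Rcpp::export(name = ".find_overlaps_indexed_cpp")]]
DataFrame find_overlaps_indexed_cpp(CharacterVector seqs, int b, int max_mm) {
  const int n = seqs.size();
  std::vector<std::string> fwd(n), rev(n);
  size_t max_len = 0;
  for (int i = 0; i < n; ++i) {
    fwd[i] = std::string(seqs[i]);
    rev[i] = revcomp_str(fwd[i]);
    max_len = std::max(max_len, fwd[i].size());
  }
  int seed_len = (max_mm == 0) ? b : (b - max_mm) / (max_mm + 1);
  if (seed_len < 1) seed_len = 1;

  std::unordered_map<std::string, std::vector<SeedHit>> index;
  index.reserve((size_t)n * 8);
  std::string rc;
  for (int i = 0; i < n; ++i) {
    const std::string& s = fwd[i];
    const int L = (int)s.size();
    for (int p = 0; p + seed_len <= L; ++p) {
      std::string k = s.substr(p, seed_len);
      if (k.find('N') != std::string::npos) continue;
      rc = revcomp_str(k);
      const bool plus = !(rc < k);
      index[plus ? k : rc].push_back(SeedHit{i, p, plus ? 1 : 0});
    }
  }

  // (pair, strand, diagonal) -> scanned once; per-pair best by strand
  const uint64_t doff = (uint64_t)max_len + 1;
  std::unordered_set<uint64_t> seen_diag;
  std::unordered_map<uint64_t, std::pair<int, int>> best; // idx -> (same, opp)
  for (auto& kv : index) {
    const std::vector<SeedHit>& v = kv.second;
    const size_t m = v.size();
    if (m < 2) continue;
    for (size_t x = 0; x + 1 < m; ++x) {
      for (size_t y = x + 1; y < m; ++y) {
        const SeedHit& hx = v[x];
        const SeedHit& hy = v[y];
        if (hx.read == hy.read) continue;
        const SeedHit& hi = (hx.read < hy.read) ? hx : hy;
        const SeedHit& hj = (hx.read < hy.read) ? hy : hx;
        const int i = hi.read, j = hj.read;
        const bool same = (hi.orient == hj.orient);
        // diagonal of the implied alignment:
        //   same strand:  fwd_i vs fwd_j at d = pi - pj
        //   opposite:     fwd_i vs rev_j, kmer sits in rev_j at
        //                 len_j - seed_len - pj
        const int d = same
          ? hi.pos - hj.pos
          : hi.pos - ((int)fwd[j].size() - seed_len - hj.pos);
        const uint64_t idx_pair = (uint64_t)i * (uint64_t)n + (uint64_t)j;
        const uint64_t key =
          (((idx_pair << 1) | (same ? 1u : 0u)) * (2 * doff + 1)) +
          (uint64_t)(d + (int64_t)doff);
        if (!seen_diag.insert(key).second) continue;
        const int L = same ? scan_diag(fwd[i], fwd[j], d, max_mm)
                           : scan_diag(fwd[i], rev[j], d, max_mm);
        if (L >= b) {
          auto& e = best[idx_pair];
          if (same) e.first = std::max(e.first, L);
          else e.second = std::max(e.second, L);
        }
      }
    }
  }

  std::vector<int> ia, ja, len, same_out;
  ia.reserve(best.size());
  for (auto& kv : best) {
    const int i = (int)(kv.first / (uint64_t)n);
    const int j = (int)(kv.first % (uint64_t)n);
    const int ls = kv.second.first, lo = kv.second.second;
    ia.push_back(i);
    ja.push_back(j);
    len.push_back(std::max(ls, lo));
    same_out.push_back(ls >= lo ? 1 : 0);
  }
  return DataFrame::create(_["i"] = ia, _["j"] = ja,
                           _["length"] = len, _["same_strand"] = same_out);
}
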