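#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// IUPAC nucleotide codes as bitmasks over {A=1, C=2, G=4, T=8}.
// Subject N carries mask 0 so it matches nothing (counts as mismatch).
static inline int iupac_mask(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': case 'U': case 'u': return 8;
    case 'R': case 'r': return 1 | 4;
    case 'Y': case 'y': return 2 | 8;
    case 'S': case 's': return 2 | 4;
    case 'W': case 'w': return 1 | 8;
    case 'K': case 'k': return 4 | 8;
    case 'M': case 'm': return 1 | 2;
    case 'B': case 'b': return 2 | 4 | 8;
    case 'D': case 'd': return 1 | 4 | 8;
    case 'H': case 'h': return 1 | 2 | 8;
    case 'V': case 'v': return 1 | 2 | 4;
    case 'N': case 'n': return 1 | 2 | 4 | 8;
    default: return -1;
  }
}

// mask of a concrete subject base; N (and anything ambiguous) -> 0
static inline int subject_mask(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': return 8;
    default: return 0;
  }
}

// [[Rcpp::export]]
bool cpp_iupac_match(std::string pattern_base, std::string base) {
  if (pattern_base.size() != 1 || base.size() != 1)
    stop("pattern_base and base must be single characters");
  int pm = iupac_mask(pattern_base[0]);
  if (pm < 0) stop("invalid IUPAC symbol: %s", pattern_base.c_str());
  char b = base[0];
  if (subject_mask(b) == 0 && b != 'N' && b != 'n')
    stop("invalid subject base: %s", base.c_str());
  return (pm & subject_mask(b)) != 0;
}

// All windows of `sequence` whose IUPAC-aware Hamming distance to `primer`
// is <= max_mismatches. Positions are 0-based. No indels.
// [[Rcpp::export]]
DataFrame cpp_find_primer_sites(std::string sequence, std::string primer,
                                int max_mismatches) {
  int n = sequence.size(), k = primer.size();
  if (k == 0) stop("primer must be non-empty");
  std::vector<int> pmask(k);
  for (int i = 0; i < k; ++i) {
    pmask[i] = iupac_mask(primer[i]);
    if (pmask[i] < 0) stop("invalid IUPAC symbol in primer");
  }
  std::vector<int> smask(n);
  for (int i = 0; i < n; ++i) smask[i] = subject_mask(sequence[i]);
  std::vector<int> pos, mm;
  for (int s = 0; s + k <= n; ++s) {
    int d = 0;
    for (int i = 0; i < k; ++i) {
      if ((pmask[i] & smask[s + i]) == 0 && ++d > max_mismatches) break;
    }
    if (d <= max_mismatches) { pos.push_back(s); mm.push_back(d); }
  }
  return DataFrame::create(_["position"] = pos, _["mismatches"] = mm);
}

// Semi-global (glocal) alignment: the full query is aligned within the
// target; leading and trailing target gaps are free. Linear gap penalty.
// The band restricts computation to the corridor
//   i - band <= j <= i + (n - m) + band
// which contains the optimal path whenever the path's indel count <= band.
// band < 0 disables banding. Returns band_ok = FALSE when the corridor
// cannot connect row 0 to row m (caller should widen the band).
// [[Rcpp::export]]
List cpp_align_semiglobal(std::string query, std::string target, int band,
                          int match = 1, int mismatch = -1, int gap = -2) {
  int m = query.size(), n = target.size();
  if (m == 0 || n == 0) stop("query and target must be non-empty");
  const int NEG = INT_MIN / 4;
  int shift = n - m;
  if (band >= 0 && shift + 2 * band < 0) {
    return List::create(_["band_ok"] = false);
  }
  std::vector<int> qcode(m), tcode(n);
  for (int i = 0; i < m; ++i) qcode[i] = subject_mask(query[i]);
  for (int j = 0; j < n; ++j) tcode[j] = subject_mask(target[j]);
  std::vector<int> H((size_t)(m + 1) * (n + 1), NEG);
  const size_t W = n + 1;
  auto at = [&](int i, int j) -> int& { return H[(size_t)i * W + j]; };
  auto lo = [&](int i) { return band < 0 ? 0 : std::max(0, i - band); };
  auto hi = [&](int i) { return band < 0 ? n : std::min(n, i + shift + band); };

  for (int j = lo(0); j <= hi(0); ++j) at(0, j) = 0;  // free leading target gap
  for (int i = 1; i <= m; ++i) {
    int jl = lo(i), jh = hi(i);
    int *row = &H[(size_t)i * W];
    const int *prev = &H[(size_t)(i - 1) * W];
    const int qc = qcode[i - 1];
    for (int j = jl; j <= jh; ++j) {
      int best = NEG;
      if (j > 0 && prev[j - 1] > NEG) {
        best = prev[j - 1] + ((qc != 0 && qc == tcode[j - 1]) ? match : mismatch);
      }
      if (prev[j] > NEG && prev[j] + gap > best) best = prev[j] + gap;
      if (j > 0 && row[j - 1] > NEG && row[j - 1] + gap > best)
        best = row[j - 1] + gap;
      row[j] = best;
    }
  }
  // best end: max over last row, smallest j on ties (deterministic)
  int best_score = NEG, jend = -1;
  for (int j = lo(m); j <= hi(m); ++j) {
    if (at(m, j) > best_score) { best_score = at(m, j); jend = j; }
  }
  if (jend < 0 || best_score <= NEG) {
    return List::create(_["band_ok"] = false);
  }
  // traceback, preference: diagonal, then up (gap in target), then left
  std::string qaln, taln;
  int i = m, j = jend;
  int nmatch = 0, ndiag = 0, ncols = 0;
  while (i > 0) {
    bool moved = false;
    if (j > 0 && at(i - 1, j - 1) > NEG) {
      int s = (subject_mask(query[i - 1]) != 0 &&
               subject_mask(query[i - 1]) == subject_mask(target[j - 1]))
                  ? match : mismatch;
      if (at(i, j) == at(i - 1, j - 1) + s) {
        qaln.push_back(query[i - 1]); taln.push_back(target[j - 1]);
        if (s == match) ++nmatch;
        ++ndiag; ++ncols; --i; --j; moved = true;
      }
    }
    if (!moved && at(i - 1, j) > NEG && at(i, j) == at(i - 1, j) + gap) {
      qaln.push_back(query[i - 1]); taln.push_back('-');
      ++ncols; --i; moved = true;
    }
    if (!moved && j > 0 && at(i, j - 1) > NEG && at(i, j) == at(i, j - 1) + gap) {
      qaln.push_back('-'); taln.push_back(target[j - 1]);
      ++ncols; --j; moved = true;
    }
    if (!moved) stop("internal error: traceback stuck");
  }
  int tstart = j;
  std::reverse(qaln.begin(), qaln.end());
  std::reverse(taln.begin(), taln.end());
  return List::create(
      _["band_ok"] = true, _["score"] = best_score,
      _["identity"] = ncols > 0 ? (double)nmatch / ncols : 0.0,
      _["coverage"] = (double)ndiag / m, _["nmatch"] = nmatch,
      _["ncols"] = ncols, _["qaln"] = qaln, _["taln"] = taln,
      _["tstart"] = tstart, _["tend"] = jend);
}
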