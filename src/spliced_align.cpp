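#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Spliced alignment of a reference transcript (CDS nucleotides or protein)
// against a gene haplotype, est2genome style: exon match/mismatch with
// affine gaps, plus an intron state that consumes genome only at a flat
// entry penalty and a minimum intron length.  The maximum intron bound is
// vacuous for the gene-plus-flank extracts this package aligns (always
// shorter than the bound); callers verify it on the traceback otherwise.
//
// Column-major DP (query outer, genome inner), rolling score columns, and
// a packed one-byte traceback per cell:
//   bits 0-1: source of M at the diagonal predecessor (0=M, 1=X, 2=Y, 3=J)
//   bit 2:    X extended (else opened from M)
//   bit 3:    Y extended (else opened from M)
//   bit 4:    J extended (else opened from M at lag min_intron)
// States: M aligned unit (1 base or 1 codon), X query-only gap,
//         Y genome-only gap, J intron (genome-only, flat penalty).

static const int NEG = INT32_MIN / 4;

static inline int nscore(char x, char y, int match, int mismatch) {
  if (x == 'N' || y == 'N') return mismatch;
  return (x == y) ? match : mismatch;
}

static char translate_codon(const char *g) {
  auto idx = [](char c) -> int {
    switch (c) { case 'T': return 0; case 'C': return 1;
                 case 'A': return 2; case 'G': return 3; default: return -1; }
  };
  static const char aa[] =
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG";
  int i0 = idx(g[0]), i1 = idx(g[1]), i2 = idx(g[2]);
  if (i0 < 0 || i1 < 0 || i2 < 0) return 'X';
  return aa[i0 * 16 + i1 * 4 + i2];
}

static List run_spliced(const std::string &genome, const std::string &query,
                        bool protein, int match, int mismatch, int stop_pen,
                        int gap_open, int gap_ext, int intron_penalty,
                        int min_intron, int motif_bonus) {
  const int G = genome.size(), Q = query.size();
  const int step = protein ? 3 : 1;
  if (G < step || Q < 1) stop("sequence too short for spliced alignment");
  if ((double)(G + 1) * (Q + 1) > 3e8) stop("sequences too long for spliced DP");
  const char *g = genome.c_str(), *q = query.c_str();
  const long long GW = (long long)G + 1;

  std::vector<int> Mp(G + 1), Xp(G + 1), Yp(G + 1), Jp(G + 1);
  std::vector<int> Mc(G + 1), Xc(G + 1), Yc(G + 1), Jc(G + 1);
  std::vector<uint8_t> tb((size_t)(Q + 1) * GW, 0);

  // column 0: free genome prefix (any start position/frame), no gaps open
  for (int i = 0; i <= G; ++i) { Mp[i] = 0; Xp[i] = NEG; Yp[i] = NEG; Jp[i] = NEG; }

  for (int j = 1; j <= Q; ++j) {
    size_t cb = (size_t)j * GW;
    for (int i = 0; i <= G; ++i) {
      uint8_t t = 0;
      // X: query-only gap, predecessor (i, j-1)
      {
        int fromM = (Mp[i] > NEG) ? Mp[i] - gap_open - gap_ext : NEG;
        int fromX = (Xp[i] > NEG) ? Xp[i] - gap_ext : NEG;
        if (fromX > fromM) { Xc[i] = fromX; t |= 0x04; } else Xc[i] = fromM;
      }
      // M: aligned unit ending at genome i, predecessor (i-step, j-1)
      if (i >= step) {
        int ip = i - step;
        int best = Mp[ip], src = 0;
        if (Xp[ip] > best) { best = Xp[ip]; src = 1; }
        if (Yp[ip] > best) { best = Yp[ip]; src = 2; }
        // exiting an intron whose last two bases are AG earns the
        // acceptor bonus (canonical splice preference, est2genome style)
        int jopt = Jp[ip];
        if (jopt > NEG && ip >= 2 && g[ip - 2] == 'A' && g[ip - 1] == 'G')
          jopt += motif_bonus;
        if (jopt > best) { best = jopt; src = 3; }
        if (best > NEG) {
          int s;
          if (protein) {
            char aa = translate_codon(g + i - 3);
            s = (aa == '*') ? stop_pen
                            : ((aa == q[j - 1] && aa != 'X') ? match : mismatch);
          } else s = nscore(g[i - 1], q[j - 1], match, mismatch);
          Mc[i] = best + s;
          t |= (uint8_t)src;
        } else Mc[i] = NEG;
      } else Mc[i] = NEG;
      // Y: genome-only gap, predecessor (i-step, j), same column
      if (i >= step) {
        int ip = i - step;
        int fromM = (Mc[ip] > NEG) ? Mc[ip] - gap_open - gap_ext : NEG;
        int fromY = (Yc[ip] > NEG) ? Yc[ip] - gap_ext : NEG;
        if (fromY > fromM) { Yc[i] = fromY; t |= 0x08; } else Yc[i] = fromM;
      } else Yc[i] = NEG;
      // J: intron, same column; open from M at lag min_intron or extend;
      // a GT donor at the intron start earns the motif bonus
      if (i >= 1) {
        int ext = Jc[i - 1];
        int opn = (i >= min_intron && Mc[i - min_intron] > NEG)
                    ? Mc[i - min_intron] - intron_penalty : NEG;
        if (opn > NEG && i - min_intron + 1 < G &&
            g[i - min_intron] == 'G' && g[i - min_intron + 1] == 'T')
          opn += motif_bonus;
        if (ext >= opn) { Jc[i] = ext; if (ext > NEG) t |= 0x10; }
        else Jc[i] = opn;
      } else Jc[i] = NEG;
      tb[cb + i] = t;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc); std::swap(Jp, Jc);
  }

  // best end: query fully consumed (aligned or trailing query gap)
  int best = NEG, best_i = 0, best_state = 0;
  for (int i = 0; i <= G; ++i) {
    if (Mp[i] > best) { best = Mp[i]; best_i = i; best_state = 0; }
    if (Xp[i] > best) { best = Xp[i]; best_i = i; best_state = 1; }
  }
  if (best <= NEG) stop("spliced alignment found no path");

  // traceback
  std::vector<int> exon_start, exon_end, intron_start, intron_end;
  int i = best_i, j = Q, state = best_state;
  int cur_end = -1;
  int qlo = Q + 1, qhi = 0, nmatch = 0, naligned = 0;
  while (j > 0 || state == 3 || state == 2) {
    uint8_t t = tb[(size_t)j * GW + i];
    if (state == 0) {
      if (cur_end < 0) cur_end = i;
      if (j < qlo) qlo = j;
      if (j > qhi) qhi = j;
      ++naligned;
      if (protein) { if (translate_codon(g + i - 3) == q[j - 1]) ++nmatch; }
      else if (g[i - 1] == q[j - 1] && g[i - 1] != 'N') ++nmatch;
      int src = t & 0x03;
      i -= step; j -= 1;
      if (src == 3) {
        exon_start.push_back(i); exon_end.push_back(cur_end);
        intron_end.push_back(i);
        cur_end = -1;
        state = 3;
      } else state = src;
      if (j == 0 && state != 3 && state != 2) break;
    } else if (state == 1) {
      state = (t & 0x04) ? 1 : 0;
      j -= 1;
    } else if (state == 2) {
      if (cur_end < 0) cur_end = i;
      state = (t & 0x08) ? 2 : 0;
      i -= step;
      if (j == 0 && state == 0) break;
    } else {  // intron
      if (t & 0x10) { i -= 1; }
      else { intron_start.push_back(i - min_intron); i -= min_intron; state = 0; }
    }
    if (i <= 0 && j <= 0) break;
  }
  if (cur_end >= 0) { exon_start.push_back(i), exon_end.push_back(cur_end); }
  std::reverse(exon_start.begin(), exon_start.end());
  std::reverse(exon_end.begin(), exon_end.end());
  std::reverse(intron_start.begin(), intron_start.end());
  std::reverse(intron_end.begin(), intron_end.end());
  int ne = exon_start.size(), ni = intron_start.size();
  IntegerMatrix ex(ne, 2), in(ni, 2);
  for (int k = 0; k < ne; ++k) { ex(k, 0) = exon_start[k]; ex(k, 1) = exon_end[k]; }
  for (int k = 0; k < ni; ++k) { in(k, 0) = intron_start[k]; in(k, 1) = intron_end[k]; }
  return List::create(_["score"] = best, _["exons"] = ex, _["introns"] = in,
                      _["q_first"] = (qlo <= qhi ? qlo : NA_INTEGER),
                      _["q_last"] = (qlo <= qhi ? qhi : NA_INTEGER),
                      _["n_aligned"] = naligned, _["n_match"] = nmatch);
}

// [[Rcpp::export]]
List cpp_spliced_align_nt(std::string genome, std::string query,
                          int match = 5, int mismatch = -4,
                          int gap_open = 10, int gap_ext = 2,
                          int intron_penalty = 10, int min_intron = 10,
                          int motif_bonus = 4) {
  return run_spliced(genome, query, false, match, mismatch, 0,
                     gap_open, gap_ext, intron_penalty, min_intron,
                     motif_bonus);
}

// [[Rcpp::export]]
List cpp_spliced_align_aa(std::string genome, std::string protein,
                          int match = 12, int mismatch = -6,
                          int stop_penalty = -20,
                          int gap_open = 20, int gap_ext = 6,
                          int intron_penalty = 10, int min_intron = 10,
                          int motif_bonus = 4) {
  return run_spliced(genome, protein, true, match, mismatch, stop_penalty,
                     gap_open, gap_ext, intron_penalty, min_intron,
                     motif_bonus);
}

// [[Rcpp::export]]
std::string cpp_translate(std::string dna) {
  int n = dna.size() / 3;
  std::string out(n, 'X');
  for (int k = 0; k < n; ++k) out[k] = translate_codon(dna.c_str() + 3 * k);
  return out;
}
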