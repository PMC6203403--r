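#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Banded global pairwise alignment with affine gaps, used by the builtin
// window-alignment engine.  Haplotypes of inbred lines are near-identical to
// the reference, so a band around the main diagonal (widened by the length
// difference) contains the optimal path for the variant densities this
// package targets.  'N' never matches anything, itself included.
//
// Conventions: a = reference slice, b = sample haplotype slice.  Returned
// aligned strings have equal length with '-' for gaps.  Tie-breaking is
// fixed (diagonal, then gap-in-haplotype, then gap-in-reference) so that
// identical inputs always yield identical alignments.

static const int NEG = INT32_MIN / 4;

static inline int base_score(char x, char y, int match, int mismatch) {
  if (x == 'N' || y == 'N') return mismatch;
  return (x == y) ? match : mismatch;
}

struct BandDP {
  int n, m, hw, W;
  std::vector<int> M, X, Y;       // two rolling rows handled by caller
  std::vector<uint8_t> tb;        // full traceback, 1 byte per band cell
};

// traceback byte layout: bits 0-1 source of M (0=M,1=X,2=Y), bit 2 source of
// X (0=open from M, 1=extend), bit 3 source of Y, bits 4-5 best state at cell
// (unused except final), bit 6 M-cell valid.

// [[Rcpp::export]]
List cpp_banded_align(std::string a, std::string b,
                      int match = 5, int mismatch = -4,
                      int gap_open = 10, int gap_ext = 1,
                      int band_extra = 100) {
  // trim common prefix/suffix, backed off by a margin so repeat tracts at
  // the trim edges stay inside the DP core (keeps gap placement a function
  // of local context only, independent of where the first difference sits)
  const int backoff = 64;
  int n0 = a.size(), m0 = b.size();
  int p = 0;
  while (p < n0 && p < m0 && a[p] == b[p]) ++p;
  p = std::max(0, p - backoff);
  int s = 0;
  while (s < n0 - p && s < m0 - p && a[n0 - 1 - s] == b[m0 - 1 - s]) ++s;
  s = std::max(0, s - backoff);
  int n = n0 - p - s, m = m0 - p - s;  // core lengths

  std::string ra, rb;               // aligned core
  if (n == 0 && m == 0) {
    // identical after trimming
  } else if (n == 0) {
    ra.assign(m, '-'); rb = b.substr(p, m);
  } else if (m == 0) {
    ra = a.substr(p, n); rb.assign(n, '-');
  } else {
    const char *ca = a.c_str() + p, *cb = b.c_str() + p;
    int hw = std::abs(n - m) + std::max(8, band_extra);
    long long Wl = 2LL * hw + 1;
    if (Wl > m + 1) { hw = m; Wl = 2LL * hw + 1; }
    int W = (int)Wl;
    // band center for row i: ci = round(i*m/n)
    std::vector<int> Mprev(W, NEG), Xprev(W, NEG), Yprev(W, NEG);
    std::vector<int> Mcur(W, NEG), Xcur(W, NEG), Ycur(W, NEG);
    std::vector<uint8_t> tb((size_t)(n + 1) * W, 0);
    std::vector<int> off(n + 1);
    for (int i = 0; i <= n; ++i) {
      long long ci = (long long)i * m / n;
      off[i] = (int)ci - hw;
    }
    // row 0
    for (int jb = 0; jb < W; ++jb) {
      int j = off[0] + jb;
      if (j < 0 || j > m) continue;
      if (j == 0) { Mprev[jb] = 0; }
      else {
        Xprev[jb] = -(gap_open + j * gap_ext);
        tb[jb] = (uint8_t)((j > 1) ? 0x04 : 0x00);
      }
    }
    for (int i = 1; i <= n; ++i) {
      int oc = off[i], op = off[i - 1];
      std::fill(Mcur.begin(), Mcur.end(), NEG);
      std::fill(Xcur.begin(), Xcur.end(), NEG);
      std::fill(Ycur.begin(), Ycur.end(), NEG);
      size_t rowbase = (size_t)i * W;
      for (int jb = 0; jb < W; ++jb) {
        int j = oc + jb;
        if (j < 0 || j > m) continue;
        uint8_t t = 0;
        // Y: gap in b (deletion), consume a only; sources at (i-1, j)
        int jpb = j - op;  // index of column j in previous row's band
        if (jpb >= 0 && jpb < W) {
          int fromM = (Mprev[jpb] > NEG) ? Mprev[jpb] - gap_open - gap_ext : NEG;
          int fromY = (Yprev[jpb] > NEG) ? Yprev[jpb] - gap_ext : NEG;
          if (fromY > fromM) { Ycur[jb] = fromY; t |= 0x08; }
          else if (fromM > NEG) { Ycur[jb] = fromM; }
        }
        // X: gap in a (insertion), consume b only; sources at (i, j-1)
        if (jb - 1 >= 0 && j - 1 >= 0) {
          int fromM = (Mcur[jb - 1] > NEG) ? Mcur[jb - 1] - gap_open - gap_ext : NEG;
          int fromX = (Xcur[jb - 1] > NEG) ? Xcur[jb - 1] - gap_ext : NEG;
          if (fromX > fromM) { Xcur[jb] = fromX; t |= 0x04; }
          else if (fromM > NEG) { Xcur[jb] = fromM; }
        }
        // M: diagonal; sources at (i-1, j-1)
        if (j - 1 >= 0) {
          int jpd = j - 1 - op;
          if (jpd >= 0 && jpd < W) {
            int best = Mprev[jpd]; int src = 0;
            if (Xprev[jpd] > best) { best = Xprev[jpd]; src = 1; }
            if (Yprev[jpd] > best) { best = Yprev[jpd]; src = 2; }
            if (best > NEG) {
              Mcur[jb] = best + base_score(ca[i - 1], cb[j - 1], match, mismatch);
              t |= (uint8_t)src;
              t |= 0x40;
            }
          }
        }
        tb[rowbase + jb] = t;
      }
      std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
    }
    // end cell (n, m)
    int jb_end = m - off[n];
    if (jb_end < 0 || jb_end >= W)
      stop("alignment band does not contain the end cell; increase band_extra");
    int state;  // 0=M 1=X 2=Y
    int bm = Mprev[jb_end], bx = Xprev[jb_end], by = Yprev[jb_end];
    if (bm >= bx && bm >= by) state = 0;
    else if (by >= bx) state = 2;
    else state = 1;
    if ((state == 0 ? bm : (state == 1 ? bx : by)) <= NEG)
      stop("banded alignment failed: no path inside band; increase band_extra");
    // traceback
    int i = n, j = m;
    std::string ta, tbs;
    while (i > 0 || j > 0) {
      int jb = j - off[i];
      uint8_t t = tb[(size_t)i * W + jb];
      if (state == 0) {
        if (i == 0 || j == 0) break;
        ta.push_back(ca[i - 1]); tbs.push_back(cb[j - 1]);
        state = t & 0x03; --i; --j;
      } else if (state == 1) {      // gap in a, consume b
        ta.push_back('-'); tbs.push_back(cb[j - 1]);
        state = (t & 0x04) ? 1 : 0; --j;
      } else {                      // gap in b, consume a
        ta.push_back(ca[i - 1]); tbs.push_back('-');
        state = (t & 0x08) ? 2 : 0; --i;
      }
    }
    ra.assign(ta.rbegin(), ta.rend());
    rb.assign(tbs.rbegin(), tbs.rend());
  }
  std::string outa = a.substr(0, p) + ra + a.substr(n0 - s);
  std::string outb = b.substr(0, p) + rb + b.substr(m0 - s);
  return List::create(_["ref"] = outa, _["hap"] = outb);
}
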