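#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
#include <functional>

using namespace Rcpp;

static const double NEG_INF = -1e30;

// Substitution score: literal letter identity only; N never matches and is
// scored as a mismatch, so identity means identity of unambiguous letters.
static inline double subst(char x, char y, double match, double mismatch) {
  if (x == y && x != 'N') return match;
  return mismatch;
}

static inline double gapcost(long g, double open, double ext) {
  return g > 0 ? open + (double)(g - 1) * ext : 0.0;
}

// Traceback byte layout (2 bits per state):
//   bits 0-1: predecessor of M  (0=M, 1=Ib, 2=Ia, 3=local fresh start)
//   bits 2-3: predecessor of Ia (0=M, 1=Ib, 2=Ia)
//   bits 4-5: predecessor of Ib (0=M, 1=Ib, 2=Ia)
// States: M = a[i] against b[j]; Ia = a[i] against '-' (gap in b row);
//         Ib = '-' against b[j] (gap in a row).
// Tie-break preference everywhere: M (diagonal) > Ib (gap in a) > Ia (gap in b).

// pick the preferred predecessor among (vm, vib, via); returns code 0(M)/1(Ib)/2(Ia)
static inline int pick3(double vm, double vib, double via, double &best) {
  best = vm; int code = 0;
  if (vib > best) { best = vib; code = 1; }
  if (via > best) { best = via; code = 2; }
  return code;
}

static inline int code2state(int code) {
  // predecessor code 0=M,1=Ib,2=Ia -> internal state ids M=0, Ia=1, Ib=2
  return code == 0 ? 0 : (code == 1 ? 2 : 1);
}

// Banded affine-gap pairwise alignment (Gotoh three-state DP).
// a has length n (rows), b has length m (cols); a cell (i,j) is inside the
// band iff band_lo <= j - i <= band_hi.  mode: 0 = global, 1 = local.
// end_free: global mode only; leading/trailing gaps cost nothing but are
// still emitted as alignment columns.
// [[Rcpp::export]]
List cpp_pair_align(std::string a, std::string b,
                    double match, double mismatch,
                    double gap_open, double gap_ext,
                    bool end_free, int mode,
                    long band_lo, long band_hi) {
  const long n = (long)a.size(), m = (long)b.size();
  if (n < 1 || m < 1) stop("empty sequence");
  band_lo = std::max(band_lo, -n);
  band_hi = std::min(band_hi, m);
  if (mode == 0) { // global band must admit a corner-to-corner path
    band_lo = std::min(band_lo, std::min((long)0, m - n));
    band_hi = std::max(band_hi, std::max((long)0, m - n));
  }
  const long W = band_hi - band_lo + 1;
  if (W < 1) stop("empty band");
  std::vector<uint8_t> tb((size_t)(n + 1) * (size_t)W, 0u);

  std::vector<double> Mprev(W, NEG_INF), Iaprev(W, NEG_INF), Ibprev(W, NEG_INF);
  std::vector<double> Mcur(W, NEG_INF), Iacur(W, NEG_INF), Ibcur(W, NEG_INF);

  const bool local = (mode == 1);

  // last-column (j == m) state values per row, for free-end-gap termination
  std::vector<double> colM(n + 1, NEG_INF), colIa(n + 1, NEG_INF),
                      colIb(n + 1, NEG_INF);

  double best_local = 0.0; long best_i = 0, best_j = 0; bool any_local = false;

  // row 0 (empty prefix of a)
  for (long j = std::max((long)0, band_lo); j <= std::min(m, band_hi); ++j) {
    long w = j - band_lo;
    if (j == 0) { Mprev[w] = 0.0; continue; }
    if (local) continue; // local alignments start fresh via the M floor
    Ibprev[w] = end_free ? 0.0 : -gapcost(j, gap_open, gap_ext);
    tb[w] |= (uint8_t)(1u << 4); // Ib from Ib
  }
  if (m - 0 >= band_lo && m <= band_hi) {
    long w = m - band_lo;
    colM[0] = Mprev[w]; colIa[0] = Iaprev[w]; colIb[0] = Ibprev[w];
  }

  for (long i = 1; i <= n; ++i) {
    std::fill(Mcur.begin(), Mcur.end(), NEG_INF);
    std::fill(Iacur.begin(), Iacur.end(), NEG_INF);
    std::fill(Ibcur.begin(), Ibcur.end(), NEG_INF);
    const long jlo = std::max((long)0, i + band_lo);
    const long jhi = std::min(m, i + band_hi);
    const char ca = a[i - 1];
    for (long j = jlo; j <= jhi; ++j) {
      const long w = j - i - band_lo;
      uint8_t cell = 0;
      if (j == 0) {
        if (!local) {
          Iacur[w] = end_free ? 0.0 : -gapcost(i, gap_open, gap_ext);
          cell |= (uint8_t)(2u << 2); // Ia from Ia
        }
        tb[(size_t)i * W + w] = cell;
        continue;
      }
      // M from (i-1, j-1): same w, previous row
      {
        double bestp; int code = pick3(Mprev[w], Ibprev[w], Iaprev[w], bestp);
        double sc = subst(ca, b[j - 1], match, mismatch);
        double v = (bestp <= NEG_INF / 2) ? NEG_INF : bestp + sc;
        if (local) {
          if (v < sc) { v = sc; code = 3; } // fresh start at this column
          if (v < 0) v = NEG_INF;           // negative local M never survives
        }
        if (v > NEG_INF / 2) { Mcur[w] = v; cell |= (uint8_t)code; }
      }
      // Ia from (i-1, j): band index w+1, previous row (a[i] against '-')
      if (w + 1 < W) {
        double vm  = Mprev[w + 1]  > NEG_INF / 2 ? Mprev[w + 1]  - gap_open : NEG_INF;
        double vib = Ibprev[w + 1] > NEG_INF / 2 ? Ibprev[w + 1] - gap_open : NEG_INF;
        double via = Iaprev[w + 1] > NEG_INF / 2 ? Iaprev[w + 1] - gap_ext  : NEG_INF;
        double bestp; int code = pick3(vm, vib, via, bestp);
        if (bestp > NEG_INF / 2) { Iacur[w] = bestp; cell |= (uint8_t)(code << 2); }
      }
      // Ib from (i, j-1): band index w-1, same row ('-' against b[j])
      if (w - 1 >= 0) {
        double vm  = Mcur[w - 1]  > NEG_INF / 2 ? Mcur[w - 1]  - gap_open : NEG_INF;
        double vib = Ibcur[w - 1] > NEG_INF / 2 ? Ibcur[w - 1] - gap_ext  : NEG_INF;
        double via = Iacur[w - 1] > NEG_INF / 2 ? Iacur[w - 1] - gap_open : NEG_INF;
        double bestp; int code = pick3(vm, vib, via, bestp);
        if (bestp > NEG_INF / 2) { Ibcur[w] = bestp; cell |= (uint8_t)(code << 4); }
      }
      tb[(size_t)i * W + w] = cell;
      if (local && Mcur[w] > best_local) {
        best_local = Mcur[w]; best_i = i; best_j = j; any_local = true;
      }
      if (j == m) { colM[i] = Mcur[w]; colIa[i] = Iacur[w]; colIb[i] = Ibcur[w]; }
    }
    std::swap(Mprev, Mcur); std::swap(Iaprev, Iacur); std::swap(Ibprev, Ibcur);
  }
  // Mprev/Iaprev/Ibprev now hold row n.

  std::string ga, gb; // built reversed
  double score = 0.0;
  long a_start = 1, a_end = n, b_start = 1, b_end = m;

  if (local) {
    if (!any_local || best_local <= 0.0) {
      return List::create(_["score"] = 0.0, _["gapped_a"] = "", _["gapped_b"] = "",
                          _["a_start"] = 0, _["a_end"] = -1,
                          _["b_start"] = 0, _["b_end"] = -1);
    }
    score = best_local;
    long i = best_i, j = best_j; int state = 0; // a local optimum ends in M
    while (true) {
      uint8_t cell = tb[(size_t)i * W + (j - i - band_lo)];
      if (state == 0) {
        ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
        int code = cell & 3u;
        --i; --j;
        if (code == 3) break; // fresh start: first column already emitted
        state = code2state(code);
      } else if (state == 1) { // Ia
        ga.push_back(a[i - 1]); gb.push_back('-');
        state = code2state((cell >> 2) & 3u);
        --i;
      } else { // Ib
        ga.push_back('-'); gb.push_back(b[j - 1]);
        state = code2state((cell >> 4) & 3u);
        --j;
      }
      if (i == 0 || j == 0) break;
    }
    a_start = i + 1; a_end = best_i; b_start = j + 1; b_end = best_j;
  } else {
    // choose the global end cell; scan order makes ties deterministic:
    // (n, m) first, then the last row right-to-left, then the last column
    // bottom-to-top.
    long ei = n, ej = m; int estate = 0; double ebest = NEG_INF;
    auto consider = [&](long i, long j, double vm, double vib, double via) {
      double b1; int code = pick3(vm, vib, via, b1);
      if (b1 <= NEG_INF / 2) return;
      if (b1 > ebest) { ebest = b1; ei = i; ej = j; estate = code2state(code); }
    };
    if (end_free) {
      const long jlo = std::max((long)0, n + band_lo);
      const long jhi = std::min(m, n + band_hi);
      for (long j = jhi; j >= jlo; --j) {
        long w = j - n - band_lo;
        consider(n, j, Mprev[w], Ibprev[w], Iaprev[w]);
      }
      for (long i = n - 1; i >= 0; --i)
        consider(i, m, colM[i], colIb[i], colIa[i]);
    } else {
      long w = m - n - band_lo;
      if (w < 0 || w >= W) stop("band excludes the global end cell");
      consider(n, m, Mprev[w], Ibprev[w], Iaprev[w]);
    }
    if (ebest <= NEG_INF / 2) stop("no alignment path inside the band");
    score = ebest;

    // trailing pad: exactly one of the two overhangs can be non-empty
    for (long jj = m; jj > ej; --jj) { ga.push_back('-'); gb.push_back(b[jj - 1]); }
    for (long ii = n; ii > ei; --ii) { ga.push_back(a[ii - 1]); gb.push_back('-'); }

    long i = ei, j = ej; int state = estate;
    while (i > 0 && j > 0) {
      uint8_t cell = tb[(size_t)i * W + (j - i - band_lo)];
      if (state == 0) {
        ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
        state = code2state(cell & 3u);
        --i; --j;
      } else if (state == 1) {
        ga.push_back(a[i - 1]); gb.push_back('-');
        state = code2state((cell >> 2) & 3u);
        --i;
      } else {
        ga.push_back('-'); gb.push_back(b[j - 1]);
        state = code2state((cell >> 4) & 3u);
        --j;
      }
    }
    while (i > 0) { ga.push_back(a[i - 1]); gb.push_back('-'); --i; }
    while (j > 0) { ga.push_back('-'); gb.push_back(b[j - 1]); --j; }
  }

  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["score"] = score,
                      _["gapped_a"] = ga, _["gapped_b"] = gb,
                      _["a_start"] = a_start, _["a_end"] = a_end,
                      _["b_start"] = b_start, _["b_end"] = b_end);
}

// Score-only local (Smith-Waterman-Gotoh), linear memory.  Used for shuffle
// nulls where only the score distribution matters.
// [[Rcpp::export]]
double cpp_local_score(std::string a, std::string b,
                       double match, double mismatch,
                       double gap_open, double gap_ext) {
  const long n = (long)a.size(), m = (long)b.size();
  if (n < 1 || m < 1) stop("empty sequence");
  std::vector<double> Mp(m + 1, 0.0), Iap(m + 1, NEG_INF), Ibp(m + 1, NEG_INF);
  std::vector<double> Mc(m + 1, 0.0), Iac(m + 1, NEG_INF), Ibc(m + 1, NEG_INF);
  double best = 0.0;
  for (long i = 1; i <= n; ++i) {
    Mc[0] = 0.0; Iac[0] = NEG_INF; Ibc[0] = NEG_INF;
    const char ca = a[i - 1];
    for (long j = 1; j <= m; ++j) {
      double sc = subst(ca, b[j - 1], match, mismatch);
      double diag = std::max(Mp[j - 1], std::max(Iap[j - 1], Ibp[j - 1]));
      double v = (diag > 0 ? diag : 0.0) + sc;
      Mc[j] = v > 0 ? v : 0.0;
      Iac[j] = std::max(Mp[j] - gap_open,
                        std::max(Iap[j] - gap_ext, Ibp[j] - gap_open));
      Ibc[j] = std::max(Mc[j - 1] - gap_open,
                        std::max(Ibc[j - 1] - gap_ext, Iac[j - 1] - gap_open));
      if (Mc[j] > best) best = Mc[j];
    }
    std::swap(Mp, Mc); std::swap(Iap, Iac); std::swap(Ibp, Ibc);
  }
  return best;
}

// k-tuple word matches binned by diagonal (Wilbur-Lipman seeding).
// Returns an integer vector of length n + m - 1; 0-based diagonal d = j - i
// lands at R index d + n (1-based).
// [[Rcpp::export]]
IntegerVector cpp_diag_hits(std::string a, std::string b, int k) {
  const long n = (long)a.size(), m = (long)b.size();
  if (k < 1 || k > 12) stop("k-tuple size out of range");
  if (n + m - 1 <= 0) stop("empty sequence");
  IntegerVector out(n + m - 1);
  if (n < k || m < k) return out;
  auto code_at = [&](const std::string &s, long pos) -> long {
    long c = 0;
    for (int t = 0; t < k; ++t) {
      int v;
      switch (s[pos + t]) { case 'A': v = 0; break; case 'C': v = 1; break;
                            case 'G': v = 2; break; case 'T': v = 3; break;
                            default: return -1; }
      c = c * 4 + v;
    }
    return c;
  };
  const long nw = 1L << (2 * k);
  std::vector<std::vector<int>> posb(nw);
  for (long j = 0; j + k <= m; ++j) {
    long c = code_at(b, j);
    if (c >= 0) posb[c].push_back((int)j);
  }
  for (long i = 0; i + k <= n; ++i) {
    long c = code_at(a, i);
    if (c < 0) continue;
    for (int j : posb[c]) out[(long)j - i + (n - 1)]++;
  }
  return out;
}

// Brute-force optimal affine-gap alignment score by exhaustive enumeration of
// all monotone matchings between the two sequences (no dynamic programming).
// Between consecutive matched pairs each row's unmatched letters form a
// single gap run, the cheapest arrangement when gap_open >= gap_ext >= 0, so
// the maximum over matchings equals the optimum over all gapped alignments.
// Independent reference for short sequences only.
// [[Rcpp::export]]
double cpp_brute_score(std::string a, std::string b,
                       double match, double mismatch,
                       double gap_open, double gap_ext, bool end_free) {
  const long n = (long)a.size(), m = (long)b.size();
  if (n < 1 || m < 1) stop("empty sequence");
  if (n > 9 || m > 9) stop("brute-force oracle limited to length <= 9");
  double best = NEG_INF;
  std::function<void(long, long, double, bool)> rec =
    [&](long i, long j, double acc, bool first) {
      double tail = end_free ? 0.0
        : -(gapcost(n - i + 1, gap_open, gap_ext) +
            gapcost(m - j + 1, gap_open, gap_ext));
      if (acc + tail > best) best = acc + tail;
      for (long p = i; p <= n; ++p) {
        for (long q = j; q <= m; ++q) {
          double seg = (first && end_free) ? 0.0
            : -(gapcost(p - i, gap_open, gap_ext) +
                gapcost(q - j, gap_open, gap_ext));
          double s = subst(a[p - 1], b[q - 1], match, mismatch);
          rec(p + 1, q + 1, acc + seg + s, false);
        }
      }
    };
  rec(1, 1, 0.0, true);
  return best;
}

// Longest common substring length (ungapped, N excluded from matching).
// [[Rcpp::export]]
int cpp_longest_common_substring(std::string a, std::string b) {
  const long n = (long)a.size(), m = (long)b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0;
  for (long i = 1; i <= n; ++i) {
    cur[0] = 0;
    for (long j = 1; j <= m; ++j) {
      if (a[i - 1] == b[j - 1] && a[i - 1] != 'N') {
        cur[j] = prev[j - 1] + 1;
        if (cur[j] > best) best = cur[j];
      } else cur[j] = 0;
    }
    std::swap(prev, cur);
  }
  return best;
}
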