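#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gap costs (Gotoh) and full
// traceback. `a` is the query window, `b` the oriented read; gap_open and
// gap_ext are positive costs (a gap of length L costs gap_open + L*gap_ext).
// Positions involving a non-ACGT character always score as mismatches.
// Returns 1-based coordinates; q_cols/r_cols list the aligned (match or
// mismatch) columns, del_cols the query positions aligned against a gap in
// the read.

static inline bool is_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b, double match, double mismatch,
                  double gap_open, double gap_ext) {
  const int m = (int)a.size(), n = (int)b.size();
  const double NEG = -1e18;
  const int W = n + 1;
  std::vector<double> H((m + 1) * W, 0.0), E((m + 1) * W, NEG), F((m + 1) * W, NEG);
  std::vector<unsigned char> tH((m + 1) * W, 0), tE((m + 1) * W, 0), tF((m + 1) * W, 0);
  const double go = gap_open + gap_ext;
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const char ca = a[i - 1];
    const bool aok = is_base(ca);
    for (int j = 1; j <= n; ++j) {
      const int idx = i * W + j;
      const double e_open = H[i * W + (j - 1)] - go;
      const double e_ext = E[i * W + (j - 1)] - gap_ext;
      if (e_open >= e_ext) { E[idx] = e_open; tE[idx] = 1; }
      else { E[idx] = e_ext; tE[idx] = 0; }
      const double f_open = H[(i - 1) * W + j] - go;
      const double f_ext = F[(i - 1) * W + j] - gap_ext;
      if (f_open >= f_ext) { F[idx] = f_open; tF[idx] = 1; }
      else { F[idx] = f_ext; tF[idx] = 0; }
      const char cb = b[j - 1];
      const double s = (aok && is_base(cb) && ca == cb) ? match : mismatch;
      const double diag = H[(i - 1) * W + (j - 1)] + s;
      double h = 0.0;
      unsigned char t = 0;
      if (diag > h) { h = diag; t = 1; }
      if (E[idx] > h) { h = E[idx]; t = 2; }
      if (F[idx] > h) { h = F[idx]; t = 3; }
      H[idx] = h; tH[idx] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::vector<int> qcols, rcols, dels;
  int matches = 0, mismatches = 0, gapcols = 0;
  int i = bi, j = bj;
  if (best > 0) {
    char state = 'H';
    while (i > 0 && j > 0) {
      const int idx = i * W + j;
      if (state == 'H') {
        const unsigned char t = tH[idx];
        if (t == 0) break;
        if (t == 1) {
          qcols.push_back(i);
          rcols.push_back(j);
          const char ca = a[i - 1], cb = b[j - 1];
          if (is_base(ca) && ca == cb) ++matches; else ++mismatches;
          --i; --j;
        } else if (t == 2) {
          state = 'E';
        } else {
          state = 'F';
        }
      } else if (state == 'E') {
        ++gapcols;
        const unsigned char t = tE[idx];
        --j;
        if (t == 1) state = 'H';
      } else {
        ++gapcols;
        dels.push_back(i);
        --i;
        if (tF[idx] == 1) state = 'H';
      }
    }
  }
  std::reverse(qcols.begin(), qcols.end());
  std::reverse(rcols.begin(), rcols.end());
  std::reverse(dels.begin(), dels.end());
  return List::create(
    _["score"] = best,
    _["a_start"] = best > 0 ? i + 1 : 0,
    _["a_end"] = bi,
    _["b_start"] = best > 0 ? j + 1 : 0,
    _["b_end"] = bj,
    _["q_cols"] = IntegerVector(qcols.begin(), qcols.end()),
    _["r_cols"] = IntegerVector(rcols.begin(), rcols.end()),
    _["del_cols"] = IntegerVector(dels.begin(), dels.end()),
    _["matches"] = matches,
    _["mismatches"] = mismatches,
    _["gap_columns"] = gapcols);
}
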