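#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// median of a scratch buffer (modified in place)
static double med(std::vector<double>& v) {
  const size_t n = v.size();
  std::vector<double>::iterator mid = v.begin() + n / 2;
  std::nth_element(v.begin(), mid, v.end());
  double hi = *mid;
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(v.begin(), mid);
  return (hi + lo) / 2.0;
}

// Per-cell median difference between group A segments and the complement.
// S: segments x cells (one column per frequency-time cell);
// idxA: 1-based segment indices of group A ("post").
// [[Rcpp::export]]
NumericVector median_diff_cells(NumericMatrix S, IntegerVector idxA) {
  const int nseg = S.nrow(), ncell = S.ncol(), na = idxA.size();
  std::vector<bool> inA(nseg, false);
  for (int j = 0; j < na; ++j) inA[idxA[j] - 1] = true;
  const int nb = nseg - na;
  NumericVector out(ncell);
  std::vector<double> a(na), b(nb);
  for (int c = 0; c < ncell; ++c) {
    const double* col = &S(0, c);
    int ia = 0, ib = 0;
    for (int s = 0; s < nseg; ++s) {
      if (inA[s]) a[ia++] = col[s]; else b[ib++] = col[s];
    }
    out[c] = med(a) - med(b);
  }
  return out;
}

// Permutation reference distribution of the median-difference map.
// idxA: n_perm x N matrix of 1-based group-A segment indices.
// Scalar mode (matrixwise = false): per permutation, the global max and min
// of the map. Matrixwise mode: per-cell running max/min across permutations.
// Per-cell values are presorted once; each permutation's two group medians
// are then found by a single rank-counting pass over the sorted values.
// [[Rcpp::export]]
List perm_extremes(NumericMatrix S, IntegerMatrix idxA, bool matrixwise) {
  const int nseg = S.nrow(), ncell = S.ncol();
  const int nperm = idxA.nrow(), na = idxA.ncol();
  const int nb = nseg - na;
  if (nb <= 0) stop("group A cannot contain every segment");

  // presort each cell's column, remembering the segment of each value
  std::vector<double> sval((size_t)nseg * ncell);
  std::vector<unsigned short> sseg((size_t)nseg * ncell);
  {
    std::vector<int> ord(nseg);
    for (int c = 0; c < ncell; ++c) {
      const double* col = &S(0, c);
      for (int s = 0; s < nseg; ++s) ord[s] = s;
      std::sort(ord.begin(), ord.end(),
                [col](int i, int j) { return col[i] < col[j]; });
      for (int s = 0; s < nseg; ++s) {
        sval[(size_t)c * nseg + s] = col[ord[s]];
        sseg[(size_t)c * nseg + s] = (unsigned short)ord[s];
      }
    }
  }

  // 1-based ranks of the lower/upper middle order statistics per group
  const int raLo = (na + 1) / 2, raHi = na / 2 + 1;
  const int rbLo = (nb + 1) / 2, rbHi = nb / 2 + 1;

  std::vector<bool> inA(nseg);
  NumericVector gmax(matrixwise ? 0 : nperm), gmin(matrixwise ? 0 : nperm);
  NumericVector cmax(matrixwise ? ncell : 0), cmin(matrixwise ? ncell : 0);
  if (matrixwise) {
    std::fill(cmax.begin(), cmax.end(), R_NegInf);
    std::fill(cmin.begin(), cmin.end(), R_PosInf);
  }

  for (int p = 0; p < nperm; ++p) {
    std::fill(inA.begin(), inA.end(), false);
    for (int j = 0; j < na; ++j) inA[idxA(p, j) - 1] = true;
    double pmax = R_NegInf, pmin = R_PosInf;
    for (int c = 0; c < ncell; ++c) {
      const double* v = &sval[(size_t)c * nseg];
      const unsigned short* sg = &sseg[(size_t)c * nseg];
      int ca = 0, cb = 0;
      double aLo = 0, aHi = 0, bLo = 0, bHi = 0;
      for (int k = 0; k < nseg; ++k) {
        if (inA[sg[k]]) {
          ++ca;
          if (ca == raLo) aLo = v[k];
          if (ca == raHi) {
            aHi = v[k];
            if (cb >= rbHi) break;
          }
        } else {
          ++cb;
          if (cb == rbLo) bLo = v[k];
          if (cb == rbHi) {
            bHi = v[k];
            if (ca >= raHi) break;
          }
        }
      }
      double d = (aLo + aHi) / 2.0 - (bLo + bHi) / 2.0;
      if (matrixwise) {
        if (d > cmax[c]) cmax[c] = d;
        if (d < cmin[c]) cmin[c] = d;
      } else {
        if (d > pmax) pmax = d;
        if (d < pmin) pmin = d;
      }
    }
    if (!matrixwise) { gmax[p] = pmax; gmin[p] = pmin; }
  }

  if (matrixwise) {
    return List::create(Named("cell_max") = cmax, Named("cell_min") = cmin);
  }
  return List::create(Named("max") = gmax, Named("min") = gmin);
}
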