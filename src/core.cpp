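#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Longest common subsequence kernels.
//
// Sequences arrive as integer code vectors (1-based alphabet codes).  The
// classic O(|A||B|) dynamic programming recurrence serves as the reference;
// the bit-parallel variant packs 64 DP cells into one machine word and must
// return identical values for every input.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".lcs_dp_cpp")]]
int lcs_dp_cpp(IntegerVector a, IntegerVector b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      if (ai == b[j - 1])
        cur[j] = prev[j - 1] + 1;
      else
        cur[j] = prev[j] > cur[j - 1] ? prev[j] : cur[j - 1];
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Bit-vector LCS (Crochemore-style row update).  Bits span the shorter
// sequence so ceil(min(|A|,|B|)/64) words are updated per row:
//   U = V & PM[c];  V = (V + U) | (V - U)
// with carry/borrow propagated across words; LCS = bits − popcount(V).
// [[Rcpp::export(name = ".lcs_bitparallel_cpp")]]
int lcs_bitparallel_cpp(IntegerVector a, IntegerVector b) {
  IntegerVector s = (a.size() <= b.size()) ? a : b;   // bit dimension
  IntegerVector t = (a.size() <= b.size()) ? b : a;   // scanned dimension
  const int m = s.size();
  const int nw = (m + 63) / 64;

  int maxcode = 0;
  for (int i = 0; i < m; ++i) if (s[i] > maxcode) maxcode = s[i];

  std::vector<uint64_t> pm((size_t)(maxcode + 1) * nw, 0ULL);
  for (int i = 0; i < m; ++i)
    pm[(size_t)s[i] * nw + (i >> 6)] |= (1ULL << (i & 63));

  std::vector<uint64_t> V(nw, ~0ULL);
  if (m & 63) V[nw - 1] = (1ULL << (m & 63)) - 1;  // mask unused high bits
  const uint64_t topmask = V[nw - 1];

  const int tn = t.size();
  for (int j = 0; j < tn; ++j) {
    const int c = t[j];
    const uint64_t *M = (c <= maxcode) ? &pm[(size_t)c * nw] : NULL;
    uint64_t carry = 0, borrow = 0;
    for (int w = 0; w < nw; ++w) {
      const uint64_t u = M ? (V[w] & M[w]) : 0ULL;
      const uint64_t v = V[w];
      // add = v + u + carry
      uint64_t add = v + u;
      uint64_t c1 = add < v;
      uint64_t add2 = add + carry;
      c1 |= (add2 < add);
      // sub = v - u - borrow
      uint64_t sub = v - u;
      uint64_t b1 = v < u;
      uint64_t sub2 = sub - borrow;
      b1 |= (sub < borrow);
      V[w] = add2 | sub2;
      carry = c1;
      borrow = b1;
    }
    V[nw - 1] &= topmask;
  }

  int ones = 0;
  for (int w = 0; w < nw; ++w) {
    uint64_t x = V[w];
    while (x) { x &= x - 1; ++ones; }
  }
  return m - ones;
}

// ---------------------------------------------------------------------------
// Profile-profile affine dynamic programming (three states).
//
// States: M (match of one X column with one Y column), GY (a gap column is
// inserted into profile Y while consuming an X column), GX (gap column into
// X consuming a Y column).  Direct GX<->GY transitions are allowed: with
// gap-type correction a pair of consecutive gap columns in both profiles can
// beat a match, so the double-gap option must be explored.
//
// Terminal gap penalties apply to runs lying before the first or after the
// last column of the receiving profile (j == 0 / j == n2 for GY, i == 0 /
// i == n1 for GX); a run keeps its j (resp. i) constant, so the decision is
// per run, matching the per-row truth whenever member rows carry no earlier
// terminal gaps at that flank.
//
// smatch[i][j]  : summed pair score of aligning X column i with Y column j.
// gy_open[i] .. : cost of a freshly opened / extended (internal or terminal)
//                 gap column in Y placed against X column i; gx_* likewise.
// Ties are broken preferring MATCH > GAP_IN_Y > GAP_IN_X.
// Returned ops: 1 = MATCH, 2 = GAP_IN_X (consumes a Y column),
//               3 = GAP_IN_Y (consumes an X column), left to right.
// ---------------------------------------------------------------------------

static const double NEG_INF = -1e300;

// [[Rcpp::export(name = ".affine_dp_cpp")]]
List affine_dp_cpp(NumericMatrix smatch,
                   NumericVector gy_open, NumericVector gy_ext,
                   NumericVector gy_topen, NumericVector gy_text,
                   NumericVector gx_open, NumericVector gx_ext,
                   NumericVector gx_topen, NumericVector gx_text) {
  const int n1 = smatch.nrow(), n2 = smatch.ncol();
  const size_t W = (size_t)n2 + 1;

  std::vector<double> Mp(W), GYp(W), GXp(W), Mc(W), GYc(W), GXc(W);
  // traceback planes: predecessor state (0 = M, 1 = GY, 2 = GX)
  std::vector<uint8_t> ptrM((size_t)(n1 + 1) * W), ptrGY((size_t)(n1 + 1) * W),
      ptrGX((size_t)(n1 + 1) * W);

  // row i = 0
  Mp[0] = 0.0; GYp[0] = NEG_INF; GXp[0] = NEG_INF;
  for (int j = 1; j <= n2; ++j) {
    Mp[j] = NEG_INF;
    GYp[j] = NEG_INF;
    // gaps inserted into X before any X column: terminal (i == 0)
    double open_from = Mp[j - 1] + gx_topen[j - 1];
    double ext_from = GXp[j - 1] + gx_text[j - 1];
    if (j == 1 || open_from >= ext_from) { GXp[j] = open_from; ptrGX[j] = 0; }
    if (j > 1 && ext_from > open_from)   { GXp[j] = ext_from;  ptrGX[j] = 2; }
  }

  for (int i = 1; i <= n1; ++i) {
    const size_t row = (size_t)i * W;
    Mc[0] = NEG_INF; GXc[0] = NEG_INF;
    {
      // gaps into Y before any Y column: terminal (j == 0)
      double open_from = Mp[0] + gy_topen[i - 1];
      double ext_from = GYp[0] + gy_text[i - 1];
      if (i == 1 || open_from >= ext_from) { GYc[0] = open_from; ptrGY[row] = 0; }
      if (i > 1 && ext_from > open_from)   { GYc[0] = ext_from;  ptrGY[row] = 1; }
    }
    for (int j = 1; j <= n2; ++j) {
      // M from diagonal
      double best = Mp[j - 1]; uint8_t arg = 0;
      if (GYp[j - 1] > best) { best = GYp[j - 1]; arg = 1; }
      if (GXp[j - 1] > best) { best = GXp[j - 1]; arg = 2; }
      Mc[j] = best + smatch(i - 1, j - 1);
      ptrM[row + j] = arg;

      // GY: gap column into Y, consuming X column i
      const bool tY = (j == n2);  // j == 0 handled above
      const double oY = tY ? gy_topen[i - 1] : gy_open[i - 1];
      const double eY = tY ? gy_text[i - 1] : gy_ext[i - 1];
      best = Mp[j] + oY; arg = 0;
      if (GYp[j] + eY > best) { best = GYp[j] + eY; arg = 1; }
      if (GXp[j] + oY > best) { best = GXp[j] + oY; arg = 2; }
      GYc[j] = best;
      ptrGY[row + j] = arg;

      // GX: gap column into X, consuming Y column j
      const bool tX = (i == n1);
      const double oX = tX ? gx_topen[j - 1] : gx_open[j - 1];
      const double eX = tX ? gx_text[j - 1] : gx_ext[j - 1];
      best = Mc[j - 1] + oX; arg = 0;
      if (GYc[j - 1] + oX > best) { best = GYc[j - 1] + oX; arg = 1; }
      if (GXc[j - 1] + eX > best) { best = GXc[j - 1] + eX; arg = 2; }
      GXc[j] = best;
      ptrGX[row + j] = arg;
    }
    std::swap(Mp, Mc); std::swap(GYp, GYc); std::swap(GXp, GXc);
  }

  double score = Mp[n2]; int state = 0;
  if (GYp[n2] > score) { score = GYp[n2]; state = 1; }
  if (GXp[n2] > score) { score = GXp[n2]; state = 2; }

  std::vector<int> ops;
  ops.reserve(n1 + n2);
  int i = n1, j = n2;
  while (i > 0 || j > 0) {
    const size_t row = (size_t)i * W;
    if (state == 0) {
      ops.push_back(1); state = ptrM[row + j]; --i; --j;
    } else if (state == 1) {
      ops.push_back(3); state = ptrGY[row + j]; --i;
    } else {
      ops.push_back(2); state = ptrGX[row + j]; --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["ops"] = wrap(ops), _["score"] = score);
}
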