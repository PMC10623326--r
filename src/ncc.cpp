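#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Normalized cross-correlation of two equal-shape tiles at integer
// displacement (du, dv): b is displaced by (du, dv) relative to a, terms are
// mean-centered by the overlap-region means (unbiased at nonzero shifts;
// identical to whole-tile means at (0,0)). Degenerate overlaps (zero
// variance on either side) give 0.
static double ncc_at(const double* a, const double* b,
                     int nr, int nc, int du, int dv, bool* degenerate) {
  // overlap rows in a: r in [max(0, du), min(nr, nr + du))
  int r0 = du > 0 ? du : 0, r1 = du > 0 ? nr : nr + du;
  int c0 = dv > 0 ? dv : 0, c1 = dv > 0 ? nc : nc + dv;
  int n = (r1 - r0) * (c1 - c0);
  if (n <= 1) { *degenerate = true; return 0.0; }
  double sa = 0, sb = 0;
  for (int c = c0; c < c1; ++c)
    for (int r = r0; r < r1; ++r) {
      sa += a[c * nr + r];
      sb += b[(c - dv) * nr + (r - du)];
    }
  double ma = sa / n, mb = sb / n;
  double num = 0, da = 0, db = 0;
  for (int c = c0; c < c1; ++c)
    for (int r = r0; r < r1; ++r) {
      double xa = a[c * nr + r] - ma;
      double xb = b[(c - dv) * nr + (r - du)] - mb;
      num += xa * xb;
      da += xa * xa;
      db += xb * xb;
    }
  if (da <= 0.0 || db <= 0.0) { *degenerate = true; return 0.0; }
  return num / std::sqrt(da * db);
}

// Full correlation surface for displacements in [-max_shift, max_shift]^2.
// Row i of the result is row displacement du = i - max_shift, column j is
// dv = j - max_shift. attr "degenerate": zero variance at (0,0).
// [[Rcpp::export(name = ".cpp_ncc_surface")]]
NumericMatrix cpp_ncc_surface(NumericMatrix a, NumericMatrix b,
                              int max_shift) {
  int nr = a.nrow(), nc = a.ncol();
  if (b.nrow() != nr || b.ncol() != nc)
    stop("tiles must have identical shape");
  int m = 2 * max_shift + 1;
  NumericMatrix out(m, m);
  bool deg00 = false;
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < m; ++i) {
      bool deg = false;
      out(i, j) = ncc_at(&a[0], &b[0], nr, nc,
                         i - max_shift, j - max_shift, &deg);
      if (deg && i == max_shift && j == max_shift) deg00 = true;
    }
  out.attr("degenerate") = deg00;
  return out;
}

// Peak location with tie-breaking toward the smaller displacement magnitude,
// then row-major order; then per-axis three-point parabolic refinement.
// Returns (uhat, vhat, du, dv, flag): flag 1 = border / flat-parabola
// fallback (that axis refined to 0) or clamped, flag 2 = degenerate
// (all-zero) surface, offset (0,0,0,0).
static void refine_peak_core(const double* s, int m, int max_shift,
                             double out[5]) {
  int bi = -1, bj = -1;
  double best = R_NegInf;
  bool all_zero = true;
  // row-major scan (row displacement u outer) so that among exact ties of
  // equal magnitude the earlier row-major candidate is kept
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < m; ++j) {
      double v = s[j * m + i];
      if (v != 0.0) all_zero = false;
      if (v > best) { best = v; bi = i; bj = j; }
      else if (v == best) {
        int du = i - max_shift, dv = j - max_shift;
        int bu = bi - max_shift, bv = bj - max_shift;
        if (du * du + dv * dv < bu * bu + bv * bv) { bi = i; bj = j; }
      }
    }
  if (all_zero) {
    out[0] = out[1] = out[2] = out[3] = 0.0;
    out[4] = 2.0;
    return;
  }
  double flag = 0.0;
  double delta[2] = {0.0, 0.0};
  int idx[2] = {bi, bj};
  for (int ax = 0; ax < 2; ++ax) {
    if (idx[ax] == 0 || idx[ax] == m - 1) { flag = 1.0; continue; }
    double sm, s0, sp;
    if (ax == 0) {
      sm = s[bj * m + (bi - 1)]; s0 = s[bj * m + bi]; sp = s[bj * m + (bi + 1)];
    } else {
      sm = s[(bj - 1) * m + bi]; s0 = s[bj * m + bi]; sp = s[(bj + 1) * m + bi];
    }
    double denom = 2.0 * (sm - 2.0 * s0 + sp);
    if (std::fabs(denom) < 1e-12) { flag = 1.0; continue; }
    double d = (sm - sp) / denom;
    if (d > 0.5)  { d = 0.5;  flag = 1.0; }
    if (d < -0.5) { d = -0.5; flag = 1.0; }
    delta[ax] = d;
  }
  out[0] = bi - max_shift;
  out[1] = bj - max_shift;
  out[2] = delta[0];
  out[3] = delta[1];
  out[4] = flag;
}

// [[Rcpp::export(name = ".cpp_refine_peak")]]
NumericVector cpp_refine_peak(NumericMatrix surface) {
  int m = surface.nrow();
  if (surface.ncol() != m || m % 2 != 1)
    stop("surface must be square with odd side");
  double out[5];
  refine_peak_core(&surface[0], m, (m - 1) / 2, out);
  return NumericVector::create(out[0], out[1], out[2], out[3], out[4]);
}

// Refined offsets for every tile of one frame pair. rows0/cols0 are 0-based
// pixel origins of the tiles. Returns ntiles x 5 (duRow, dvCol incl.
// subpixel part as columns 0..3: uhat, vhat, deltaRow, deltaCol; col 4 flag).
// [[Rcpp::export(name = ".cpp_pair_offsets")]]
NumericMatrix cpp_pair_offsets(NumericMatrix a, NumericMatrix b,
                               IntegerVector rows0, IntegerVector cols0,
                               int tile, int max_shift) {
  int nr = a.nrow(), nc = a.ncol();
  if (b.nrow() != nr || b.ncol() != nc)
    stop("frames must have identical shape");
  int ntiles = rows0.size();
  int m = 2 * max_shift + 1;
  NumericMatrix out(ntiles, 5);
  std::vector<double> ta(tile * tile), tb(tile * tile), surf(m * m);
  for (int t = 0; t < ntiles; ++t) {
    int r0 = rows0[t], c0 = cols0[t];
    if (r0 < 0 || c0 < 0 || r0 + tile > nr || c0 + tile > nc)
      stop("tile outside frame");
    for (int c = 0; c < tile; ++c)
      for (int r = 0; r < tile; ++r) {
        ta[c * tile + r] = a[(c0 + c) * nr + (r0 + r)];
        tb[c * tile + r] = b[(c0 + c) * nr + (r0 + r)];
      }
    bool deg00 = false;
    for (int j = 0; j < m; ++j)
      for (int i = 0; i < m; ++i) {
        bool deg = false;
        surf[j * m + i] = ncc_at(ta.data(), tb.data(), tile, tile,
                                 i - max_shift, j - max_shift, &deg);
        if (deg && i == max_shift && j == max_shift) deg00 = true;
      }
    double res[5];
    refine_peak_core(surf.data(), m, max_shift, res);
    if (deg00 && res[4] < 2.0) res[4] = 2.0;
    // report motion-signed offsets: the displacement of frame b's content
    // relative to frame a is the negative of the correlation argmax
    for (int k = 0; k < 4; ++k) out(t, k) = -res[k];
    out(t, 4) = res[4];
  }
  return out;
}
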