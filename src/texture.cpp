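#include <Rcpp.h>
using namespace Rcpp;

// Grey-level co-occurrence counts for one (distance, angle) offset.
// `q` holds levels 1..ng inside the ROI and 0 outside; pairs with either
// pixel outside the ROI are ignored.  The returned ng x ng matrix holds the
// symmetrised raw counts (each ordered pair contributes to (i,j) and (j,i)).
// [[Rcpp::export]]
NumericMatrix cpp_glcm_counts(const IntegerMatrix& q, int ng,
                              int drow, int dcol) {
  const int nr = q.nrow(), nc = q.ncol();
  NumericMatrix out(ng, ng);
  for (int r = 0; r < nr; ++r) {
    const int r2 = r + drow;
    if (r2 < 0 || r2 >= nr) continue;
    for (int c = 0; c < nc; ++c) {
      const int c2 = c + dcol;
      if (c2 < 0 || c2 >= nc) continue;
      const int a = q(r, c), b = q(r2, c2);
      if (a == 0 || b == 0) continue;
      out(a - 1, b - 1) += 1.0;
      out(b - 1, a - 1) += 1.0;
    }
  }
  return out;
}

// Run-length counts along one direction.  A run is a maximal sequence of
// in-mask pixels with equal level along the direction; out-of-mask pixels
// (level 0) and image edges terminate runs.  Rows index levels 1..ng,
// columns run lengths 1..max_len (max_len = longest possible traversal).
// [[Rcpp::export]]
NumericMatrix cpp_glrlm_counts(const IntegerMatrix& q, int ng,
                               int drow, int dcol) {
  const int nr = q.nrow(), nc = q.ncol();
  const int max_len = std::max(nr, nc);
  NumericMatrix out(ng, max_len);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      // start of a traversal line: predecessor cell lies outside the image
      const int pr = r - drow, pc = c - dcol;
      if (pr >= 0 && pr < nr && pc >= 0 && pc < nc) continue;
      int cur = 0, len = 0;
      int rr = r, cc = c;
      while (rr >= 0 && rr < nr && cc >= 0 && cc < nc) {
        const int v = q(rr, cc);
        if (v == cur) {
          if (v != 0) ++len;
        } else {
          if (cur != 0) out(cur - 1, len - 1) += 1.0;
          cur = v;
          len = (v != 0) ? 1 : 0;
        }
        rr += drow;
        cc += dcol;
      }
      if (cur != 0) out(cur - 1, len - 1) += 1.0;
    }
  }
  return out;
}

// Separable 3x3 Sobel gradient magnitude, normalised so that an ideal
// vertical step edge of height h attains magnitude h.  Border pixels use
// replicated edges.
// [[Rcpp::export]]
NumericMatrix cpp_sobel_magnitude(const NumericMatrix& img) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  auto at = [&](int r, int c) {
    if (r < 0) r = 0; if (r >= nr) r = nr - 1;
    if (c < 0) c = 0; if (c >= nc) c = nc - 1;
    return img(r, c);
  };
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      const double gx =
        (at(r - 1, c + 1) + 2.0 * at(r, c + 1) + at(r + 1, c + 1)) -
        (at(r - 1, c - 1) + 2.0 * at(r, c - 1) + at(r + 1, c - 1));
      const double gy =
        (at(r + 1, c - 1) + 2.0 * at(r + 1, c) + at(r + 1, c + 1)) -
        (at(r - 1, c - 1) + 2.0 * at(r - 1, c) + at(r - 1, c + 1));
      out(r, c) = std::sqrt(gx * gx + gy * gy) / 4.0;
    }
  }
  return out;
}
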