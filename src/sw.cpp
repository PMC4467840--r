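#include <Rcpp.h>
using namespace Rcpp;

// Local alignment with affine gaps (Gotoh). Penalties are positive; a gap
// of length L costs gap_open + gap_extend * L. Sequences arrive as 1-based
// integer codes into the scoring matrix. Traceback ties prefer diagonal,
// then up (gap in b), then left (gap in a).
// [[Rcpp::export]]
List sw_align(IntegerVector a, IntegerVector b, NumericMatrix smat,
              double gap_open, double gap_extend) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0) stop("sw_align: empty sequence");
  const double open_cost = gap_open + gap_extend;
  // H: best score ending at (i,j); E: gap in a (left); F: gap in b (up)
  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Eprev(n + 1, R_NegInf), Ecur(n + 1, R_NegInf);
  std::vector<double> Fcur(n + 1, R_NegInf), Fprev(n + 1, R_NegInf);
  // traceback codes per cell: 0 stop, 1 diag, 2 up(F), 3 left(E)
  std::vector<unsigned char> tbH((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbE((size_t)(m + 1) * (n + 1), 0); // 1: extend
  std::vector<unsigned char> tbF((size_t)(m + 1) * (n + 1), 0);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0.0; Ecur[0] = R_NegInf; Fcur[0] = R_NegInf;
    for (int j = 1; j <= n; ++j) {
      size_t idx = (size_t)i * (n + 1) + j;
      // F: gap in b (move down / consume a)
      double f_open = Hprev[j] - open_cost;
      double f_ext  = Fprev[j] - gap_extend;
      double f = (f_ext > f_open) ? f_ext : f_open;
      tbF[idx] = (f_ext > f_open) ? 1 : 0;
      Fcur[j] = f;
      // E: gap in a (move right / consume b)
      double e_open = Hcur[j - 1] - open_cost;
      double e_ext  = Ecur[j - 1] - gap_extend;
      double e = (e_ext > e_open) ? e_ext : e_open;
      tbE[idx] = (e_ext > e_open) ? 1 : 0;
      Ecur[j] = e;
      double diag = Hprev[j - 1] + smat(a[i - 1] - 1, b[j - 1] - 1);
      double h = diag; unsigned char dir = 1;
      if (f > h) { h = f; dir = 2; }
      if (e > h) { h = e; dir = 3; }
      if (h <= 0.0) { h = 0.0; dir = 0; }
      Hcur[j] = h; tbH[idx] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
    std::swap(Fprev, Fcur);
  }
  // traceback from (bi, bj)
  int i = bi, j = bj, matches = 0, alen = 0;
  int state = 0; // 0 = in H, 1 = in F, 2 = in E
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (n + 1) + j;
    if (state == 0) {
      unsigned char d = tbH[idx];
      if (d == 0) break;
      if (d == 1) {
        if (a[i - 1] == b[j - 1]) ++matches;
        ++alen; --i; --j;
      } else if (d == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // F: consume a
      ++alen;
      unsigned char ext = tbF[idx];
      --i;
      if (!ext) state = 0;
    } else { // E: consume b
      ++alen;
      unsigned char ext = tbE[idx];
      --j;
      if (!ext) state = 0;
    }
  }
  return List::create(
    _["score"] = best,
    _["a_start"] = i, _["a_end"] = bi,   // 0-based half-open on a
    _["b_start"] = j, _["b_end"] = bj,
    _["matches"] = matches, _["aln_len"] = alen);
}
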