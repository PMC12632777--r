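#include <Rcpp.h>
using namespace Rcpp;

// LOD scan kernel: haplotype codes H (n strains x M markers, 1..8, 0 =
// missing) against phenotypes Y (n x P). For each marker and phenotype,
// LOD = (n/2) log10(RSS0 / RSS1) with maximum-likelihood (divide by n)
// variance estimates; RSS0 about the grand mean, RSS1 about the means of
// the observed haplotype classes. Strains missing at a marker are
// excluded at that marker.
// [[Rcpp::export]]
NumericMatrix lod_scan_cpp(IntegerMatrix H, NumericMatrix Y) {
  const int n = H.nrow(), M = H.ncol(), P = Y.ncol();
  if (Y.nrow() != n) stop("H and Y row counts disagree");
  NumericMatrix out(M, P);

  // full-data per-phenotype totals, reused for markers with no missing
  std::vector<double> totS(P), totQ(P);
  for (int p = 0; p < P; ++p) {
    double s = 0.0, q = 0.0;
    for (int i = 0; i < n; ++i) { double y = Y(i, p); s += y; q += y * y; }
    totS[p] = s; totQ[p] = q;
  }

  std::vector<int> cnt(8);
  std::vector<double> gs(8);
  for (int m = 0; m < M; ++m) {
    std::fill(cnt.begin(), cnt.end(), 0);
    int nm = 0;
    bool missing = false;
    for (int i = 0; i < n; ++i) {
      int g = H(i, m);
      if (g >= 1 && g <= 8) { ++cnt[g - 1]; ++nm; }
      else missing = true;
    }
    if (nm < 2) { for (int p = 0; p < P; ++p) out(m, p) = NA_REAL; continue; }
    for (int p = 0; p < P; ++p) {
      std::fill(gs.begin(), gs.end(), 0.0);
      double s, q;
      if (!missing) {
        s = totS[p]; q = totQ[p];
        for (int i = 0; i < n; ++i) {
          int g = H(i, m);
          gs[g - 1] += Y(i, p);
        }
      } else {
        s = 0.0; q = 0.0;
        for (int i = 0; i < n; ++i) {
          int g = H(i, m);
          if (g < 1 || g > 8) continue;
          double y = Y(i, p);
          gs[g - 1] += y; s += y; q += y * y;
        }
      }
      double rss0 = q - s * s / nm;
      double rss1 = q;
      for (int g = 0; g < 8; ++g)
        if (cnt[g] > 0) rss1 -= gs[g] * gs[g] / cnt[g];
      double lod;
      if (rss1 <= 0.0 || rss0 <= 0.0)
        lod = (rss0 <= 0.0) ? 0.0 : R_PosInf;
      else
        lod = 0.5 * nm * (std::log10(rss0) - std::log10(rss1));
      if (lod < 0.0) lod = 0.0;  // guard tiny negative rounding
      out(m, p) = lod;
    }
  }
  return out;
}
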