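#include "fqcmd.h"
using namespace Rcpp;

// Histogram of minimum-image pair distances for one frame.
// idx1/idx2: 1-based atom indices of the two species sets; mol: 1-based
// molecule id per atom (pairs sharing a molecule are excluded). If
// `same_set`, idx2 is ignored and unordered pairs within idx1 are counted.
// [[Rcpp::export]]
NumericVector pair_hist_cpp(NumericMatrix pos, NumericVector cell,
                            IntegerVector idx1, IntegerVector idx2,
                            IntegerVector mol, bool same_set,
                            double rmin, double dr, int nbins) {
  NumericVector counts(nbins);
  int n1 = idx1.size();
  int n2 = same_set ? n1 : idx2.size();
  for (int a = 0; a < n1; ++a) {
    int i = idx1[a] - 1;
    int bstart = same_set ? a + 1 : 0;
    for (int b = bstart; b < n2; ++b) {
      int j = (same_set ? idx1[b] : idx2[b]) - 1;
      if (mol[i] == mol[j]) continue;
      double d2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        double d = min_image(pos(j, k) - pos(i, k), cell[k]);
        d2 += d * d;
      }
      double r = std::sqrt(d2);
      int bin = (int)((r - rmin) / dr);
      if (bin >= 0 && bin < nbins) counts[bin] += 1.0;
    }
  }
  return counts;
}

// Per-molecule internal geometry (r1, r2, theta) for one O,H,H-ordered
// configuration, with minimum-image intramolecular vectors.
// [[Rcpp::export]]
NumericMatrix intra_geometry_cpp(NumericMatrix pos, NumericVector cell) {
  int nmol = pos.nrow() / 3;
  NumericMatrix out(nmol, 3);
  for (int m = 0; m < nmol; ++m) {
    double d1[3], d2[3];
    for (int k = 0; k < 3; ++k) {
      d1[k] = min_image(pos(3 * m + 1, k) - pos(3 * m, k), cell[k]);
      d2[k] = min_image(pos(3 * m + 2, k) - pos(3 * m, k), cell[k]);
    }
    double r1 = std::sqrt(d1[0] * d1[0] + d1[1] * d1[1] + d1[2] * d1[2]);
    double r2 = std::sqrt(d2[0] * d2[0] + d2[1] * d2[1] + d2[2] * d2[2]);
    double ct = (d1[0] * d2[0] + d1[1] * d2[1] + d1[2] * d2[2]) / (r1 * r2);
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
    out(m, 0) = r1;
    out(m, 1) = r2;
    out(m, 2) = std::acos(ct);
  }
  return out;
}

// Evaluate a tabulated pair correction (value and derivative) on a vector
// of distances; mirrors the interpolation used inside the engines.
// [[Rcpp::export]]
List pair_table_eval_cpp(List table, NumericVector r) {
  PairTable t;
  t.present = true;
  t.rmin = as<double>(table["r_min"]);
  t.dr = as<double>(table["dr"]);
  t.V = as<std::vector<double> >(table["V"]);
  t.D = as<std::vector<double> >(table["dV"]);
  t.rmax = t.rmin + t.dr * (t.V.size() - 1);
  int n = r.size();
  NumericVector v(n), d(n);
  for (int i = 0; i < n; ++i) {
    double vv, dd;
    t.eval(r[i], vv, dd);
    v[i] = vv;
    d[i] = dd;
  }
  return List::create(_["V"] = v, _["dV"] = d,
                      _["n_extrapolated"] = (double)t.extrap);
}
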