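#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area.
//
// For every atom i a deterministic point set (rows of `pts`, unit sphere)
// is scaled to radius r_i + probe and centred on the atom; points falling
// inside any neighbour's expanded sphere are buried. The accessible area
// is 4*pi*(r_i+probe)^2 times the accessible point fraction. `eval` (1-based
// indices) restricts which atoms are evaluated; all atoms occlude.
// [[Rcpp::export]]
NumericVector sasa_cpp(const NumericMatrix& xyz, const NumericVector& radii,
                       double probe, const NumericMatrix& pts,
                       const IntegerVector& eval) {
  const int n = xyz.nrow(), np = pts.nrow();
  NumericVector out(eval.size());
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);

  std::vector<double> ex(n);
  for (int i = 0; i < n; ++i) ex[i] = radii[i] + probe;

  for (int k = 0; k < eval.size(); ++k) {
    const int i = eval[k] - 1;
    const double ri = ex[i];
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);

    // neighbours whose expanded sphere can bury points of atom i
    std::vector<int> nb;
    const double reach = ri + rmax + probe;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi,
                   dz = xyz(j, 2) - zi;
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double lim = ri + ex[j];
      if (d2 < lim * lim && d2 < reach * reach) nb.push_back(j);
    }

    int acc = 0;
    for (int p = 0; p < np; ++p) {
      const double px = xi + ri * pts(p, 0);
      const double py = yi + ri * pts(p, 1);
      const double pz = zi + ri * pts(p, 2);
      bool buried = false;
      for (size_t q = 0; q < nb.size(); ++q) {
        const int j = nb[q];
        const double dx = px - xyz(j, 0), dy = py - xyz(j, 1),
                     dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < ex[j] * ex[j]) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    out[k] = 4.0 * M_PI * ri * ri * (double)acc / (double)np;
  }
  return out;
}

// All cross-group atom pairs within `cutoff`, with distances.
// g1/g2 are 1-based atom indices into xyz. Returns a 3-column matrix
// (i, j, d) with i from g1 and j from g2 (1-based).
// [[Rcpp::export]]
NumericMatrix close_pairs_cpp(const NumericMatrix& xyz,
                              const IntegerVector& g1,
                              const IntegerVector& g2, double cutoff) {
  const double c2 = cutoff * cutoff;
  std::vector<double> vi, vj, vd;
  for (int a = 0; a < g1.size(); ++a) {
    const int i = g1[a] - 1;
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    for (int b = 0; b < g2.size(); ++b) {
      const int j = g2[b] - 1;
      const double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi,
                   dz = xyz(j, 2) - zi;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 <= c2) {
        vi.push_back(g1[a]); vj.push_back(g2[b]); vd.push_back(std::sqrt(d2));
      }
    }
  }
  NumericMatrix out(vi.size(), 3);
  for (size_t r = 0; r < vi.size(); ++r) {
    out(r, 0) = vi[r]; out(r, 1) = vj[r]; out(r, 2) = vd[r];
  }
  colnames(out) = CharacterVector::create("i", "j", "d");
  return out;
}
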