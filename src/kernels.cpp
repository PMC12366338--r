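#include <Rcpp.h>
using namespace Rcpp;

// Minimum patristic distance from every taxon to the taxa present in each
// sample, under an optional permutation of the taxon labels (tip shuffle).
// D: n_taxa x n_taxa patristic distances; presence: list of 1-based index
// vectors of taxa present per sample; perm: 1-based permutation of taxa.
// Returns n_taxa x n_samples matrix M with M(j, s) = min_{t in s} D(perm[j], perm[t]).
// [[Rcpp::export(name = ".min_taxon_dist")]]
NumericMatrix min_taxon_dist(const NumericMatrix& D, const List& presence,
                             const IntegerVector& perm) {
  const int n_taxa = D.nrow();
  const int n_samp = presence.size();
  NumericMatrix M(n_taxa, n_samp);
  for (int s = 0; s < n_samp; ++s) {
    IntegerVector idx = presence[s];
    const int k = idx.size();
    for (int j = 0; j < n_taxa; ++j) {
      const double* drow = &D(0, perm[j] - 1); // column-major: column perm[j]-1
      double best = R_PosInf;
      for (int t = 0; t < k; ++t) {
        double v = drow[perm[idx[t] - 1] - 1];
        if (v < best) best = v;
      }
      M(j, s) = best;
    }
  }
  return M;
}

// Raup-Crick comparison counts: for each sample pair, how many of the
// n_null paired null draws have Bray-Curtis dissimilarity below / equal to
// the observed one. stacks: list (per sample) of n_taxa x n_null integer
// count matrices; obs_bc: n_samp x n_samp observed Bray-Curtis.
// [[Rcpp::export(name = ".rc_null_counts")]]
List rc_null_counts(const List& stacks, const NumericMatrix& obs_bc,
                    double tol) {
  const int n_samp = stacks.size();
  IntegerMatrix n_less(n_samp, n_samp), n_equal(n_samp, n_samp);
  for (int a = 0; a < n_samp; ++a) {
    IntegerMatrix xa = stacks[a];
    const int n_taxa = xa.nrow(), n_null = xa.ncol();
    for (int b = a + 1; b < n_samp; ++b) {
      IntegerMatrix xb = stacks[b];
      int less = 0, eq = 0;
      const double obs = obs_bc(a, b);
      for (int k = 0; k < n_null; ++k) {
        const int* ca = &xa(0, k);
        const int* cb = &xb(0, k);
        long num = 0, den = 0;
        for (int j = 0; j < n_taxa; ++j) {
          int d = ca[j] - cb[j];
          num += d > 0 ? d : -d;
          den += ca[j] + cb[j];
        }
        double bc = den > 0 ? (double)num / (double)den : 0.0;
        if (bc < obs - tol) ++less;
        else if (bc <= obs + tol) ++eq;
      }
      n_less(a, b) = n_less(b, a) = less;
      n_equal(a, b) = n_equal(b, a) = eq;
    }
  }
  return List::create(_["n_less"] = n_less, _["n_equal"] = n_equal);
}
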