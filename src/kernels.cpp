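#include <Rcpp.h>
using namespace Rcpp;

// Inbreeding coefficients by the Meuwissen & Luo (1992) recursion.
// sire/dam: 1-based indices into the (topologically sorted) pedigree, 0 = unknown.
// Parents must precede offspring.
// [[Rcpp::export]]
NumericVector inbreeding_cpp(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n), D(n);
  std::vector<double> L(n + 1, 0.0);
  std::vector<int> touched;
  touched.reserve(64);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    double Fs = s ? F[s - 1] : 0.0, Fd = d ? F[d - 1] : 0.0;
    if (!s && !d)
      D[i] = 1.0;  // founder: a_ii = 1
    else if (s && d)
      D[i] = 0.5 - 0.25 * (Fs + Fd);
    else
      D[i] = 0.75 - 0.25 * (s ? Fs : Fd);
    if (!s || !d) { F[i] = 0.0; continue; }
    // a_ii = sum over ancestors j of L_ij^2 D_j, traversed terminal -> founders
    double aii = 0.0;
    touched.clear();
    L[i + 1] = 1.0;
    touched.push_back(i + 1);
    for (int j = i + 1; j >= 1; --j) {
      double Lj = L[j];
      if (Lj == 0.0) continue;
      int js = sire[j - 1], jd = dam[j - 1];
      if (js) { if (L[js] == 0.0) touched.push_back(js); L[js] += 0.5 * Lj; }
      if (jd) { if (L[jd] == 0.0) touched.push_back(jd); L[jd] += 0.5 * Lj; }
      aii += Lj * Lj * D[j - 1];
    }
    for (size_t k = 0; k < touched.size(); ++k) L[touched[k]] = 0.0;
    F[i] = aii - 1.0;
  }
  return F;
}

// Dense numerator relationship matrix by the tabular (recursive) method.
// [[Rcpp::export]]
NumericMatrix tabular_a_cpp(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    A(i, i) = 1.0 + ((s && d) ? 0.5 * A(s - 1, d - 1) : 0.0);
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s) v += 0.5 * A(j, s - 1);
      if (d) v += 0.5 * A(j, d - 1);
      A(i, j) = A(j, i) = v;
    }
  }
  return A;
}

// Meiosis: one gamete per requested parent, Haldane crossovers.
// h1, h2: haplotype matrices (individuals x loci), integer alleles.
// parent: 1-based row index of the parent for each meiosis.
// rswitch: per-locus probability of switching the active haplotype between
// locus l-1 and l (rswitch[0] applies before the first locus; 0.5 at every
// chromosome start gives an independent random start per chromosome).
// Uses R's RNG so seeds propagate.
// [[Rcpp::export]]
IntegerMatrix drop_gametes_cpp(IntegerMatrix h1, IntegerMatrix h2,
                               IntegerVector parent, NumericVector rswitch) {
  int L = h1.ncol(), nm = parent.size();
  IntegerMatrix out(nm, L);
  for (int k = 0; k < nm; ++k) {
    int p = parent[k] - 1;
    int state = 0;
    for (int l = 0; l < L; ++l) {
      if (unif_rand() < rswitch[l]) state = 1 - state;
      out(k, l) = state ? h2(p, l) : h1(p, l);
    }
  }
  return out;
}
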