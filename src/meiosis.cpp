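// Core meiosis and allele-lookup kernels.
//
// Individuals are founder-origin mosaics: per chromosome and haplotype
// a piecewise-constant track (segment start positions in cM, founder
// haplotype ids). Gamete formation only splices tracks, and alleles
// are read from the founder haplotype matrix through the track, so no
// allele vectors are ever copied during breeding.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Haldane model: crossover count ~ Poisson(map length in Morgans),
// positions uniform, no interference, fair-coin starting strand.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List gamete_cpp(List org1, List org2, NumericVector len_cm) {
  int n_chrom = len_cm.size();
  List out(n_chrom);
  for (int c = 0; c < n_chrom; ++c) {
    double L = len_cm[c];
    int k = (int)R::rpois(L / 100.0);
    bool first = unif_rand() < 0.5;
    List A = first ? (List)org1[c] : (List)org2[c];
    if (k == 0) {
      out[c] = A;
      continue;
    }
    List B = first ? (List)org2[c] : (List)org1[c];
    std::vector<double> cuts(k);
    for (int i = 0; i < k; ++i) cuts[i] = unif_rand() * L;
    std::sort(cuts.begin(), cuts.end());
    NumericVector sA = A["start"], sB = B["start"];
    IntegerVector iA = A["id"], iB = B["id"];
    std::vector<double> rs;
    std::vector<int> ri;
    rs.reserve(8);
    ri.reserve(8);
    double lo = 0.0;
    for (int j = 0; j <= k; ++j) {
      double hi = (j == k) ? L : cuts[j];
      if (hi > lo) {
        NumericVector& s = (j % 2 == 0) ? sA : sB;
        IntegerVector& id = (j % 2 == 0) ? iA : iB;
        int i0 = (int)(std::upper_bound(s.begin(), s.end(), lo) - s.begin()) - 1;
        int i1 = (int)(std::lower_bound(s.begin(), s.end(), hi) - s.begin()) - 1;
        for (int i = i0; i <= i1; ++i) {
          double st = (i == i0) ? lo : s[i];
          int v = id[i];
          if (!ri.empty() && ri.back() == v) continue;
          rs.push_back(st);
          ri.push_back(v);
        }
      }
      lo = hi;
    }
    out[c] = List::create(_["start"] = wrap(rs), _["id"] = wrap(ri));
  }
  return out;
}

// Per-bin signature of one haplotype on a regular genetic grid: the
// founder id when a single segment covers the bin, otherwise the
// exact within-bin breakpoint layout, so copied haplotypes (and only
// those, up to floating-point coincidence) share mixed-bin signatures.
// [[Rcpp::export]]
CharacterVector bin_signature_cpp(List org, NumericVector len_cm, double seg) {
  int n_chrom = len_cm.size();
  std::vector<std::string> out;
  char buf[64];
  for (int c = 0; c < n_chrom; ++c) {
    List tr = org[c];
    NumericVector s = tr["start"];
    IntegerVector id = tr["id"];
    int ns = s.size();
    int nbin = (int)std::lround(len_cm[c] / seg);
    int i = 0;
    for (int b = 0; b < nbin; ++b) {
      double lo = b * seg, hi = lo + seg;
      while (i + 1 < ns && s[i + 1] <= lo) ++i;
      int i1 = i;
      while (i1 + 1 < ns && s[i1 + 1] < hi - 1e-9) ++i1;
      if (i1 == i) {
        out.push_back(std::to_string(id[i]));
      } else {
        std::string sig;
        for (int k = i; k <= i1; ++k) {
          double st = (k == i) ? 0.0 : s[k] - lo;
          snprintf(buf, sizeof(buf), "%d@%.9g|", id[k], st);
          sig += buf;
        }
        out.push_back(sig);
      }
    }
  }
  return wrap(out);
}

// Alleles of one haplotype at a set of loci (1-based global indices,
// grouped by chromosome and position-sorted within it, as all locus
// index sets in this package are).
// [[Rcpp::export]]
IntegerVector hap_alleles_cpp(List org, IntegerVector chrom, NumericVector pos,
                              IntegerVector loci, IntegerMatrix H) {
  int n = loci.size();
  IntegerVector out(n);
  int j = 0;
  while (j < n) {
    int c = chrom[loci[j] - 1];
    List tr = org[c - 1];
    NumericVector s = tr["start"];
    IntegerVector id = tr["id"];
    int ns = s.size();
    int i = 0;
    for (; j < n && chrom[loci[j] - 1] == c; ++j) {
      int l = loci[j] - 1;
      double p = pos[l];
      if (p < s[i]) {  // out-of-order query: restart the walk
        i = (int)(std::upper_bound(s.begin(), s.end(), p) - s.begin()) - 1;
        if (i < 0) i = 0;
      }
      while (i + 1 < ns && s[i + 1] <= p) ++i;
      out[j] = H(id[i] - 1, l);
    }
  }
  return out;
}
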