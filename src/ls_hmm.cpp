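#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Haploid Li-Stephens copying model: a target haplotype typed at a scaffold
// of sites is modelled as a mosaic of K panel haplotypes.  Switches between
// copied haplotypes occur between adjacent scaffold sites with probability
// rho_j = 1 - exp(-4 * Ne * rec * d_j / K) for inter-site distance d_j; at a
// typed site the copied allele is observed with per-site error lambda_ls
// (match 1 - lambda, mismatch lambda).  State posteriors at the scaffold are
// obtained by forward-backward with per-site rescaling; the allele posterior
// at an untyped site is the state-weighted panel allele, linearly
// interpolated in position between the flanking scaffold sites.
//
// The inner loops run over raw column pointers of the (column-major) panel
// matrix with a branch-free emission  e = lambda + (1 - 2*lambda) * match.

static void ls_one(const int* panel, int K,
                   const NumericVector& positions,
                   const std::vector<int>& sc,   // 0-based scaffold sites
                   const std::vector<int>& tg,   // target alleles at sc
                   const IntegerVector& out_idx, // 1-based output sites
                   double ne, double rec, double lambda_ls,
                   std::vector<double>& alpha,   // K*S work matrices
                   std::vector<double>& beta,
                   std::vector<double>& gamma,
                   double* out) {
  const int S = (int)sc.size();
  const int U = out_idx.size();

  if (S == 0) {
    // no typed sites: posterior is the panel allele frequency
    for (int u = 0; u < U; ++u) {
      const int* pc = panel + (size_t)(out_idx[u] - 1) * K;
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += pc[k];
      out[u] = s / K;
    }
    return;
  }

  alpha.resize((size_t)K * S);
  beta.resize((size_t)K * S);
  gamma.resize((size_t)K * S);
  std::vector<double> rho(S > 1 ? S - 1 : 0);
  for (int j = 0; j + 1 < S; ++j) {
    const double d = positions[sc[j + 1]] - positions[sc[j]];
    rho[j] = 1.0 - std::exp(-4.0 * ne * rec * d / K);
  }
  const double slope = 1.0 - 2.0 * lambda_ls;

  // forward, normalised to sum 1 at each site
  {
    const int* pc = panel + (size_t)sc[0] * K;
    const int t = tg[0];
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      const double e = lambda_ls + slope * (pc[k] == t);
      alpha[k] = e;
      tot += e;
    }
    const double inv = 1.0 / tot;
    for (int k = 0; k < K; ++k) alpha[k] *= inv;
  }
  for (int j = 1; j < S; ++j) {
    const int* pc = panel + (size_t)sc[j] * K;
    const int t = tg[j];
    const double stay = 1.0 - rho[j - 1];
    const double sw = rho[j - 1] / K;  // sum(alpha_{j-1}) == 1
    double* aj = &alpha[(size_t)K * j];
    const double* ap = &alpha[(size_t)K * (j - 1)];
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      const double e = lambda_ls + slope * (pc[k] == t);
      aj[k] = (stay * ap[k] + sw) * e;
      tot += aj[k];
    }
    const double inv = 1.0 / tot;
    for (int k = 0; k < K; ++k) aj[k] *= inv;
  }

  // backward, normalised to mean 1 at each site
  {
    double* bS = &beta[(size_t)K * (S - 1)];
    for (int k = 0; k < K; ++k) bS[k] = 1.0;
  }
  for (int j = S - 2; j >= 0; --j) {
    const int* pc = panel + (size_t)sc[j + 1] * K;
    const int t = tg[j + 1];
    const double stay = 1.0 - rho[j];
    double* bj = &beta[(size_t)K * j];
    const double* bn = &beta[(size_t)K * (j + 1)];
    double mean_eb = 0.0;
    for (int k = 0; k < K; ++k) {
      const double e = lambda_ls + slope * (pc[k] == t);
      const double eb = e * bn[k];
      bj[k] = eb;  // stash e*beta_{j+1}
      mean_eb += eb;
    }
    mean_eb /= K;
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      bj[k] = stay * bj[k] + rho[j] * mean_eb;
      tot += bj[k];
    }
    const double inv = K / tot;
    for (int k = 0; k < K; ++k) bj[k] *= inv;
  }

  // state posteriors at scaffold sites
  for (int j = 0; j < S; ++j) {
    double* gj = &gamma[(size_t)K * j];
    const double* aj = &alpha[(size_t)K * j];
    const double* bj = &beta[(size_t)K * j];
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      gj[k] = aj[k] * bj[k];
      tot += gj[k];
    }
    const double inv = 1.0 / tot;
    for (int k = 0; k < K; ++k) gj[k] *= inv;
  }

  // allele posteriors at requested sites, interpolating between flanks
  std::vector<double> spos(S);
  for (int j = 0; j < S; ++j) spos[j] = positions[sc[j]];
  for (int u = 0; u < U; ++u) {
    const int su = out_idx[u] - 1;
    const int* pc = panel + (size_t)su * K;
    const double pu = positions[su];
    int jr = std::lower_bound(spos.begin(), spos.end(), pu) - spos.begin();
    double val;
    if (jr <= 0 || jr >= S) {
      const double* gj = &gamma[(size_t)K * (jr <= 0 ? 0 : S - 1)];
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += gj[k] * pc[k];
      val = s;
    } else {
      const int jl = jr - 1;
      const double w = (spos[jr] > spos[jl])
                           ? (pu - spos[jl]) / (spos[jr] - spos[jl])
                           : 0.0;
      const double* gl = &gamma[(size_t)K * jl];
      const double* gr = &gamma[(size_t)K * jr];
      double sl = 0.0, sr = 0.0;
      for (int k = 0; k < K; ++k) {
        sl += gl[k] * pc[k];
        sr += gr[k] * pc[k];
      }
      val = (1.0 - w) * sl + w * sr;
    }
    out[u] = std::min(1.0, std::max(0.0, val));
  }
}

// Single-haplotype interface (scaffold_idx 1-based, increasing).
// [[Rcpp::export(name = ".ls_posteriors_cpp")]]
NumericVector ls_posteriors_cpp(IntegerMatrix panel,
                                NumericVector positions,
                                IntegerVector scaffold_idx,
                                IntegerVector target,
                                IntegerVector out_idx,
                                double ne,
                                double rec,
                                double lambda_ls) {
  const int K = panel.nrow();
  if (K < 1) stop("reference panel has no haplotypes");
  const int S = scaffold_idx.size();
  std::vector<int> sc(S), tg(S);
  for (int j = 0; j < S; ++j) {
    sc[j] = scaffold_idx[j] - 1;
    tg[j] = target[j];
  }
  NumericVector out(out_idx.size());
  std::vector<double> a, b, g;
  ls_one(INTEGER(panel), K, positions, sc, tg, out_idx, ne, rec,
         lambda_ls, a, b, g, REAL(out));
  return out;
}

// Batched interface: one row of `targets` per haplotype, giving allele
// calls at every scaffold site with NA_integer_ marking a missing call
// (that site is dropped from that haplotype's scaffold).  Returns a
// haplotypes x out-sites posterior matrix.
// [[Rcpp::export(name = ".ls_impute_cpp")]]
NumericMatrix ls_impute_cpp(IntegerMatrix panel,
                            NumericVector positions,
                            IntegerVector scaffold_idx,
                            IntegerMatrix targets,
                            IntegerVector out_idx,
                            double ne,
                            double rec,
                            double lambda_ls) {
  const int K = panel.nrow();
  if (K < 1) stop("reference panel has no haplotypes");
  const int n = targets.nrow();
  const int S = scaffold_idx.size();
  if (targets.ncol() != S)
    stop("targets must have one column per scaffold site");
  const int U = out_idx.size();
  NumericMatrix out(n, U);
  std::vector<double> buf(U);
  std::vector<double> a, b, g;
  std::vector<int> sc, tg;
  sc.reserve(S);
  tg.reserve(S);
  for (int i = 0; i < n; ++i) {
    sc.clear();
    tg.clear();
    for (int j = 0; j < S; ++j) {
      const int al = targets(i, j);
      if (al != NA_INTEGER) {
        sc.push_back(scaffold_idx[j] - 1);
        tg.push_back(al);
      }
    }
    ls_one(INTEGER(panel), K, positions, sc, tg, out_idx, ne, rec,
           lambda_ls, a, b, g, buf.data());
    for (int u = 0; u < U; ++u) out(i, u) = buf[u];
  }
  return out;
}
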