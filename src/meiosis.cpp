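#include <Rcpp.h>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// Gamete sampling for a whole batch of meioses.
//
// Haplotypes are stored site-major (one site per row, one line per column)
// as raw bytes, so each line's haplotype is a contiguous block and
// chromosome segments between crossovers can be copied wholesale.
//
// Crossovers follow the Haldane (no-interference) model: the crossover count
// on a chromosome of genetic length L Morgans is Poisson(L), crossover
// positions are uniform on [0, L], and the starting haplotype is chosen at
// random. Zero-crossover gametes are allowed (no obligate chiasma).
//
// Uses R's RNG stream so results are reproducible under set.seed().

// [[Rcpp::export]]
RawMatrix make_gametes_cpp(const RawMatrix& h1,
                           const RawMatrix& h2,
                           const IntegerVector& parent_idx,
                           const NumericVector& pos,
                           const double genetic_length) {
  const int n_sites = h1.nrow();
  const int n_gam = parent_idx.size();
  if (h2.nrow() != n_sites || h2.ncol() != h1.ncol())
    stop("haplotype matrices must have identical dimensions");
  if (pos.size() != n_sites)
    stop("locus position vector length must equal the number of sites");

  RawMatrix gam(n_sites, n_gam);
  const Rbyte* p1 = RAW(h1);
  const Rbyte* p2 = RAW(h2);
  const double* pp = REAL(pos);
  Rbyte* out_base = RAW(gam);
  std::vector<double> xo;

  for (int g = 0; g < n_gam; ++g) {
    const int p = parent_idx[g] - 1;  // 1-based from R
    if (p < 0 || p >= h1.ncol()) stop("parent index out of range");
    const Rbyte* hap[2] = {p1 + static_cast<size_t>(p) * n_sites,
                           p2 + static_cast<size_t>(p) * n_sites};
    Rbyte* out = out_base + static_cast<size_t>(g) * n_sites;

    const int k = static_cast<int>(R::rpois(genetic_length));
    int phase = (unif_rand() < 0.5) ? 0 : 1;

    if (k == 0) {
      std::memcpy(out, hap[phase], n_sites);
      continue;
    }

    xo.resize(k);
    for (int i = 0; i < k; ++i) xo[i] = unif_rand() * genetic_length;
    std::sort(xo.begin(), xo.end());

    int j0 = 0;
    for (int i = 0; i < k; ++i) {
      // first site at or beyond this crossover ends the current segment
      const int j1 = static_cast<int>(
        std::lower_bound(pp + j0, pp + n_sites, xo[i]) - pp);
      if (j1 > j0) std::memcpy(out + j0, hap[phase] + j0, j1 - j0);
      phase ^= 1;
      j0 = j1;
    }
    if (j0 < n_sites) std::memcpy(out + j0, hap[phase] + j0, n_sites - j0);
  }
  return gam;
}

// Additive genetic values of every line: sum over QTL of dosage x effect.
// Each line's haplotype is contiguous, so the per-line QTL gather stays in
// cache.

// [[Rcpp::export]]
NumericVector gv_lines_cpp(const RawMatrix& h1,
                           const RawMatrix& h2,
                           const IntegerVector& qtl,
                           const NumericVector& effects) {
  const int n_sites = h1.nrow();
  const int n = h1.ncol();
  const int n_qtl = qtl.size();
  if (effects.size() != n_qtl)
    stop("effects must be one per QTL");
  const Rbyte* p1 = RAW(h1);
  const Rbyte* p2 = RAW(h2);

  std::vector<int> q(n_qtl);
  for (int i = 0; i < n_qtl; ++i) {
    q[i] = qtl[i] - 1;
    if (q[i] < 0 || q[i] >= n_sites) stop("QTL index out of range");
  }

  NumericVector out(n);
  const double* ef = REAL(effects);
  const int* qi = q.data();
  const int tail = n_qtl - (n_qtl % 4);
  for (int l = 0; l < n; ++l) {
    const Rbyte* c1 = p1 + static_cast<size_t>(l) * n_sites;
    const Rbyte* c2 = p2 + static_cast<size_t>(l) * n_sites;
    // four accumulators break the floating-point add dependency chain
    double s0 = 0.0, s1 = 0.0, s2 = 0.0, s3 = 0.0;
    int i = 0;
    for (; i < tail; i += 4) {
      s0 += ef[i]     * (c1[qi[i]]     + c2[qi[i]]);
      s1 += ef[i + 1] * (c1[qi[i + 1]] + c2[qi[i + 1]]);
      s2 += ef[i + 2] * (c1[qi[i + 2]] + c2[qi[i + 2]]);
      s3 += ef[i + 3] * (c1[qi[i + 3]] + c2[qi[i + 3]]);
    }
    for (; i < n_qtl; ++i) s0 += ef[i] * (c1[qi[i]] + c2[qi[i]]);
    out[l] = (s0 + s1) + (s2 + s3);
  }
  return out;
}
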