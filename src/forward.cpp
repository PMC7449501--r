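// Divide-and-conquer forward pass over ancestral-configuration states.
//
// The transition matrix factorizes over the 2^(K+1)-1 bits of the
// state (phase bit, founder-ancestry bits, recombination bits), each
// bit moving independently with its own 2x2 kernel. Applying the
// matrix to a probability vector therefore needs only one 2x2 sweep
// per bit: O(N log N) scalar multiply-adds instead of the dense
// O(N^2) product.
//
// Bit layout (most significant first): [P | C_1..C_m | R_1..R_{m-2}],
// m = 2^K founders. Bit k (0-based from the MSB) has stride
// N / 2^(k+1) in the packed index.

#include <Rcpp.h>
using namespace Rcpp;

static inline double clamp_switch(double x, double cap) {
  return x > cap ? cap : x;
}

// One T * v product. t01[k], t10[k]: switch probabilities of bit k
// (0->1 and 1->0), bits ordered MSB-first as in the packed index.
static void dc_apply(std::vector<double> &v, const std::vector<double> &t01,
                     const std::vector<double> &t10) {
  const int b = (int)t01.size();
  const R_xlen_t N = (R_xlen_t)v.size();
  for (int k = 0; k < b; ++k) {
    const R_xlen_t stride = N >> (k + 1);
    const double a01 = t01[k], a10 = t10[k];
    const double a00 = 1.0 - a01, a11 = 1.0 - a10;
    for (R_xlen_t base = 0; base < N; base += 2 * stride) {
      double *lo = &v[base];
      double *hi = &v[base + stride];
      for (R_xlen_t j = 0; j < stride; ++j) {
        const double x0 = lo[j], x1 = hi[j];
        lo[j] = a00 * x0 + a10 * x1;
        hi[j] = a01 * x0 + a11 * x1;
      }
    }
  }
}

// Build the per-bit switch probabilities for one inter-site interval.
static void site_kernels(double d, double recp, const NumericVector &rateAB,
                         const NumericVector &rateBA, double pp, double cap,
                         std::vector<double> &t01, std::vector<double> &t10) {
  const int m = rateAB.size();          // 2^K founders
  const int b = 2 * m - 1;              // total bits
  t01.resize(b); t10.resize(b);
  t01[0] = t10[0] = clamp_switch(d * pp, cap);          // phase bit
  for (int j = 0; j < m; ++j) {                         // founder bits
    t01[1 + j] = clamp_switch(d * rateAB[j], cap);      // A -> B
    t10[1 + j] = clamp_switch(d * rateBA[j], cap);      // B -> A
  }
  for (int k = m + 1; k < b; ++k) t01[k] = t10[k] = recp; // R bits
}

// [[Rcpp::export]]
NumericVector dc_forward_step_cpp(NumericVector prev, double d, double recp,
                                  NumericVector rateAB, NumericVector rateBA,
                                  double pp, double cap) {
  std::vector<double> v(prev.begin(), prev.end());
  std::vector<double> t01, t10;
  site_kernels(d, recp, rateAB, rateBA, pp, cap, t01, t10);
  dc_apply(v, t01, t10);
  return NumericVector(v.begin(), v.end());
}

// Generic Kronecker-structured matrix-vector product given explicit
// per-bit kernels (used for unit-testing the bipartition step alone).
// [[Rcpp::export]]
NumericVector dc_matvec_cpp(NumericVector prev, NumericVector t01,
                            NumericVector t10) {
  std::vector<double> v(prev.begin(), prev.end());
  std::vector<double> a01(t01.begin(), t01.end());
  std::vector<double> a10(t10.begin(), t10.end());
  if ((R_xlen_t)1 << a01.size() != prev.size())
    stop("length(prev) must equal 2^length(t01)");
  dc_apply(v, a01, a10);
  return NumericVector(v.begin(), v.end());
}

// Scaled forward pass over one chromosome. Returns the chromosome
// log-likelihood. h1/h2: observed alleles (0/1) per site; gap: bp to
// the previous site (gap[0] unused); recp: inter-site recombination
// probability (recp[0] unused); tab1/tab2: founder index (1-based)
// routed to H1/H2 for each packed (P, R) combination.
// [[Rcpp::export]]
double forward_loglik_chrom_cpp(IntegerVector h1, IntegerVector h2,
                                NumericVector gap, NumericVector recp,
                                NumericVector freqA, NumericVector freqB,
                                NumericVector rateAB, NumericVector rateBA,
                                double pp, double cap, NumericVector init,
                                IntegerVector tab1, IntegerVector tab2) {
  const int n = h1.size();
  const int m = rateAB.size();
  const int b = 2 * m - 1;
  const R_xlen_t N = (R_xlen_t)1 << b;
  const int nR = m - 2;
  const R_xlen_t Rmask = ((R_xlen_t)1 << nR) - 1;
  if (init.size() != N) stop("init has wrong length");

  std::vector<double> v(init.begin(), init.end());
  std::vector<double> t01, t10;
  double loglik = 0.0;

  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      site_kernels(gap[i], recp[i], rateAB, rateBA, pp, cap, t01, t10);
      dc_apply(v, t01, t10);
    }
    // emission: per-haplotype allele frequency lookup
    const double e1A = h1[i] ? freqA[i] : 1.0 - freqA[i];
    const double e1B = h1[i] ? freqB[i] : 1.0 - freqB[i];
    const double e2A = h2[i] ? freqA[i] : 1.0 - freqA[i];
    const double e2B = h2[i] ? freqB[i] : 1.0 - freqB[i];
    double total = 0.0;
    for (R_xlen_t s = 0; s < N; ++s) {
      const int P = (int)((s >> (b - 1)) & 1);
      const R_xlen_t pr = ((R_xlen_t)P << nR) | (s & Rmask);
      const int j1 = tab1[pr];          // 1-based founder index
      const int j2 = tab2[pr];
      const int c1 = (int)((s >> (b - 1 - j1)) & 1);
      const int c2 = (int)((s >> (b - 1 - j2)) & 1);
      const double e = (c1 ? e1B : e1A) * (c2 ? e2B : e2A);
      v[s] *= e;
      total += v[s];
    }
    if (!(total > 0.0) || !R_finite(total)) return R_NegInf;
    const double inv = 1.0 / total;
    for (R_xlen_t s = 0; s < N; ++s) v[s] *= inv;
    loglik += std::log(total);
  }
  return loglik;
}
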