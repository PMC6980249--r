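#include <Rcpp.h>
#include <random>
#include <vector>

// Forward Wright-Fisher simulation of deleterious mutations at independent
// loci.  Each new mutation draws a selection coefficient magnitude from a
// gamma DFE (in rescaled units) and its derived-allele frequency trajectory
// is propagated by binomial sampling with genic selection (h = 0.5) through
// a piecewise population-size history.  Mutations stronger than `s_cap`
// (not representable at the rescaled population size) are skipped here and
// handled analytically by the R wrapper via mutation-selection balance.
//
// n_traj: diploid population size per forward generation (element 1 = most
//         ancient, last = present).
// mu_locus: per-chromosome per-generation mutation rate over the whole
//         locus (rescaled units).
// Returns, pooled over loci, the rescaled selection coefficients and the
// derived allele counts from binomial sampling of n_chrom_out chromosomes
// at the final generation (monomorphic outcomes dropped).

struct Mut {
  double s;   // rescaled selection magnitude
  int k;      // derived copies in the current generation
};

// [[Rcpp::export(name = ".wf_fitness_core")]]
Rcpp::List wf_fitness_core(Rcpp::IntegerVector n_traj, double mu_locus,
                           int n_loci, double gamma_shape,
                           double gamma_scale, double s_cap,
                           int n_chrom_out, int seed) {
  std::vector<double> out_s;
  std::vector<int> out_c;
  const int T = n_traj.size();

  for (int locus = 0; locus < n_loci; ++locus) {
    std::mt19937_64 rng(static_cast<uint64_t>(seed) * 2654435761ULL +
                        locus + 1);
    std::gamma_distribution<double> rgam(gamma_shape, gamma_scale);
    std::vector<Mut> active;
    active.reserve(4096);

    for (int g = 0; g < T; ++g) {
      const int N_prev = (g == 0) ? n_traj[0] : n_traj[g - 1];
      const int N_cur = n_traj[g];
      const double two_n_prev = 2.0 * N_prev;
      const int two_n_cur = 2 * N_cur;

      // propagate existing mutations
      std::size_t keep = 0;
      for (std::size_t i = 0; i < active.size(); ++i) {
        const double p = active[i].k / two_n_prev;
        const double sm = active[i].s;
        double pp = p * (1.0 - sm * (1.0 + p) / 2.0) / (1.0 - sm * p);
        if (pp < 0.0) pp = 0.0;
        if (pp > 1.0) pp = 1.0;
        std::binomial_distribution<int> rbin(two_n_cur, pp);
        const int k = rbin(rng);
        if (k > 0 && k < two_n_cur) {
          active[keep].s = sm;
          active[keep].k = k;
          ++keep;
        }
      }
      active.resize(keep);

      // new mutations this generation
      std::poisson_distribution<int> rpois(two_n_cur * mu_locus);
      const int n_new = rpois(rng);
      for (int j = 0; j < n_new; ++j) {
        const double s = rgam(rng);
        if (s > s_cap) continue;  // strong tail handled analytically
        if (two_n_cur > 1) active.push_back({s, 1});
      }
    }

    // binomial projection of final population frequencies to the sample
    const double two_n_final = 2.0 * n_traj[T - 1];
    for (std::size_t i = 0; i < active.size(); ++i) {
      std::binomial_distribution<int> rbin(n_chrom_out,
                                           active[i].k / two_n_final);
      const int c = rbin(rng);
      if (c > 0 && c < n_chrom_out) {
        out_s.push_back(active[i].s);
        out_c.push_back(c);
      }
    }
  }

  return Rcpp::List::create(Rcpp::Named("s") = Rcpp::wrap(out_s),
                            Rcpp::Named("count") = Rcpp::wrap(out_c));
}
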