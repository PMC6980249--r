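#include <Rcpp.h>
#include <vector>

// Haplotype-copying (Li-Stephens) imputation.  Each target haplotype is
// modelled as an imperfect mosaic of reference haplotypes: a hidden copying
// path over a per-target subset of the reference panel, with a constant
// per-bp switch rate and a symmetric allele-mismatch rate at typed sites.
// Posterior copying probabilities are obtained by forward-backward over the
// typed sites; at untyped sites the posterior is propagated into the
// flanking intervals (no emission), and the expected reference allele under
// the posterior gives the per-haplotype dosage.
//
// ref:       n_ref_hap x S matrix of reference alleles at all sites.
// obs:       n_target_hap x T matrix of observed alleles at typed sites.
// typed_idx: 1-based column indices of the typed sites within 1..S.
// states:    n_states x n_target_hap, 1-based rows of `ref` to use per
//            target haplotype.
// pos:       site positions (bp), length S.
// Returns an n_target_hap x S matrix of per-haplotype expected dosages.

// [[Rcpp::export(name = ".ls_impute_core")]]
Rcpp::NumericMatrix ls_impute_core(Rcpp::IntegerMatrix ref,
                                   Rcpp::IntegerMatrix obs,
                                   Rcpp::IntegerVector typed_idx,
                                   Rcpp::IntegerMatrix states,
                                   Rcpp::NumericVector pos,
                                   double r_sw, double eps) {
  const int S = ref.ncol();
  const int T = typed_idx.size();
  const int K = states.nrow();
  const int n_tgt = obs.nrow();
  Rcpp::NumericMatrix dos(n_tgt, S);

  std::vector<double> alpha(static_cast<size_t>(K) * T);
  std::vector<double> bt(static_cast<size_t>(K) * T);  // e_t * beta_t
  std::vector<double> beta(K), tmp(K);

  auto theta = [&](double d) { return 1.0 - std::exp(-r_sw * d); };

  for (int h = 0; h < n_tgt; ++h) {
    // forward over typed sites
    for (int t = 0; t < T; ++t) {
      const int site = typed_idx[t] - 1;
      double sum = 0.0;
      for (int k = 0; k < K; ++k) {
        const int rk = states(k, h) - 1;
        const double e =
            (ref(rk, site) == obs(h, t)) ? 1.0 - eps : eps;
        double prev;
        if (t == 0) {
          prev = 1.0 / K;
        } else {
          const double th = theta(pos[site] - pos[typed_idx[t - 1] - 1]);
          prev = (1.0 - th) * alpha[(t - 1) * K + k] + th / K;
        }
        alpha[t * K + k] = prev * e;
        sum += alpha[t * K + k];
      }
      for (int k = 0; k < K; ++k) alpha[t * K + k] /= sum;
    }

    // backward, storing e_t * beta_t
    for (int t = T - 1; t >= 0; --t) {
      const int site = typed_idx[t] - 1;
      if (t == T - 1) {
        std::fill(beta.begin(), beta.end(), 1.0);
      } else {
        const double th = theta(pos[typed_idx[t + 1] - 1] - pos[site]);
        double mean_bt = 0.0;
        for (int k = 0; k < K; ++k) mean_bt += bt[(t + 1) * K + k];
        mean_bt /= K;
        for (int k = 0; k < K; ++k) {
          beta[k] = (1.0 - th) * bt[(t + 1) * K + k] + th * mean_bt;
        }
      }
      double sum = 0.0;
      for (int k = 0; k < K; ++k) {
        const int rk = states(k, h) - 1;
        const double e =
            (ref(rk, site) == obs(h, t)) ? 1.0 - eps : eps;
        bt[t * K + k] = e * beta[k];
        sum += bt[t * K + k];
      }
      for (int k = 0; k < K; ++k) bt[t * K + k] /= sum;  // rescale only
    }

    // posterior dosage at every site
    int t_right = 0;  // first typed site with index >= current site
    for (int s = 0; s < S; ++s) {
      while (t_right < T && typed_idx[t_right] - 1 < s) ++t_right;
      if (t_right < T && typed_idx[t_right] - 1 == s) {
        dos(h, s) = obs(h, t_right);  // typed passthrough
        continue;
      }
      double sum = 0.0, d = 0.0;
      if (t_right == 0) {
        const double th = theta(pos[typed_idx[0] - 1] - pos[s]);
        double mean_bt = 0.0;
        for (int k = 0; k < K; ++k) mean_bt += bt[k];
        mean_bt /= K;
        for (int k = 0; k < K; ++k) {
          tmp[k] = (1.0 - th) * bt[k] + th * mean_bt;
        }
      } else if (t_right == T) {
        const double th = theta(pos[s] - pos[typed_idx[T - 1] - 1]);
        for (int k = 0; k < K; ++k) {
          tmp[k] = (1.0 - th) * alpha[(T - 1) * K + k] + th / K;
        }
      } else {
        const double th1 = theta(pos[s] - pos[typed_idx[t_right - 1] - 1]);
        const double th2 = theta(pos[typed_idx[t_right] - 1] - pos[s]);
        double mean_bt = 0.0;
        for (int k = 0; k < K; ++k) mean_bt += bt[t_right * K + k];
        mean_bt /= K;
        for (int k = 0; k < K; ++k) {
          const double f =
              (1.0 - th1) * alpha[(t_right - 1) * K + k] + th1 / K;
          const double g =
              (1.0 - th2) * bt[t_right * K + k] + th2 * mean_bt;
          tmp[k] = f * g;
        }
      }
      for (int k = 0; k < K; ++k) sum += tmp[k];
      for (int k = 0; k < K; ++k) {
        d += tmp[k] / sum * ref(states(k, h) - 1, s);
      }
      dos(h, s) = d;
    }
  }
  return dos;
}
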