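#include <Rcpp.h>
#include <random>
#include <vector>

// KBAC permutation engine.  Individuals arrive ordered with carriers of a
// non-null rare genotype pattern first (pattern id > 0); `pat` is 0 for
// the null (all-reference) pattern.  The statistic weights each pattern by
// the hypergeometric lower-tail probability of its case count and sums the
// weighted case-minus-control pattern frequency differences.  Permutation
// of the phenotype only needs the labels landing on carrier slots, so a
// partial Fisher-Yates shuffle of the first n_carrier entries suffices.

static double kbac_stat(const std::vector<int>& pat_count,
                        const std::vector<int>& case_count,
                        double n_case, double n_ctrl, bool two_sided) {
  double stat = 0.0;
  for (std::size_t g = 0; g < pat_count.size(); ++g) {
    const double a = case_count[g];
    const double ng = pat_count[g];
    const double w = R::phyper(a, n_case, n_ctrl, ng, 1, 0);
    stat += w * (a / n_case - (ng - a) / n_ctrl);
  }
  return two_sided ? std::fabs(stat) : stat;
}

// [[Rcpp::export(name = ".kbac_perm_core")]]
Rcpp::List kbac_perm_core(Rcpp::IntegerVector pat, Rcpp::IntegerVector y,
                          int max_perm, double alpha_stop, bool two_sided,
                          int seed) {
  const int n = pat.size();
  int n_carrier = 0;
  while (n_carrier < n && pat[n_carrier] > 0) ++n_carrier;
  int n_pat = 0;
  for (int i = 0; i < n_carrier; ++i) n_pat = std::max(n_pat, pat[i]);

  double n_case = 0.0;
  for (int i = 0; i < n; ++i) n_case += y[i];
  const double n_ctrl = n - n_case;

  std::vector<int> pat_count(n_pat, 0), case_count(n_pat, 0);
  for (int i = 0; i < n_carrier; ++i) {
    ++pat_count[pat[i] - 1];
    if (y[i] == 1) ++case_count[pat[i] - 1];
  }
  const double obs = kbac_stat(pat_count, case_count, n_case, n_ctrl,
                               two_sided);

  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL
                      + 1442695040888963407ULL);
  std::vector<int> yy(y.begin(), y.end());
  long hits = 0, done = 0;
  int batch = 1000;
  const double zcrit = 2.5758;  // 99% CI for the early-stopping rule

  while (done < max_perm) {
    batch = std::min<long>(batch, max_perm - done);
    for (int b = 0; b < batch; ++b) {
      // partial Fisher-Yates: uniform labels on the carrier slots
      for (int i = 0; i < n_carrier; ++i) {
        std::uniform_int_distribution<int> pick(i, n - 1);
        std::swap(yy[i], yy[pick(rng)]);
      }
      std::fill(case_count.begin(), case_count.end(), 0);
      for (int i = 0; i < n_carrier; ++i) {
        if (yy[i] == 1) ++case_count[pat[i] - 1];
      }
      if (kbac_stat(pat_count, case_count, n_case, n_ctrl, two_sided) >=
          obs - 1e-12) {
        ++hits;
      }
    }
    done += batch;
    const double phat = (1.0 + hits) / (1.0 + done);
    const double se = std::sqrt(phat * (1.0 - phat) / done);
    // alpha_stop <= 0 disables adaptive early stopping (full max_perm)
    if (alpha_stop > 0 &&
        (phat - zcrit * se > alpha_stop || phat + zcrit * se < alpha_stop)) {
      break;
    }
    batch = std::min(batch * 10, 1000000);
  }

  return Rcpp::List::create(
      Rcpp::Named("p") = (1.0 + hits) / (1.0 + done),
      Rcpp::Named("n_perm") = static_cast<double>(done),
      Rcpp::Named("stat") = obs);
}
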