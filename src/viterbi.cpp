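#include <Rcpp.h>
using namespace Rcpp;

// Genotype cluster means on the BAF axis for copy numbers 0..4.
// Copy 0 has no genotype signal: BAF is modelled uniform on [0,1].
static const double CL1[] = {0.0, 1.0};
static const double CL2[] = {0.0, 0.5, 1.0};
static const double CL3[] = {0.0, 1.0 / 3.0, 2.0 / 3.0, 1.0};
static const double CL4[] = {0.0, 0.25, 0.5, 0.75, 1.0};

static double baf_logdens(double b, int state, double sd) {
  if (state == 0) return 0.0; // uniform on [0,1]
  const double *cl;
  int k;
  switch (state) {
  case 1: cl = CL1; k = 2; break;
  case 2: cl = CL2; k = 3; break;
  case 3: cl = CL3; k = 4; break;
  default: cl = CL4; k = 5; break;
  }
  double dens = 0.0;
  for (int j = 0; j < k; ++j)
    dens += R::dnorm(b, cl[j], sd, 0);
  return std::log(dens / k);
}

// Per-probe log-emission for the five copy-number states.  Missing LRR or
// BAF contributes nothing (log 1), so masked probes stay on the path
// without informing it.
// [[Rcpp::export]]
NumericMatrix cnv_log_emissions(NumericVector lrr, NumericVector baf,
                                NumericVector lrr_means, NumericVector lrr_sds,
                                double baf_sd) {
  int n = lrr.size();
  NumericMatrix em(n, 5);
  for (int i = 0; i < n; ++i) {
    for (int s = 0; s < 5; ++s) {
      double le = 0.0;
      if (!NumericVector::is_na(lrr[i]))
        le += R::dnorm(lrr[i], lrr_means[s], lrr_sds[s], 1);
      if (!NumericVector::is_na(baf[i]))
        le += baf_logdens(baf[i], s, baf_sd);
      em(i, s) = le;
    }
  }
  return em;
}

// Viterbi decoding over the 5 copy-number states with distance-dependent
// transitions: stay probability 1 - p_event * (1 - exp(-d / dist_scale)),
// remaining mass split evenly over the four other states.  Initial state
// distribution: diploid with probability 1 - p_event, p_event/4 otherwise.
// [[Rcpp::export]]
List viterbi_cnv(NumericVector lrr, NumericVector baf, NumericVector pos,
                 NumericVector lrr_means, NumericVector lrr_sds,
                 double baf_sd, double p_event, double dist_scale) {
  int n = lrr.size();
  NumericMatrix em = cnv_log_emissions(lrr, baf, lrr_means, lrr_sds, baf_sd);
  NumericMatrix delta(n, 5);
  IntegerMatrix psi(n, 5);
  for (int s = 0; s < 5; ++s) {
    double lp = (s == 2) ? std::log(1.0 - p_event) : std::log(p_event / 4.0);
    delta(0, s) = lp + em(0, s);
  }
  for (int i = 1; i < n; ++i) {
    double d = pos[i] - pos[i - 1];
    double theta = p_event * (1.0 - std::exp(-d / dist_scale));
    double lstay = std::log(1.0 - theta);
    double lmove = std::log(theta / 4.0);
    for (int s = 0; s < 5; ++s) {
      double best = R_NegInf;
      int arg = 0;
      for (int r = 0; r < 5; ++r) {
        double cand = delta(i - 1, r) + (r == s ? lstay : lmove);
        if (cand > best) { best = cand; arg = r; }
      }
      delta(i, s) = best + em(i, s);
      psi(i, s) = arg;
    }
  }
  IntegerVector path(n);
  double best = R_NegInf;
  int arg = 0;
  for (int s = 0; s < 5; ++s)
    if (delta(n - 1, s) > best) { best = delta(n - 1, s); arg = s; }
  path[n - 1] = arg;
  for (int i = n - 1; i > 0; --i)
    path[i - 1] = psi(i, path[i]);
  return List::create(_["states"] = path, _["logemit"] = em,
                      _["loglik"] = best);
}
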