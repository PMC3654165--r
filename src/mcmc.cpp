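#include <Rcpp.h>
using namespace Rcpp;

// Pairwise retention log-likelihood with sufficient statistics:
// cognate words contribute -(t/1e4) * sum(rates); non-cognate words
// log(1 - exp(-r t / 1e4)) each.
static double pair_ll(double t, double sum_rc, const NumericVector& rn) {
  double ll = -(t / 1e4) * sum_rc;
  for (int i = 0; i < rn.size(); ++i) {
    double x = rn[i] * t / 1e4;
    if (x <= 0.0) return R_NegInf;
    ll += std::log(-std::expm1(-x));
  }
  return ll;
}

// Prior encoding: {family, par1, par2, lo, hi}; family 0 flat, 1 uniform,
// 2 normal (support lo/hi from the R side).
static double prior_ld(const NumericVector& p, double x) {
  if (x < p[3] || x > p[4]) return R_NegInf;
  int fam = (int)p[0];
  if (fam == 0) return 0.0;
  if (fam == 1) return -std::log(p[2] - p[1]);
  return R::dnorm(x, p[1], p[2], 1);
}

static double log_post(double homer, double hittite, double root,
                       double sum_rc_hh, const NumericVector& rn_hh,
                       double sum_rc_hm, const NumericVector& rn_hm,
                       double sum_rc_om, const NumericVector& rn_om,
                       const NumericVector& pr_h, const NumericVector& pr_t,
                       const NumericVector& pr_r, bool use_lik) {
  if (!(homer >= 0.0 && homer < root && hittite > 0.0 && hittite < root))
    return R_NegInf;
  double lp = prior_ld(pr_h, homer) + prior_ld(pr_t, hittite) + prior_ld(pr_r, root);
  if (!R_finite(lp)) return R_NegInf;
  if (use_lik) {
    double t_hh = (root - hittite) + (root - homer);
    double t_hm = (root - hittite) + root;
    double t_om = homer;
    lp += pair_ll(t_hh, sum_rc_hh, rn_hh);
    lp += pair_ll(t_hm, sum_rc_hm, rn_hm);
    lp += pair_ll(t_om, sum_rc_om, rn_om);
  }
  return lp;
}

// Componentwise Metropolis-Hastings with symmetric normal proposals and a
// pre-burn-in adaptation phase targeting 20-40% acceptance. Uses R's RNG,
// so determinism follows from set.seed() on the R side.
// [[Rcpp::export(name = ".mh_chain")]]
List mh_chain(NumericVector init,
              double sum_rc_hh, NumericVector rn_hh,
              double sum_rc_hm, NumericVector rn_hm,
              double sum_rc_om, NumericVector rn_om,
              NumericVector pr_h, NumericVector pr_t, NumericVector pr_r,
              int n_iter, int n_burn, int thin,
              NumericVector prop_sd, bool use_lik) {
  double par[3] = { init[0], init[1], init[2] };
  double sd[3] = { prop_sd[0], prop_sd[1], prop_sd[2] };
  double lp = log_post(par[0], par[1], par[2],
                       sum_rc_hh, rn_hh, sum_rc_hm, rn_hm, sum_rc_om, rn_om,
                       pr_h, pr_t, pr_r, use_lik);
  if (!R_finite(lp)) stop("initial state has zero posterior density");

  int n_keep = (n_iter - n_burn) / thin;
  NumericMatrix out(n_keep, 4);
  IntegerVector kept_iter(n_keep);
  double acc[3] = {0, 0, 0}, tries[3] = {0, 0, 0};
  // adaptation bookkeeping (first half of burn-in only)
  int adapt_until = n_burn / 2, window = 200;
  double w_acc[3] = {0, 0, 0}, w_try[3] = {0, 0, 0};

  int k = 0;
  for (int it = 1; it <= n_iter; ++it) {
    for (int j = 0; j < 3; ++j) {
      double prop[3] = { par[0], par[1], par[2] };
      prop[j] += R::rnorm(0.0, sd[j]);
      double lp_new = log_post(prop[0], prop[1], prop[2],
                               sum_rc_hh, rn_hh, sum_rc_hm, rn_hm,
                               sum_rc_om, rn_om, pr_h, pr_t, pr_r, use_lik);
      bool ok = R_finite(lp_new) &&
        (lp_new >= lp || std::log(R::runif(0.0, 1.0)) < lp_new - lp);
      if (ok) { par[j] = prop[j]; lp = lp_new; }
      if (it > n_burn) { tries[j] += 1; acc[j] += ok ? 1 : 0; }
      if (it <= adapt_until) {
        w_try[j] += 1; w_acc[j] += ok ? 1 : 0;
        if (w_try[j] >= window) {
          double r = w_acc[j] / w_try[j];
          if (r > 0.4) sd[j] *= 1.4;
          else if (r < 0.2) sd[j] *= 0.7;
          w_try[j] = 0; w_acc[j] = 0;
        }
      }
    }
    if (it > n_burn && (it - n_burn) % thin == 0 && k < n_keep) {
      out(k, 0) = par[0]; out(k, 1) = par[1]; out(k, 2) = par[2];
      out(k, 3) = lp;
      kept_iter[k] = it;
      ++k;
    }
  }
  NumericVector acc_rate(3), final_sd(3);
  for (int j = 0; j < 3; ++j) {
    acc_rate[j] = tries[j] > 0 ? acc[j] / tries[j] : NA_REAL;
    final_sd[j] = sd[j];
  }
  return List::create(_["samples"] = out, _["iteration"] = kept_iter,
                      _["acceptance"] = acc_rate, _["proposal_sd"] = final_sd);
}
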