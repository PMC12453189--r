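#include <Rcpp.h>
using namespace Rcpp;

// Marginal Cormack-Jolly-Seber likelihood for population persistence.
//
// For each population i the latent state z[i, t] (extant/extirpated) is
// monotone non-increasing with z[i, 1] = 1, so the full latent history is
// indexed by the extirpation time tau in {2, ..., T + 1} (tau = T + 1 means
// the population survived the whole period).  Writing k = tau - 1 for the
// last extant year and L_i for the index of the last detection, the exact
// marginal likelihood is
//
//   L_i = sum_{k = L_i}^{T} phi_i^(k-1) * (1 - phi_i)^[k < T]
//            * prod_{t <= k} p_it^y_it (1 - p_it)^(1 - y_it)
//
// with phi_i the annual persistence probability (logit-linear in the three
// spatial covariates with an ecoregion intercept) and p_it the detection
// probability (logit-linear in calendar year and scaled search effort).
// Detection factors for years after extirpation are certain (y = 0) and
// drop out.  The persistence posterior at fixed parameters is the k = T
// term divided by L_i.  Everything is accumulated in log space.

// [[Rcpp::export]]
List cjs_eval_cpp(NumericVector alpha, double beta_hs, double beta_rain,
                  double beta_imp, double gamma0, double beta_trend,
                  double beta_effort, NumericMatrix X, IntegerVector eco,
                  IntegerMatrix y, NumericMatrix e, IntegerVector L,
                  NumericVector tcov, bool want_persist) {
  int N = y.nrow(), T = y.ncol();
  NumericVector ll(N), persist(N);
  std::vector<double> lt(T);
  double total = 0.0;
  for (int i = 0; i < N; ++i) {
    double eta = alpha[eco[i] - 1] + beta_hs * X(i, 0) +
                 beta_rain * X(i, 1) + beta_imp * X(i, 2);
    double logphi = -R::log1pexp(-eta);
    double log1mphi = -R::log1pexp(eta);
    int Li = L[i];
    if (Li < 1) Li = 1;
    if (Li > T) Li = T;
    double cum = 0.0, m = R_NegInf;
    for (int k = 1; k <= T; ++k) {
      double etad = gamma0 + beta_trend * tcov[k - 1] + beta_effort * e(i, k - 1);
      cum += (y(i, k - 1) == 1) ? -R::log1pexp(-etad) : -R::log1pexp(etad);
      if (k >= Li) {
        double v = (k - 1) * logphi + (k < T ? log1mphi : 0.0) + cum;
        lt[k - 1] = v;
        if (v > m) m = v;
      }
    }
    double s = 0.0;
    for (int k = Li; k <= T; ++k) s += std::exp(lt[k - 1] - m);
    double li = m + std::log(s);
    ll[i] = li;
    total += li;
    if (want_persist) persist[i] = std::exp(lt[T - 1] - li);
  }
  List out = List::create(_["loglik"] = total, _["loglik_pop"] = ll);
  if (want_persist) out["persist"] = persist;
  return out;
}

// Full adaptive Metropolis-within-Gibbs chain for the marginalized model.
//
// Parameter layout: theta = (alpha_1..alpha_R, beta_hs, beta_rain,
// beta_imp, gamma0, beta_trend, beta_effort).  The sweep exploits the
// likelihood factorization: persistence parameters leave the cumulative
// detection terms (cumld) untouched, and an ecoregion intercept only
// touches the populations of that ecoregion, so each single-parameter
// update recomputes the minimum necessary.  Proposal scales adapt in
// batches of 50 iterations during burn-in toward `target_acc`, then stay
// fixed.  Uses R's RNG, so set.seed() in R makes chains reproducible.

static double popll_from_cumld(const double* cumld_i, double logphi,
                               double log1mphi, int Li, int T,
                               std::vector<double>& scratch) {
  double m = R_NegInf;
  for (int k = Li; k <= T; ++k) {
    double v = (k - 1) * logphi + (k < T ? log1mphi : 0.0) + cumld_i[k - 1];
    scratch[k - 1] = v;
    if (v > m) m = v;
  }
  double s = 0.0;
  for (int k = Li; k <= T; ++k) s += std::exp(scratch[k - 1] - m);
  return m + std::log(s);
}

// [[Rcpp::export]]
List cjs_mwg_cpp(NumericVector theta0, NumericMatrix X, IntegerVector eco,
                 IntegerMatrix y, NumericMatrix e, IntegerVector L,
                 NumericVector tcov, double prior_sd, int iterations,
                 int burn_in, int thin, NumericVector scales0,
                 double target_acc) {
  int N = y.nrow(), T = y.ncol();
  int R = theta0.size() - 6;
  int K = theta0.size();
  std::vector<double> theta(theta0.begin(), theta0.end());
  std::vector<double> scales(scales0.begin(), scales0.end());
  std::vector<int> Li(N);
  for (int i = 0; i < N; ++i) {
    int l = L[i];
    Li[i] = l < 1 ? 1 : (l > T ? T : l);
  }
  std::vector<double> cumld(std::max(1, N) * T), cumld_new(std::max(1, N) * T);
  std::vector<double> logphi(N), log1mphi(N), eta(N);
  std::vector<double> llpop(N), llpop_new(N), scratch(std::max(1, T));

  auto set_phi = [&](int i) {
    double et = theta[eco[i] - 1] + theta[R] * X(i, 0) +
                theta[R + 1] * X(i, 1) + theta[R + 2] * X(i, 2);
    eta[i] = et;
    logphi[i] = -R::log1pexp(-et);
    log1mphi[i] = -R::log1pexp(et);
  };
  auto fill_cumld = [&](std::vector<double>& buf, double g0, double bt,
                        double be) {
    for (int i = 0; i < N; ++i) {
      double cum = 0.0;
      double* row = &buf[(size_t)i * T];
      for (int t = 0; t < T; ++t) {
        double etad = g0 + bt * tcov[t] + be * e(i, t);
        cum += (y(i, t) == 1) ? -R::log1pexp(-etad) : -R::log1pexp(etad);
        row[t] = cum;
      }
    }
  };

  for (int i = 0; i < N; ++i) set_phi(i);
  fill_cumld(cumld, theta[R + 3], theta[R + 4], theta[R + 5]);
  double lltot = 0.0;
  for (int i = 0; i < N; ++i) {
    llpop[i] = popll_from_cumld(&cumld[(size_t)i * T], logphi[i],
                                log1mphi[i], Li[i], T, scratch);
    lltot += llpop[i];
  }

  int n_keep = 0;
  for (int it = burn_in + 1; it <= iterations; it += thin) ++n_keep;
  NumericMatrix draws(n_keep, K);
  std::vector<double> acc(K, 0.0), batch_acc(K, 0.0);
  int stored = 0;
  int next_keep = burn_in + 1;

  for (int it = 1; it <= iterations; ++it) {
    for (int k = 0; k < K; ++k) {
      double old = theta[k];
      double cand = old + R::norm_rand() * scales[k];
      double lprior_ratio = (old * old - cand * cand) / (2 * prior_sd * prior_sd);
      double delta = 0.0;
      bool is_det = (k >= R + 3);
      bool is_beta = (k >= R && k < R + 3);
      if (is_det) {
        double g0 = k == R + 3 ? cand : theta[R + 3];
        double bt = k == R + 4 ? cand : theta[R + 4];
        double be = k == R + 5 ? cand : theta[R + 5];
        fill_cumld(cumld_new, g0, bt, be);
        for (int i = 0; i < N; ++i) {
          llpop_new[i] = popll_from_cumld(&cumld_new[(size_t)i * T],
                                          logphi[i], log1mphi[i], Li[i], T,
                                          scratch);
          delta += llpop_new[i] - llpop[i];
        }
      } else {
        // persistence parameter: phi changes for all pops (betas) or for
        // one ecoregion's pops (alphas); cumld is untouched
        double shift = cand - old;
        for (int i = 0; i < N; ++i) {
          bool touched = is_beta ? true : (eco[i] - 1 == k);
          if (!touched) { llpop_new[i] = llpop[i]; continue; }
          double et = eta[i] + shift * (is_beta ? X(i, k - R) : 1.0);
          double lp = -R::log1pexp(-et);
          double l1mp = -R::log1pexp(et);
          llpop_new[i] = popll_from_cumld(&cumld[(size_t)i * T], lp, l1mp,
                                          Li[i], T, scratch);
          delta += llpop_new[i] - llpop[i];
        }
      }
      if (std::isfinite(delta) &&
          std::log(R::unif_rand()) < delta + lprior_ratio) {
        theta[k] = cand;
        lltot += delta;
        std::swap(llpop, llpop_new);
        if (is_det) std::swap(cumld, cumld_new);
        else {
          double shift = cand - old;
          for (int i = 0; i < N; ++i) {
            bool touched = is_beta ? true : (eco[i] - 1 == k);
            if (!touched) continue;
            eta[i] += shift * (is_beta ? X(i, k - R) : 1.0);
            logphi[i] = -R::log1pexp(-eta[i]);
            log1mphi[i] = -R::log1pexp(eta[i]);
          }
        }
        batch_acc[k] += 1.0;
        if (it > burn_in) acc[k] += 1.0;
      }
    }
    if (it <= burn_in && it % 50 == 0) {
      for (int k = 0; k < K; ++k) {
        double rate = batch_acc[k] / 50.0;
        scales[k] *= std::exp(rate - target_acc);
        if (scales[k] < 1e-4) scales[k] = 1e-4;
        if (scales[k] > 25) scales[k] = 25;
        batch_acc[k] = 0.0;
      }
    }
    if (stored < n_keep && it == next_keep) {
      for (int k = 0; k < K; ++k) draws(stored, k) = theta[k];
      ++stored;
      next_keep += thin;
    }
  }
  NumericVector accrate(K);
  int denom = iterations - burn_in;
  for (int k = 0; k < K; ++k) accrate[k] = acc[k] / std::max(1, denom);
  return List::create(_["draws"] = draws, _["acceptance"] = accrate,
                      _["scales"] = NumericVector(scales.begin(), scales.end()));
}
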