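// Metropolis-within-Gibbs sampler for non-spatial and BYM Poisson models.
//
// Random-walk Metropolis updates for beta0 (flat prior), each beta_k
// (Gaussian prior), each u_i (ICAR full conditional) and each v_i (iid
// Gaussian); conjugate Gibbs draws for the two precisions; per-component
// sum-to-zero recentering of u after every sweep. Proposal SDs adapt by
// Robbins-Monro toward a target acceptance rate during burn-in only.
// Uses R's RNG, so set.seed() in R makes chains reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double rw_adapt(double ls, bool accepted, double target,
                              int iter) {
  double g = 1.0 / std::sqrt((double)iter);
  ls += g * ((accepted ? 1.0 : 0.0) - target);
  if (ls < -10.0) ls = -10.0;
  if (ls > 3.0) ls = 3.0;
  return ls;
}

// [[Rcpp::export]]
List bym_mcmc_chain(IntegerVector y, NumericVector E, NumericMatrix X,
                    List nbr, IntegerVector comp, bool spatial,
                    double beta_sd, double prec_shape, double prec_rate,
                    int n_iter, int n_burnin, int thin,
                    double target_accept, int adapt_until,
                    double lik_weight = 1.0,
                    double fix_prec_u = -1.0, double fix_prec_v = -1.0) {
  const int n = y.size();
  const int p = X.ncol();
  const double lw = lik_weight;

  std::vector<std::vector<int>> nb(n);
  if (spatial) {
    for (int i = 0; i < n; ++i) {
      IntegerVector v = nbr[i];
      nb[i].assign(v.begin(), v.end());   // 0-based indices
    }
  }
  int G = 0;
  for (int i = 0; i < n; ++i) G = std::max(G, comp[i]);

  // state
  double sumY = 0.0, sumE = 0.0;
  for (int i = 0; i < n; ++i) { sumY += y[i]; sumE += E[i]; }
  double beta0 = std::log(std::max(sumY, 0.5) / sumE);
  std::vector<double> beta(p, 0.0), u(n, 0.0), v(n, 0.0), eta(n, beta0);
  double prec_u = (fix_prec_u > 0) ? fix_prec_u : 10.0;
  double prec_v = (fix_prec_v > 0) ? fix_prec_v : 10.0;

  // adaptive log proposal SDs
  double ls0 = std::log(0.1);
  std::vector<double> lsb(p, std::log(0.1)), lsu(n, std::log(0.3)),
      lsv(n, std::log(0.3));

  // acceptance bookkeeping (post burn-in)
  double acc0 = 0, try0 = 0, accb = 0, tryb = 0, accu = 0, tryu = 0,
         accv = 0, tryv = 0;

  const int n_keep = (n_iter - n_burnin) / thin;
  NumericVector out_beta0(n_keep), out_su2(spatial ? n_keep : 0),
      out_sv2(spatial ? n_keep : 0);
  NumericMatrix out_beta(n_keep, p), out_u(spatial ? n_keep : 0, spatial ? n : 0),
      out_v(spatial ? n_keep : 0, spatial ? n : 0);

  RNGScope scope;
  int kept = 0;
  for (int iter = 1; iter <= n_iter; ++iter) {
    const bool adapting = iter <= adapt_until && iter <= n_burnin;
    const bool tally = iter > n_burnin;

    // --- beta0 (flat prior; fixed in prior-only mode) ---
    if (lw > 0) {
      double d = norm_rand() * std::exp(ls0);
      double dlp = 0.0;
      for (int i = 0; i < n; ++i)
        dlp += lw * (y[i] * d - E[i] * (std::exp(eta[i] + d) - std::exp(eta[i])));
      bool acc = std::isfinite(dlp) && std::log(unif_rand()) < dlp;
      if (acc) { beta0 += d; for (int i = 0; i < n; ++i) eta[i] += d; }
      if (adapting) ls0 = rw_adapt(ls0, acc, target_accept, iter);
      if (tally) { try0 += 1; acc0 += acc; }
    }

    // --- beta_k, Gaussian prior N(0, beta_sd^2) ---
    for (int k = 0; lw > 0 && k < p; ++k) {
      double d = norm_rand() * std::exp(lsb[k]);
      double bnew = beta[k] + d;
      double dlp = (beta[k] * beta[k] - bnew * bnew) / (2.0 * beta_sd * beta_sd);
      for (int i = 0; i < n; ++i) {
        double de = X(i, k) * d;
        dlp += lw * (y[i] * de -
                     E[i] * (std::exp(eta[i] + de) - std::exp(eta[i])));
      }
      bool acc = std::isfinite(dlp) && std::log(unif_rand()) < dlp;
      if (acc) {
        beta[k] = bnew;
        for (int i = 0; i < n; ++i) eta[i] += X(i, k) * d;
      }
      if (adapting) lsb[k] = rw_adapt(lsb[k], acc, target_accept, iter);
      if (tally) { tryb += 1; accb += acc; }
    }

    if (spatial) {
      // --- u_i: ICAR full conditional; islands stay at 0 ---
      for (int i = 0; i < n; ++i) {
        if (nb[i].empty()) continue;
        double d = norm_rand() * std::exp(lsu[i]);
        double un = u[i] + d;
        double dpr = 0.0;
        for (int j : nb[i])
          dpr += (un - u[j]) * (un - u[j]) - (u[i] - u[j]) * (u[i] - u[j]);
        double dlp = -0.5 * prec_u * dpr;
        if (lw > 0)
          dlp += lw * (y[i] * d - E[i] * (std::exp(eta[i] + d) - std::exp(eta[i])));
        bool acc = std::isfinite(dlp) && std::log(unif_rand()) < dlp;
        if (acc) { u[i] = un; eta[i] += d; }
        if (adapting) lsu[i] = rw_adapt(lsu[i], acc, target_accept, iter);
        if (tally) { tryu += 1; accu += acc; }
      }

      // --- v_i: iid N(0, 1/prec_v) prior ---
      for (int i = 0; i < n; ++i) {
        double d = norm_rand() * std::exp(lsv[i]);
        double vn = v[i] + d;
        double dlp = -0.5 * prec_v * (vn * vn - v[i] * v[i]);
        if (lw > 0)
          dlp += lw * (y[i] * d - E[i] * (std::exp(eta[i] + d) - std::exp(eta[i])));
        bool acc = std::isfinite(dlp) && std::log(unif_rand()) < dlp;
        if (acc) { v[i] = vn; eta[i] += d; }
        if (adapting) lsv[i] = rw_adapt(lsv[i], acc, target_accept, iter);
        if (tally) { tryv += 1; accv += acc; }
      }

      // --- per-component sum-to-zero recentering of u ---
      {
        std::vector<double> msum(G, 0.0);
        std::vector<int> mcnt(G, 0);
        for (int i = 0; i < n; ++i) {
          if (nb[i].empty()) continue;     // islands pinned at 0
          msum[comp[i] - 1] += u[i];
          mcnt[comp[i] - 1] += 1;
        }
        for (int i = 0; i < n; ++i) {
          if (nb[i].empty()) continue;
          double m = msum[comp[i] - 1] / mcnt[comp[i] - 1];
          u[i] -= m;
          eta[i] -= m;
        }
      }

      // --- conjugate Gibbs precision updates ---
      if (fix_prec_u <= 0) {
        double qf = 0.0;
        for (int i = 0; i < n; ++i)
          for (int j : nb[i])
            if (j > i) qf += (u[i] - u[j]) * (u[i] - u[j]);
        double shape = prec_shape + 0.5 * (n - G);
        double rate = prec_rate + 0.5 * qf;
        if (shape <= 0 || rate <= 0) stop("non-positive Gibbs shape/rate");
        prec_u = R::rgamma(shape, 1.0 / rate);
      }
      if (fix_prec_v <= 0) {
        double ss = 0.0;
        for (int i = 0; i < n; ++i) ss += v[i] * v[i];
        double shape = prec_shape + 0.5 * n;
        double rate = prec_rate + 0.5 * ss;
        if (shape <= 0 || rate <= 0) stop("non-positive Gibbs shape/rate");
        prec_v = R::rgamma(shape, 1.0 / rate);
      }
    }

    if (!std::isfinite(beta0))
      stop("divergent non-finite state at iteration %d", iter);

    if (iter > n_burnin && (iter - n_burnin) % thin == 0 && kept < n_keep) {
      out_beta0[kept] = beta0;
      for (int k = 0; k < p; ++k) out_beta(kept, k) = beta[k];
      if (spatial) {
        for (int i = 0; i < n; ++i) {
          out_u(kept, i) = u[i];
          out_v(kept, i) = v[i];
        }
        out_su2[kept] = 1.0 / prec_u;
        out_sv2[kept] = 1.0 / prec_v;
      }
      ++kept;
    }
  }

  return List::create(
      _["beta0"] = out_beta0, _["beta"] = out_beta,
      _["u"] = out_u, _["v"] = out_v,
      _["sigma_u2"] = out_su2, _["sigma_v2"] = out_sv2,
      _["accept"] = NumericVector::create(
          _["beta0"] = try0 > 0 ? acc0 / try0 : NA_REAL,
          _["beta"] = tryb > 0 ? accb / tryb : NA_REAL,
          _["u"] = tryu > 0 ? accu / tryu : NA_REAL,
          _["v"] = tryv > 0 ? accv / tryv : NA_REAL));
}
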