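// Adaptive Metropolis-within-Gibbs sampler for the multigroup Partial
// Credit Model with optional extreme-response-style (ERS) dimension and
// a country-level latent quadratic regression.
//
// Model (ext variant):
//   P(Y_pi = k) propto exp((k-1) theta_p + s_k eta_p - sum_{j<k} tau_ij)
//   theta_p ~ N(mu_theta_{g(p)}, 1)           (sigma_theta = 1 fixed)
//   mu_theta_g = x_g' beta + u_g, u_g ~ N(0, sigma_u^2)
//   eta_p ~ N(mu_eta_{g(p)}, sigma_eta^2)
//   mu_eta ~ N(0, sigma_mu_eta^2) restricted to sum_g mu_eta_g = 0
// Priors: tau ~ N(0, tau_sd), beta ~ N(0, beta_sd),
//   sigma_u, sigma_eta, sigma_mu_eta ~ half-Normal(sigma_scale).
//
// The threshold grand-sum direction is only softly identified during
// sampling (proper priors + a likelihood-invariant translation move);
// every saved draw is mapped to the identified scale by grand-mean
// centering tau with compensation absorbed into beta0 and mu_theta,
// which leaves the likelihood and all hierarchical densities unchanged.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int MAX_K = 32;

// log P(Y = y | theta, eta) for one item with cumulative thresholds ct
// (ct[0] = 0, ct[k] = tau_1 + ... + tau_k), 0-based category y.
static inline double cell_loglik(double theta, double eta,
                                 const double *ct, const double *s,
                                 int K, int y) {
  double z[MAX_K];
  double zmax = -1e300;
  for (int k = 0; k < K; ++k) {
    z[k] = k * theta + s[k] * eta - ct[k];
    if (z[k] > zmax) zmax = z[k];
  }
  double denom = 0.0;
  for (int k = 0; k < K; ++k) denom += std::exp(z[k] - zmax);
  return z[y] - zmax - std::log(denom);
}

static inline double dnorm_log(double v, double m, double sd) {
  double r = (v - m) / sd;
  return -0.5 * r * r - std::log(sd) - 0.9189385332046727;
}

// conditional log-density of a positive scale parameter sig given a sum
// of squares over `n` Gaussian deviations, with half-Normal(scale) prior
static inline double scale_logpost(double sig, double ss, int n,
                                   double prior_scale) {
  return -n * std::log(sig) - 0.5 * ss / (sig * sig) -
         0.5 * sig * sig / (prior_scale * prior_scale);
}

// Cholesky solve for the small (<= 3x3) Gibbs update of beta:
// sample from N(A^{-1} b, A^{-1}) given A (SPD) and b.
static void sample_mvn(int d, double A[3][3], double b[3], double out[3]) {
  double L[3][3] = {{0}};
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j <= i; ++j) {
      double sum = A[i][j];
      for (int k = 0; k < j; ++k) sum -= L[i][k] * L[j][k];
      if (i == j)
        L[i][i] = std::sqrt(sum);
      else
        L[i][j] = sum / L[j][j];
    }
  }
  // solve L w = b, L' m = w
  double w[3], m[3];
  for (int i = 0; i < d; ++i) {
    double sum = b[i];
    for (int k = 0; k < i; ++k) sum -= L[i][k] * w[k];
    w[i] = sum / L[i][i];
  }
  for (int i = d - 1; i >= 0; --i) {
    double sum = w[i];
    for (int k = i + 1; k < d; ++k) sum -= L[k][i] * m[k];
    m[i] = sum / L[i][i];
  }
  // mean + L'^{-1} z
  double z[3], v[3];
  for (int i = 0; i < d; ++i) z[i] = R::norm_rand();
  for (int i = d - 1; i >= 0; --i) {
    double sum = z[i];
    for (int k = i + 1; k < d; ++k) sum -= L[k][i] * v[k];
    v[i] = sum / L[i][i];
  }
  for (int i = 0; i < d; ++i) out[i] = m[i] + v[i];
}

// univariate slice sampler (stepping out + shrinkage), used for the
// collapsed scale-parameter updates where no tuning should be needed
template <typename F>
static double slice_sample(F logpost, double x0, double w, int max_steps) {
  double y = logpost(x0) - R::exp_rand();
  double L = x0 - w * R::unif_rand();
  double Rr = L + w;
  int j = (int)std::floor(max_steps * R::unif_rand());
  int k = max_steps - 1 - j;
  while (j-- > 0 && logpost(L) > y) L -= w;
  while (k-- > 0 && logpost(Rr) > y) Rr += w;
  for (int it = 0; it < 100; ++it) {
    double x1 = L + (Rr - L) * R::unif_rand();
    if (logpost(x1) > y) return x1;
    if (x1 < x0) L = x1;
    else Rr = x1;
  }
  return x0;
}

struct AdaptScale {
  double ls;      // log proposal scale
  int acc, tot;   // batch counters
  double target;
  AdaptScale(double s0 = 0.2, double t = 0.44)
      : ls(std::log(s0)), acc(0), tot(0), target(t) {}
  double scale() const { return std::exp(ls); }
  void note(bool accepted) {
    acc += accepted;
    tot += 1;
  }
  void adapt(int batch_no) {
    if (tot == 0) return;
    double rate = (double)acc / tot;
    double step = std::min(0.25, 1.0 / std::sqrt((double)batch_no));
    ls += (rate > target) ? step : -step;
    acc = 0;
    tot = 0;
  }
};

// [[Rcpp::export]]
List run_mwg_chain(IntegerVector y, IntegerVector pidx, IntegerVector iidx,
                   int N, int I, int K, int G, IntegerVector country,
                   NumericVector x, NumericVector s_weights, bool ext,
                   int degree, double prior_tau_sd, double prior_beta_sd,
                   double prior_sigma_scale, int n_warmup, int n_save,
                   int thin, Nullable<NumericMatrix> fix_tau_,
                   double fix_sigma_u) {
  if (K > MAX_K) stop("K exceeds the compiled category limit.");
  const int M = y.size();
  const int J = K - 1;
  const int d = degree + 1;
  const bool tau_fixed = fix_tau_.isNotNull();
  const bool su_fixed = fix_sigma_u >= 0.0;

  // ---- index structures -------------------------------------------------
  std::vector<int> pptr(N + 1, 0), iptr(I + 1, 0);
  for (int r = 0; r < M; ++r) {
    pptr[pidx[r] + 1]++;
    iptr[iidx[r] + 1]++;
  }
  for (int p = 0; p < N; ++p) pptr[p + 1] += pptr[p];
  for (int i = 0; i < I; ++i) iptr[i + 1] += iptr[i];
  std::vector<int> pr(M), ir(M);  // response ids grouped by person / item
  {
    std::vector<int> cp(pptr.begin(), pptr.end() - 1),
        ci(iptr.begin(), iptr.end() - 1);
    for (int r = 0; r < M; ++r) {
      pr[cp[pidx[r]]++] = r;
      ir[ci[iidx[r]]++] = r;
    }
  }
  std::vector<int> ng(G, 0);
  for (int p = 0; p < N; ++p) ng[country[p]]++;
  std::vector<int> gptr(G + 1, 0), gpers(N);
  for (int g = 0; g < G; ++g) gptr[g + 1] = gptr[g] + ng[g];
  {
    std::vector<int> cg(gptr.begin(), gptr.end() - 1);
    for (int p = 0; p < N; ++p) gpers[cg[country[p]]++] = p;
  }

  // country design matrix rows (1, x, x^2) up to `degree`
  std::vector<double> X(G * d);
  for (int g = 0; g < G; ++g)
    for (int c = 0; c < d; ++c) X[g * d + c] = std::pow(x[g], c);

  // ---- state ------------------------------------------------------------
  std::vector<double> theta(N), eta(N, 0.0), tau(I * J), ct(I * K);
  std::vector<double> mu_theta(G, 0.0), mu_eta(G, 0.0), beta(d, 0.0);
  double sigma_u = su_fixed ? fix_sigma_u : 0.3;
  double sigma_eta = 0.5, sigma_mu_eta = 0.5;
  const double *s = &s_weights[0];
  std::vector<double> dwt(J);  // d_j = s_j - s_{j+1}
  for (int j = 0; j < J; ++j) dwt[j] = s[j] - s[j + 1];

  if (tau_fixed) {
    NumericMatrix ft(fix_tau_);
    for (int i = 0; i < I; ++i)
      for (int j = 0; j < J; ++j) tau[i * J + j] = ft(i, j);
  } else {
    for (int i = 0; i < I * J; ++i) tau[i] = 0.3 * R::norm_rand();
  }
  for (int p = 0; p < N; ++p) theta[p] = 0.5 * R::norm_rand();
  if (ext)
    for (int p = 0; p < N; ++p) eta[p] = 0.3 * R::norm_rand();

  auto refresh_ct = [&](int i) {
    ct[i * K] = 0.0;
    for (int j = 0; j < J; ++j)
      ct[i * K + j + 1] = ct[i * K + j] + tau[i * J + j];
  };
  for (int i = 0; i < I; ++i) refresh_ct(i);

  // cached per-response log-likelihood terms
  std::vector<double> llt(M);
  auto refresh_ll_item = [&](int i) {
    for (int q = iptr[i]; q < iptr[i + 1]; ++q) {
      int r = ir[q];
      llt[r] = cell_loglik(theta[pidx[r]], eta[pidx[r]], &ct[i * K], s, K,
                           y[r]);
    }
  };
  for (int i = 0; i < I; ++i) refresh_ll_item(i);

  AdaptScale sc_theta(0.6, 0.44), sc_eta(0.6, 0.44);
  std::vector<AdaptScale> sc_tau(I, AdaptScale(0.1, 0.25));
  
  AdaptScale sc_shift(0.2, 0.44), sc_eshift(0.2, 0.44);
  AdaptScale sc_loc(0.1, 0.35);
  AdaptScale sc_sur(0.3, 0.44), sc_ser(0.3, 0.44), sc_epair(0.1, 0.35);
  AdaptScale sc_joint(0.6, 0.25);
  // per-country running covariance of (mu_theta_g, mu_eta_g), warmup only
  std::vector<double> cm_mean(2 * G, 0.0), cm_cov(3 * G, 0.0);
  int cm_n = 0;

  const int P = d + 1 + G + I * J + (ext ? G + 2 : 0);
  NumericMatrix out(n_save, P);
  NumericVector acc_rates;

  std::vector<double> prop(std::max(J, K)), newll(M > 0 ? M : 1);
  int n_iter = n_warmup + n_save * thin;
  int saved = 0, batch_no = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    bool warm = iter < n_warmup;

    // -- theta updates ---------------------------------------------------
    {
      double sc = sc_theta.scale();
      for (int p = 0; p < N; ++p) {
        double cur = 0.0;
        for (int q = pptr[p]; q < pptr[p + 1]; ++q) cur += llt[pr[q]];
        double th_new = theta[p] + sc * R::norm_rand();
        double prop_ll = 0.0;
        for (int q = pptr[p]; q < pptr[p + 1]; ++q) {
          int r = pr[q];
          newll[q - pptr[p]] =
              cell_loglik(th_new, eta[p], &ct[iidx[r] * K], s, K, y[r]);
          prop_ll += newll[q - pptr[p]];
        }
        double lr = prop_ll - cur +
                    dnorm_log(th_new, mu_theta[country[p]], 1.0) -
                    dnorm_log(theta[p], mu_theta[country[p]], 1.0);
        bool acc = std::log(R::unif_rand()) < lr;
        if (acc) {
          theta[p] = th_new;
          for (int q = pptr[p]; q < pptr[p + 1]; ++q)
            llt[pr[q]] = newll[q - pptr[p]];
        }
        if (warm) sc_theta.note(acc);
      }
    }

    // -- eta updates -----------------------------------------------------
    if (ext) {
      double sc = sc_eta.scale();
      for (int p = 0; p < N; ++p) {
        double cur = 0.0;
        for (int q = pptr[p]; q < pptr[p + 1]; ++q) cur += llt[pr[q]];
        double et_new = eta[p] + sc * R::norm_rand();
        double prop_ll = 0.0;
        for (int q = pptr[p]; q < pptr[p + 1]; ++q) {
          int r = pr[q];
          newll[q - pptr[p]] =
              cell_loglik(theta[p], et_new, &ct[iidx[r] * K], s, K, y[r]);
          prop_ll += newll[q - pptr[p]];
        }
        int g = country[p];
        double lr = prop_ll - cur +
                    dnorm_log(et_new, mu_eta[g], sigma_eta) -
                    dnorm_log(eta[p], mu_eta[g], sigma_eta);
        bool acc = std::log(R::unif_rand()) < lr;
        if (acc) {
          eta[p] = et_new;
          for (int q = pptr[p]; q < pptr[p + 1]; ++q)
            llt[pr[q]] = newll[q - pptr[p]];
        }
        if (warm) sc_eta.note(acc);
      }
    }

    // -- tau updates (joint random walk per item) ------------------------
    if (!tau_fixed) {
      for (int i = 0; i < I; ++i) {
        double sc = sc_tau[i].scale();
        double prior_delta = 0.0;
        for (int j = 0; j < J; ++j) {
          prop[j] = tau[i * J + j] + sc * R::norm_rand();
          prior_delta += dnorm_log(prop[j], 0.0, prior_tau_sd) -
                         dnorm_log(tau[i * J + j], 0.0, prior_tau_sd);
        }
        double ct_new[MAX_K];
        ct_new[0] = 0.0;
        for (int j = 0; j < J; ++j) ct_new[j + 1] = ct_new[j] + prop[j];
        double cur = 0.0, nw = 0.0;
        for (int q = iptr[i]; q < iptr[i + 1]; ++q) {
          int r = ir[q];
          cur += llt[r];
          newll[q - iptr[i]] =
              cell_loglik(theta[pidx[r]], eta[pidx[r]], ct_new, s, K, y[r]);
          nw += newll[q - iptr[i]];
        }
        bool acc = std::log(R::unif_rand()) < nw - cur + prior_delta;
        if (acc) {
          for (int j = 0; j < J; ++j) tau[i * J + j] = prop[j];
          refresh_ct(i);
          for (int q = iptr[i]; q < iptr[i + 1]; ++q)
            llt[ir[q]] = newll[q - iptr[i]];
        }
        if (warm) sc_tau[i].note(acc);
      }

      // likelihood-invariant translation along the soft tau-location
      // direction: tau += c, theta += c, mu_theta += c, beta0 += c
      {
        double c = sc_shift.scale() * R::norm_rand();
        double lr = dnorm_log(beta[0] + c, 0.0, prior_beta_sd) -
                    dnorm_log(beta[0], 0.0, prior_beta_sd);
        for (int i = 0; i < I * J; ++i)
          lr += dnorm_log(tau[i] + c, 0.0, prior_tau_sd) -
                dnorm_log(tau[i], 0.0, prior_tau_sd);
        bool acc = std::log(R::unif_rand()) < lr;
        if (acc) {
          for (int i = 0; i < I * J; ++i) tau[i] += c;
          for (int i = 0; i < I; ++i) refresh_ct(i);
          for (int p = 0; p < N; ++p) theta[p] += c;
          for (int g = 0; g < G; ++g) mu_theta[g] += c;
          beta[0] += c;
          // cell logliks are invariant under this map
        }
        if (warm) sc_shift.note(acc);
      }

      // likelihood-invariant shift along the eta-location direction:
      // eta += c, tau_j -= d_j * c (probabilities unchanged)
      if (ext) {
        double c = sc_eshift.scale() * R::norm_rand();
        double lr = 0.0;
        for (int p = 0; p < N; ++p)
          lr += dnorm_log(eta[p] + c, mu_eta[country[p]], sigma_eta) -
                dnorm_log(eta[p], mu_eta[country[p]], sigma_eta);
        for (int i = 0; i < I; ++i)
          for (int j = 0; j < J; ++j)
            lr += dnorm_log(tau[i * J + j] - dwt[j] * c, 0.0,
                            prior_tau_sd) -
                  dnorm_log(tau[i * J + j], 0.0, prior_tau_sd);
        bool acc = std::log(R::unif_rand()) < lr;
        if (acc) {
          for (int p = 0; p < N; ++p) eta[p] += c;
          for (int i = 0; i < I; ++i) {
            for (int j = 0; j < J; ++j) tau[i * J + j] -= dwt[j] * c;
            refresh_ct(i);
          }
          // cell logliks are invariant: every category exponent shifts
          // by the same constant s_1 * c, which cancels in the softmax
        }
        if (warm) sc_eshift.note(acc);
      }
    }

    // -- country location moves ------------------------------------------
    // shift all theta in country g together with mu_theta_g; this block
    // update lets the country means mix at the data-informed rate
    // instead of diffusing through person-level random walks
    {
      double sc = sc_loc.scale();
      bool mu_pinned = su_fixed && fix_sigma_u == 0.0;
      for (int g = 0; g < G; ++g) {
        double c = sc * R::norm_rand();
        double m = 0.0;
        for (int cc = 0; cc < d; ++cc) m += X[g * d + cc] * beta[cc];
        double lr;
        if (mu_pinned) {
          // mu_theta_g stays on the regression line: shift theta only,
          // paying the hierarchical terms
          lr = 0.0;
          for (int q = gptr[g]; q < gptr[g + 1]; ++q) {
            int p = gpers[q];
            lr += dnorm_log(theta[p] + c, mu_theta[g], 1.0) -
                  dnorm_log(theta[p], mu_theta[g], 1.0);
          }
        } else {
          lr = dnorm_log(mu_theta[g] + c, m, sigma_u) -
               dnorm_log(mu_theta[g], m, sigma_u);
        }
        double dll = 0.0;
        for (int gq = gptr[g]; gq < gptr[g + 1]; ++gq) {
          int p = gpers[gq];
          for (int q = pptr[p]; q < pptr[p + 1]; ++q) {
            int r = pr[q];
            double nl = cell_loglik(theta[p] + c, eta[p],
                                    &ct[iidx[r] * K], s, K, y[r]);
            newll[q] = nl;  // indexed by global response slot
            dll += nl - llt[r];
          }
        }
        bool acc = std::log(R::unif_rand()) < lr + dll;
        if (acc) {
          for (int gq = gptr[g]; gq < gptr[g + 1]; ++gq) {
            int p = gpers[gq];
            theta[p] += c;
            for (int q = pptr[p]; q < pptr[p + 1]; ++q)
              llt[pr[q]] = newll[q];
          }
          if (!mu_pinned) mu_theta[g] += c;
        }
        if (warm) sc_loc.note(acc);
      }
    }

    // -- regression layer: collapsed updates -----------------------------
    // The country means are integrated out of the sigma_u and beta
    // updates via theta_bar_g ~ N(x_g' beta, sigma_u^2 + 1/n_g), which
    // removes the funnel between sigma_u and mu_theta; mu_theta is then
    // redrawn from its conjugate conditional.
    std::vector<double> sum_theta(G, 0.0);
    for (int p = 0; p < N; ++p) sum_theta[country[p]] += theta[p];

    if (!su_fixed) {
      auto marg_loglik = [&](double su) {
        double ll = 0.0;
        for (int g = 0; g < G; ++g) {
          double m = 0.0;
          for (int c = 0; c < d; ++c) m += X[g * d + c] * beta[c];
          double v = su * su + 1.0 / ng[g];
          double r = sum_theta[g] / ng[g] - m;
          ll += -0.5 * std::log(v) - 0.5 * r * r / v;
        }
        return ll;
      };
      // slice sample on the log scale (half-Normal prior + Jacobian)
      auto lp = [&](double lx) {
        double sg = std::exp(lx);
        return marg_loglik(sg) -
               0.5 * sg * sg / (prior_sigma_scale * prior_sigma_scale) +
               lx;
      };
      sigma_u = std::exp(slice_sample(lp, std::log(sigma_u), 1.0, 20));
    }

    // joint rescale of (sigma_u, country residuals): mu' = m + rho (mu - m)
    // with rho = sigma_u'/sigma_u; the Jacobian cancels against the
    // residual prior, leaving the theta-hierarchy terms and the
    // half-Normal prior
    if (!su_fixed) {
      double lcur = std::log(sigma_u);
      double lnew = lcur + sc_sur.scale() * R::norm_rand();
      double rho = std::exp(lnew - lcur);
      double snew = sigma_u * rho;
      std::vector<double> mu_new(G);
      double lr = -0.5 * (snew * snew - sigma_u * sigma_u) /
                      (prior_sigma_scale * prior_sigma_scale) +
                  lnew - lcur;
      for (int g = 0; g < G; ++g) {
        double m = 0.0;
        for (int c = 0; c < d; ++c) m += X[g * d + c] * beta[c];
        mu_new[g] = m + rho * (mu_theta[g] - m);
      }
      for (int p = 0; p < N; ++p) {
        int g = country[p];
        lr += dnorm_log(theta[p], mu_new[g], 1.0) -
              dnorm_log(theta[p], mu_theta[g], 1.0);
      }
      bool acc = std::log(R::unif_rand()) < lr;
      if (acc) {
        sigma_u = snew;
        for (int g = 0; g < G; ++g) mu_theta[g] = mu_new[g];
      }
      if (warm) sc_sur.note(acc);
    }

    {
      // beta from the collapsed Gaussian regression of theta_bar_g
      double A[3][3] = {{0}}, b[3] = {0};
      for (int g = 0; g < G; ++g) {
        double w = (su_fixed && fix_sigma_u == 0.0)
                       ? (double)ng[g]
                       : 1.0 / (sigma_u * sigma_u + 1.0 / ng[g]);
        for (int c1 = 0; c1 < d; ++c1) {
          for (int c2 = 0; c2 < d; ++c2)
            A[c1][c2] += w * X[g * d + c1] * X[g * d + c2];
          b[c1] += w * X[g * d + c1] * sum_theta[g] / ng[g];
        }
      }
      for (int c = 0; c < d; ++c)
        A[c][c] += 1.0 / (prior_beta_sd * prior_beta_sd);
      double bnew[3];
      sample_mvn(d, A, b, bnew);
      for (int c = 0; c < d; ++c) beta[c] = bnew[c];
    }

    // mu_theta from its conjugate conditional
    for (int g = 0; g < G; ++g) {
      double m = 0.0;
      for (int c = 0; c < d; ++c) m += X[g * d + c] * beta[c];
      if (su_fixed && fix_sigma_u == 0.0) {
        mu_theta[g] = m;
      } else {
        double inv_su2 = 1.0 / (sigma_u * sigma_u);
        double prec = ng[g] + inv_su2;
        double mean = (sum_theta[g] + m * inv_su2) / prec;
        mu_theta[g] = mean + R::norm_rand() / std::sqrt(prec);
      }
    }

    // -- ERS country structure -------------------------------------------
    if (ext) {
      std::vector<double> sum_eta(G, 0.0);
      for (int p = 0; p < N; ++p) sum_eta[country[p]] += eta[p];

      // sigma_eta given (eta, mu_eta)
      {
        double ss = 0.0;
        for (int p = 0; p < N; ++p) {
          double r = eta[p] - mu_eta[country[p]];
          ss += r * r;
        }
        auto lp = [&](double lx) {
          return scale_logpost(std::exp(lx), ss, N, prior_sigma_scale) +
                 lx;
        };
        sigma_eta = std::exp(slice_sample(lp, std::log(sigma_eta), 0.5, 20));
      }

      // joint rescale of (sigma_eta, eta deviations):
      // eta' = mu_eta + rho (eta - mu_eta); the Jacobian cancels against
      // the eta-hierarchy prior, leaving the response likelihood and the
      // half-Normal prior. Breaks the funnel between sigma_eta and the
      // weakly identified person-level ERS values.
      {
        double lcur = std::log(sigma_eta);
        double lnew = lcur + sc_ser.scale() * R::norm_rand();
        double rho = std::exp(lnew - lcur);
        double snew = sigma_eta * rho;
        double lr = -0.5 * (snew * snew - sigma_eta * sigma_eta) /
                        (prior_sigma_scale * prior_sigma_scale) +
                    lnew - lcur;
        std::vector<double> eta_new(N);
        for (int p = 0; p < N; ++p) {
          double m = mu_eta[country[p]];
          eta_new[p] = m + rho * (eta[p] - m);
          for (int q = pptr[p]; q < pptr[p + 1]; ++q) {
            int r = pr[q];
            double nl = cell_loglik(theta[p], eta_new[p],
                                    &ct[iidx[r] * K], s, K, y[r]);
            newll[q] = nl;
            lr += nl - llt[r];
          }
        }
        bool acc = std::log(R::unif_rand()) < lr;
        if (acc) {
          sigma_eta = snew;
          for (int p = 0; p < N; ++p) {
            eta[p] = eta_new[p];
            for (int q = pptr[p]; q < pptr[p + 1]; ++q)
              llt[pr[q]] = newll[q];
          }
        }
        if (warm) sc_ser.note(acc);
      }

      // sigma_mu_eta with mu_eta integrated out:
      // eta_bar ~ N(0, diag(sigma_eta^2/n_g) + s_m^2 (I - 11'/G)),
      // evaluated via Sherman-Morrison on A = diag(a_g) - (s_m^2/G) 11'
      {
        auto marg_loglik = [&](double sm) {
          double sm2 = sm * sm, se2 = sigma_eta * sigma_eta;
          double cc = sm2 / G;
          double logdet = 0.0, q1 = 0.0, t1 = 0.0, tb = 0.0;
          for (int g = 0; g < G; ++g) {
            double a = se2 / ng[g] + sm2;
            double eb = sum_eta[g] / ng[g];
            logdet += std::log(a);
            q1 += eb * eb / a;
            t1 += 1.0 / a;
            tb += eb / a;
          }
          double denom = 1.0 - cc * t1;
          logdet += std::log(denom);
          double quad = q1 + cc * tb * tb / denom;
          return -0.5 * logdet - 0.5 * quad;
        };
        auto lp = [&](double lx) {
          double sg = std::exp(lx);
          return marg_loglik(sg) -
                 0.5 * sg * sg /
                     (prior_sigma_scale * prior_sigma_scale) +
                 lx;
        };
        sigma_mu_eta =
            std::exp(slice_sample(lp, std::log(sigma_mu_eta), 1.0, 20));
      }

      // pairwise country ERS-location moves: shift country g's eta and
      // mu_eta by +c and a partner country's by -c, preserving the
      // sum-to-zero constraint; the eta-hierarchy terms cancel, leaving
      // the response likelihood of both countries and the mu_eta prior.
      // This lets the country ERS means trade off against the trait
      // means at the data-informed rate, which drives mixing of the
      // adjusted regression coefficients under strong confounding.
      if (G >= 2) {
        double sc = sc_epair.scale();
        for (int g = 0; g < G; ++g) {
          int g2 = (g + 1) % G;
          double c = sc * R::norm_rand();
          double lr = dnorm_log(mu_eta[g] + c, 0.0, sigma_mu_eta) +
                      dnorm_log(mu_eta[g2] - c, 0.0, sigma_mu_eta) -
                      dnorm_log(mu_eta[g], 0.0, sigma_mu_eta) -
                      dnorm_log(mu_eta[g2], 0.0, sigma_mu_eta);
          for (int side = 0; side < 2; ++side) {
            int gg = side == 0 ? g : g2;
            double cc = side == 0 ? c : -c;
            for (int gq = gptr[gg]; gq < gptr[gg + 1]; ++gq) {
              int p = gpers[gq];
              for (int q = pptr[p]; q < pptr[p + 1]; ++q) {
                int r = pr[q];
                double nl = cell_loglik(theta[p], eta[p] + cc,
                                        &ct[iidx[r] * K], s, K, y[r]);
                newll[q] = nl;
                lr += nl - llt[r];
              }
            }
          }
          bool acc = std::log(R::unif_rand()) < lr;
          if (acc) {
            mu_eta[g] += c;
            mu_eta[g2] -= c;
            for (int side = 0; side < 2; ++side) {
              int gg = side == 0 ? g : g2;
              double cc = side == 0 ? c : -c;
              for (int gq = gptr[gg]; gq < gptr[gg + 1]; ++gq) {
                int p = gpers[gq];
                eta[p] += cc;
                for (int q = pptr[p]; q < pptr[p + 1]; ++q)
                  llt[pr[q]] = newll[q];
              }
            }
          }
          if (warm) sc_epair.note(acc);
        }
      }

      // adaptive 2-D country moves along the learned posterior ridge of
      // (mu_theta_g, mu_eta_g): under strong confounding the trait mean
      // and the ERS mean of a country trade off almost one-for-one, and
      // axis-aligned moves cross that ridge slowly. Proposals shift the
      // country's theta/mu_theta by c and its eta/mu_eta by e, with
      // (c, e) drawn from the scaled empirical covariance accumulated
      // during warmup; the mu_eta shift is rebalanced across the other
      // countries (-e/(G-1)) to keep the sum-to-zero constraint, paying
      // their eta-hierarchy terms.
      if (G >= 3 && cm_n >= 100) {
        double fac = sc_joint.scale();
        for (int g = 0; g < G; ++g) {
          // Cholesky of the accumulated covariance (+ jitter)
          double c00 = cm_cov[3 * g] / (cm_n - 1) + 1e-8;
          double c01 = cm_cov[3 * g + 1] / (cm_n - 1);
          double c11 = cm_cov[3 * g + 2] / (cm_n - 1) + 1e-8;
          double l00 = std::sqrt(c00);
          double l10 = c01 / l00;
          double l11 = std::sqrt(std::max(c11 - l10 * l10, 1e-12));
          double z0 = R::norm_rand(), z1 = R::norm_rand();
          double c = fac * l00 * z0;
          double e = fac * (l10 * z0 + l11 * z1);
          double eoff = -e / (G - 1);

          double m = 0.0;
          for (int cc = 0; cc < d; ++cc) m += X[g * d + cc] * beta[cc];
          double lr = dnorm_log(mu_theta[g] + c, m, sigma_u) -
                      dnorm_log(mu_theta[g], m, sigma_u);
          // mu_eta prior on the shifted configuration
          lr += dnorm_log(mu_eta[g] + e, 0.0, sigma_mu_eta) -
                dnorm_log(mu_eta[g], 0.0, sigma_mu_eta);
          for (int g2 = 0; g2 < G; ++g2) {
            if (g2 == g) continue;
            lr += dnorm_log(mu_eta[g2] + eoff, 0.0, sigma_mu_eta) -
                  dnorm_log(mu_eta[g2], 0.0, sigma_mu_eta);
          }
          // other countries' eta-hierarchy terms (their eta stay put)
          for (int p = 0; p < N; ++p) {
            int g2 = country[p];
            if (g2 == g) continue;
            lr += dnorm_log(eta[p], mu_eta[g2] + eoff, sigma_eta) -
                  dnorm_log(eta[p], mu_eta[g2], sigma_eta);
          }
          // country g likelihood under (theta + c, eta + e)
          for (int gq = gptr[g]; gq < gptr[g + 1]; ++gq) {
            int p = gpers[gq];
            for (int q = pptr[p]; q < pptr[p + 1]; ++q) {
              int r = pr[q];
              double nl = cell_loglik(theta[p] + c, eta[p] + e,
                                      &ct[iidx[r] * K], s, K, y[r]);
              newll[q] = nl;
              lr += nl - llt[r];
            }
          }
          bool acc = std::log(R::unif_rand()) < lr;
          if (acc) {
            mu_theta[g] += c;
            for (int g2 = 0; g2 < G; ++g2)
              mu_eta[g2] += (g2 == g) ? e : eoff;
            for (int gq = gptr[g]; gq < gptr[g + 1]; ++gq) {
              int p = gpers[gq];
              theta[p] += c;
              eta[p] += e;
              for (int q = pptr[p]; q < pptr[p + 1]; ++q)
                llt[pr[q]] = newll[q];
            }
          }
          if (warm) sc_joint.note(acc);
        }
      }

      // accumulate the (mu_theta, mu_eta) covariance during warmup
      if (warm) {
        ++cm_n;
        for (int g = 0; g < G; ++g) {
          double dx = mu_theta[g] - cm_mean[2 * g];
          double dy = mu_eta[g] - cm_mean[2 * g + 1];
          cm_mean[2 * g] += dx / cm_n;
          cm_mean[2 * g + 1] += dy / cm_n;
          cm_cov[3 * g] += dx * (mu_theta[g] - cm_mean[2 * g]);
          cm_cov[3 * g + 1] += dx * (mu_eta[g] - cm_mean[2 * g + 1]);
          cm_cov[3 * g + 2] += dy * (mu_eta[g] - cm_mean[2 * g + 1]);
        }
      }

      // mu_eta: conjugate per country, then exact projection onto the
      // sum-to-zero subspace (valid Gibbs step for the constrained prior)
      {
        std::vector<double> z(G), v(G);
        double sum_z = 0.0, sum_v = 0.0;
        double inv_se2 = 1.0 / (sigma_eta * sigma_eta);
        double inv_sm2 = 1.0 / (sigma_mu_eta * sigma_mu_eta);
        for (int g = 0; g < G; ++g) {
          double prec = ng[g] * inv_se2 + inv_sm2;
          v[g] = 1.0 / prec;
          double mean = sum_eta[g] * inv_se2 * v[g];
          z[g] = mean + R::norm_rand() * std::sqrt(v[g]);
          sum_z += z[g];
          sum_v += v[g];
        }
        for (int g = 0; g < G; ++g)
          mu_eta[g] = z[g] - v[g] * sum_z / sum_v;
      }
    }

    // -- warmup adaptation ------------------------------------------------
    if (warm && (iter + 1) % 50 == 0) {
      ++batch_no;
      sc_theta.adapt(batch_no);
      sc_eta.adapt(batch_no);
      for (int i = 0; i < I; ++i) sc_tau[i].adapt(batch_no);
      sc_shift.adapt(batch_no);
      sc_eshift.adapt(batch_no);
      sc_loc.adapt(batch_no);
      sc_sur.adapt(batch_no);
      sc_ser.adapt(batch_no);
      sc_epair.adapt(batch_no);
      sc_joint.adapt(batch_no);
    }

    // -- save (identified scale) -----------------------------------------
    if (!warm && ((iter - n_warmup + 1) % thin == 0) && saved < n_save) {
      double tbar = 0.0;
      if (!tau_fixed) {
        for (int i = 0; i < I * J; ++i) tbar += tau[i];
        tbar /= (I * J);
      }
      int c0 = 0;
      out(saved, c0) = beta[0] - tbar;
      for (int c = 1; c < d; ++c) out(saved, c0 + c) = beta[c];
      c0 += d;
      out(saved, c0++) = sigma_u;
      for (int g = 0; g < G; ++g) out(saved, c0++) = mu_theta[g] - tbar;
      for (int i = 0; i < I * J; ++i) out(saved, c0++) = tau[i] - tbar;
      if (ext) {
        for (int g = 0; g < G; ++g) out(saved, c0++) = mu_eta[g];
        out(saved, c0++) = sigma_eta;
        out(saved, c0++) = sigma_mu_eta;
      }
      ++saved;
    }

    if ((iter + 1) % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["draws"] = out,
      _["scales"] = NumericVector::create(
          _["theta"] = sc_theta.scale(), _["eta"] = sc_eta.scale()));
}
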