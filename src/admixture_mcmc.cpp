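// Gibbs sampler for the Bayesian admixture model (with the
// correlated-allele-frequencies F-model as default), diploid data,
// missing allele copies skipped. Allele codes arrive as an N x 2L integer
// matrix of dense 0-based indices (-1 = missing). Uses R's RNG so results
// are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double rgamma_pos(double shape) {
  double g = R::rgamma(shape, 1.0);
  return (g > 0.0 && R_finite(g)) ? g : 1e-300;
}

// Dirichlet draw into out[0..J)
static void rdirichlet_vec(const double* a, double* out, int J) {
  double s = 0.0;
  for (int j = 0; j < J; ++j) { out[j] = rgamma_pos(a[j]); s += out[j]; }
  for (int j = 0; j < J; ++j) out[j] /= s;
}

static inline double log_dirichlet(const double* x, const double* a, int J) {
  double sa = 0.0, lg = 0.0;
  for (int j = 0; j < J; ++j) {
    sa += a[j];
    lg -= R::lgammafn(a[j]);
    lg += (a[j] - 1.0) * std::log(std::max(x[j], 1e-300));
  }
  return lg + R::lgammafn(sa);
}

// [[Rcpp::export(name = ".admixture_gibbs")]]
List admixture_gibbs(IntegerMatrix codes, IntegerVector n_alleles, int K,
                     int burnin, int iters, int record_interval,
                     bool correlated, double lambda, bool estimate_lambda,
                     double alpha_init, double alpha_propsd, double alpha_max,
                     double f_propsd, double pi_prop_conc,
                     bool store_q_draws) {
  const int N = codes.nrow();
  const int L = n_alleles.size();
  if (codes.ncol() != 2 * L) stop("codes must have 2 columns per locus");
  if (K < 1) stop("K must be >= 1");
  if (K > N) stop("K exceeds the number of individuals");
  if (lambda <= 0.0) stop("lambda must be positive");

  // flat layouts: pi at pioff[l] + j ; p at poff[l] + k*J_l + j
  std::vector<int> pioff(L + 1, 0), poff(L + 1, 0);
  for (int l = 0; l < L; ++l) {
    pioff[l + 1] = pioff[l] + n_alleles[l];
    poff[l + 1] = poff[l] + K * n_alleles[l];
  }
  const int PI_SZ = pioff[L], P_SZ = poff[L];

  std::vector<double> p(P_SZ), pi(PI_SZ), Fk(K, 0.05);
  std::vector<double> q(N * K), nik(N * K), cklj(P_SZ);
  double alpha = alpha_init;
  double cur_lambda = lambda;

  // init: pi from observed allele proportions (plus pseudocount), p = pi,
  // q from a flat Dirichlet so replicate seeds start at random labelings
  for (int l = 0; l < L; ++l) {
    const int J = n_alleles[l];
    std::vector<double> cnt(J, 1.0);
    for (int i = 0; i < N; ++i)
      for (int c = 0; c < 2; ++c) {
        int a = codes(i, 2 * l + c);
        if (a >= 0) cnt[a] += 1.0;
      }
    double s = 0.0; for (int j = 0; j < J; ++j) s += cnt[j];
    for (int j = 0; j < J; ++j) {
      pi[pioff[l] + j] = cnt[j] / s;
      for (int k = 0; k < K; ++k) p[poff[l] + k * J + j] = cnt[j] / s;
    }
  }
  {
    std::vector<double> one(K, 1.0);
    for (int i = 0; i < N; ++i) rdirichlet_vec(one.data(), &q[i * K], K);
  }

  const int n_rec = iters / record_interval;
  NumericVector loglik_trace(n_rec), alpha_trace(n_rec), lambda_trace(n_rec);
  NumericMatrix Qmean(N, K);
  std::vector<double> Pmean(P_SZ, 0.0);
  NumericVector q_draws(store_q_draws ? n_rec * N * K : 0);
  double lambda_sum = 0.0;
  int rec = 0;
  long f_acc = 0, f_try = 0, a_acc = 0, a_try = 0;

  int Jmax = K;
  for (int l = 0; l < L; ++l) if (n_alleles[l] > Jmax) Jmax = n_alleles[l];
  // scratch buffers reused across sweeps (hot loops must not allocate)
  std::vector<double> w(K), sa(Jmax), sb(Jmax), sc(Jmax), sd(Jmax), se(Jmax);

  for (int step = 0; step < burnin + iters; ++step) {
    // --- 1. latent origins z, accumulated as counts ---
    std::fill(nik.begin(), nik.end(), 0.0);
    std::fill(cklj.begin(), cklj.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      const double* qi = &q[i * K];
      for (int l = 0; l < L; ++l) {
        const int J = n_alleles[l];
        const double* pl = &p[poff[l]];
        for (int c = 0; c < 2; ++c) {
          const int a = codes(i, 2 * l + c);
          if (a < 0) continue;
          double s = 0.0;
          for (int k = 0; k < K; ++k) { w[k] = qi[k] * pl[k * J + a]; s += w[k]; }
          double u = unif_rand() * s;
          int k = 0;
          for (; k < K - 1; ++k) { u -= w[k]; if (u <= 0.0) break; }
          nik[i * K + k] += 1.0;
          cklj[poff[l] + k * J + a] += 1.0;
        }
      }
    }
    // --- 2. ancestry proportions q_i ---
    for (int i = 0; i < N; ++i) {
      for (int k = 0; k < K; ++k) sa[k] = alpha + nik[i * K + k];
      rdirichlet_vec(sa.data(), &q[i * K], K);
    }
    // --- 3. allele frequencies p_kl ---
    for (int l = 0; l < L; ++l) {
      const int J = n_alleles[l];
      for (int k = 0; k < K; ++k) {
        double r = correlated ? (1.0 - Fk[k]) / Fk[k] : 0.0;
        for (int j = 0; j < J; ++j) {
          double prior = correlated ? std::max(pi[pioff[l] + j] * r, 1e-6)
                                    : cur_lambda;
          sa[j] = prior + cklj[poff[l] + k * J + j];
        }
        rdirichlet_vec(sa.data(), &p[poff[l] + k * J], J);
      }
    }
    // --- 4. F-model hyperparameters (Metropolis) ---
    if (correlated) {
      for (int k = 0; k < K; ++k) {
        double f0 = Fk[k];
        double lo = std::log(f0 / (1.0 - f0)) + norm_rand() * f_propsd;
        double f1 = 1.0 / (1.0 + std::exp(-lo));
        if (f1 <= 1e-6 || f1 >= 1.0 - 1e-6) continue;
        double r0 = (1.0 - f0) / f0, r1 = (1.0 - f1) / f1;
        // uniform(0,1) prior; Jacobian of the logit walk; F_k only enters
        // through its own population's frequencies
        double lr2 = std::log(f1 * (1.0 - f1)) - std::log(f0 * (1.0 - f0));
        for (int l = 0; l < L; ++l) {
          const int J = n_alleles[l];
          for (int j = 0; j < J; ++j) {
            double pj = std::max(pi[pioff[l] + j], 1e-6);
            sa[j] = pj * r0; sb[j] = pj * r1;
          }
          lr2 += log_dirichlet(&p[poff[l] + k * J], sb.data(), J) -
                 log_dirichlet(&p[poff[l] + k * J], sa.data(), J);
        }
        ++f_try;
        if (std::log(unif_rand()) < lr2) { Fk[k] = f1; ++f_acc; }
      }
      // ancestral frequencies pi_l (Dirichlet random-walk proposal)
      for (int l = 0; l < L; ++l) {
        const int J = n_alleles[l];
        double* cur = sa.data(); double* prop = sb.data();
        double* acur = sc.data(); double* aprop = sd.data();
        for (int j = 0; j < J; ++j) {
          cur[j] = std::max(pi[pioff[l] + j], 1e-6);
          acur[j] = pi_prop_conc * cur[j] + 0.1;
        }
        rdirichlet_vec(acur, prop, J);
        for (int j = 0; j < J; ++j) {
          prop[j] = std::max(prop[j], 1e-6);
          aprop[j] = pi_prop_conc * prop[j] + 0.1;
        }
        std::fill(se.begin(), se.begin() + J, cur_lambda);
        double lr = log_dirichlet(prop, se.data(), J) -
                    log_dirichlet(cur, se.data(), J);
        for (int k = 0; k < K; ++k) {
          double r = (1.0 - Fk[k]) / Fk[k];
          double l1k = 0.0, l0k = 0.0;
          {
            // Dirichlet(cur*r) vs Dirichlet(prop*r) density of p_kl
            double s0 = 0.0, s1 = 0.0;
            const double* pk = &p[poff[l] + k * J];
            for (int j = 0; j < J; ++j) {
              double lp = std::log(std::max(pk[j], 1e-300));
              s0 += cur[j] * r; s1 += prop[j] * r;
              l0k += (cur[j] * r - 1.0) * lp - R::lgammafn(cur[j] * r);
              l1k += (prop[j] * r - 1.0) * lp - R::lgammafn(prop[j] * r);
            }
            l0k += R::lgammafn(s0); l1k += R::lgammafn(s1);
          }
          lr += l1k - l0k;
        }
        // proposal asymmetry
        lr += log_dirichlet(cur, aprop, J) -
              log_dirichlet(prop, acur, J);
        if (std::log(unif_rand()) < lr)
          for (int j = 0; j < J; ++j) pi[pioff[l] + j] = prop[j];
      }
    }
    // --- 5. alpha (Metropolis, uniform prior on (0, alpha_max]) ---
    if (K > 1 && alpha_propsd > 0.0) {
      double a1 = alpha + norm_rand() * alpha_propsd;
      ++a_try;
      if (a1 > 0.0 && a1 <= alpha_max) {
        double lr = N * (R::lgammafn(K * a1) - K * R::lgammafn(a1) -
                         R::lgammafn(K * alpha) + K * R::lgammafn(alpha));
        double slq = 0.0;
        for (int i = 0; i < N; ++i)
          for (int k = 0; k < K; ++k)
            slq += std::log(std::max(q[i * K + k], 1e-300));
        lr += (a1 - alpha) * slq;
        if (std::log(unif_rand()) < lr) { alpha = a1; ++a_acc; }
      }
    }
    // --- 6. lambda (Metropolis, uniform prior on (0, 10]) ---
    if (estimate_lambda) {
      double l1 = cur_lambda + norm_rand() * 0.05;
      if (l1 > 0.0 && l1 <= 10.0) {
        double lr = 0.0;
        if (correlated) {
          // lambda is the prior concentration of the ancestral frequencies
          for (int l = 0; l < L; ++l) {
            const int J = n_alleles[l];
            std::fill(sa.begin(), sa.begin() + J, cur_lambda);
            std::fill(sb.begin(), sb.begin() + J, l1);
            lr += log_dirichlet(&pi[pioff[l]], sb.data(), J) -
                  log_dirichlet(&pi[pioff[l]], sa.data(), J);
          }
        } else {
          for (int l = 0; l < L; ++l) {
            const int J = n_alleles[l];
            std::fill(sa.begin(), sa.begin() + J, cur_lambda);
            std::fill(sb.begin(), sb.begin() + J, l1);
            for (int k = 0; k < K; ++k)
              lr += log_dirichlet(&p[poff[l] + k * J], sb.data(), J) -
                    log_dirichlet(&p[poff[l] + k * J], sa.data(), J);
          }
        }
        if (std::log(unif_rand()) < lr) cur_lambda = l1;
      }
    }
    // --- record ---
    if (step >= burnin && (step - burnin) % record_interval == 0 &&
        rec < n_rec) {
      double ll = 0.0;
      for (int i = 0; i < N; ++i) {
        const double* qi = &q[i * K];
        for (int l = 0; l < L; ++l) {
          const int J = n_alleles[l];
          const double* pl = &p[poff[l]];
          for (int c = 0; c < 2; ++c) {
            const int a = codes(i, 2 * l + c);
            if (a < 0) continue;
            double s = 0.0;
            for (int k = 0; k < K; ++k) s += qi[k] * pl[k * J + a];
            ll += std::log(std::max(s, 1e-300));
          }
        }
      }
      loglik_trace[rec] = ll;
      alpha_trace[rec] = alpha;
      lambda_trace[rec] = cur_lambda;
      lambda_sum += cur_lambda;
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k) {
          Qmean(i, k) += q[i * K + k];
          if (store_q_draws)
            q_draws[(R_xlen_t)rec * N * K + i * K + k] = q[i * K + k];
        }
      for (int t = 0; t < P_SZ; ++t) Pmean[t] += p[t];
      ++rec;
    }
  }

  const double denom = rec > 0 ? (double)rec : 1.0;
  for (int i = 0; i < N; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) { Qmean(i, k) /= denom; s += Qmean(i, k); }
    for (int k = 0; k < K; ++k) Qmean(i, k) /= s;
  }
  List Pout(L);
  for (int l = 0; l < L; ++l) {
    const int J = n_alleles[l];
    NumericMatrix pm(K, J);
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < J; ++j) { pm(k, j) = Pmean[poff[l] + k * J + j] / denom; s += pm(k, j); }
      for (int j = 0; j < J; ++j) pm(k, j) /= s;
    }
    Pout[l] = pm;
  }

  List out = List::create(
      _["Q"] = Qmean, _["P"] = Pout,
      _["loglik_trace"] = loglik_trace,
      _["alpha_trace"] = alpha_trace,
      _["lambda_trace"] = lambda_trace,
      _["lambda_mean"] = lambda_sum / denom,
      _["F"] = NumericVector(Fk.begin(), Fk.end()),
      _["accept_alpha"] = a_try ? (double)a_acc / a_try : NA_REAL,
      _["accept_F"] = f_try ? (double)f_acc / f_try : NA_REAL);
  if (store_q_draws) {
    // filled with k fastest, then i, then recorded step -> dim c(K, N, rec)
    q_draws.attr("dim") = IntegerVector::create(K, N, n_rec);
    out["q_draws"] = q_draws;
  }
  return out;
}

// [[Rcpp::export(name = ".loglik_cpp")]]
double loglik_cpp(IntegerMatrix codes, IntegerVector n_alleles,
                  NumericMatrix Q, List P) {
  const int N = codes.nrow(), L = n_alleles.size(), K = Q.ncol();
  double ll = 0.0;
  for (int l = 0; l < L; ++l) {
    NumericMatrix pm = P[l];
    if (pm.nrow() != K) stop("P[[l]] must have K rows");
    for (int i = 0; i < N; ++i)
      for (int c = 0; c < 2; ++c) {
        int a = codes(i, 2 * l + c);
        if (a < 0) continue;
        double s = 0.0;
        for (int k = 0; k < K; ++k) s += Q(i, k) * pm(k, a);
        if (s <= 0.0) stop("observed allele has zero mixture probability");
        ll += std::log(s);
      }
  }
  return ll;
}
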