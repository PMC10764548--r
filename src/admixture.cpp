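#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gibbs sampler for the no-linkage admixture model with independent allele
// frequencies: latent origins Z per allele copy, population frequencies P
// with Dirichlet(lambda) prior, individual admixture proportions Q with
// symmetric Dirichlet(alpha) prior (alpha optionally sampled by a
// Metropolis step on log alpha). Uses R's RNG (seed with set.seed()).

static int sample_cat(const double *w, int K) {
  double tot = 0.0;
  for (int k = 0; k < K; ++k) tot += w[k];
  double u = unif_rand() * tot, acc = 0.0;
  for (int k = 0; k < K; ++k) {
    acc += w[k];
    if (u <= acc) return k;
  }
  return K - 1;
}

static void rdirichlet(const double *shape, double *out, int n) {
  double tot = 0.0;
  for (int i = 0; i < n; ++i) {
    out[i] = R::rgamma(shape[i], 1.0);
    tot += out[i];
  }
  if (tot <= 0.0) {
    for (int i = 0; i < n; ++i) out[i] = 1.0 / n;
  } else {
    for (int i = 0; i < n; ++i) out[i] /= tot;
  }
}

// [[Rcpp::export(name = ".admixture_gibbs_cpp")]]
List admixture_gibbs_cpp(IntegerMatrix A1, IntegerMatrix A2,
                         IntegerVector n_alleles, int K, int sweeps,
                         int burn_in, double alpha, double lambda,
                         bool infer_alpha) {
  const int n = A1.nrow(), L = A1.ncol();
  const int Amax = max(n_alleles);
  RNGScope scope;

  // P[k][l*Amax + a], Q[i*K + k], Z[copy][i*L + l]
  std::vector<double> P((size_t)K * L * Amax, 0.0);
  std::vector<double> Q((size_t)n * K, 1.0 / K);
  std::vector<int> Z1((size_t)n * L), Z2((size_t)n * L);
  for (size_t t = 0; t < Z1.size(); ++t) {
    Z1[t] = (int)(unif_rand() * K) % K;
    Z2[t] = (int)(unif_rand() * K) % K;
  }

  std::vector<double> cntP((size_t)K * Amax);
  std::vector<double> cntQ(K), w(K), shape(Amax);
  std::vector<double> Qsum((size_t)n * K, 0.0), Psum((size_t)K * L * Amax, 0.0);
  double lnL_sum = 0.0;
  std::vector<double> lnL_trace;
  lnL_trace.reserve(sweeps);
  int kept = 0;

  for (int sw = 0; sw < burn_in + sweeps; ++sw) {
    // update P | Z
    for (int l = 0; l < L; ++l) {
      const int A = n_alleles[l];
      std::fill(cntP.begin(), cntP.end(), 0.0);
      for (int i = 0; i < n; ++i) {
        const int a1 = A1(i, l), a2 = A2(i, l);
        if (a1 >= 0) cntP[(size_t)Z1[(size_t)i * L + l] * Amax + a1] += 1.0;
        if (a2 >= 0) cntP[(size_t)Z2[(size_t)i * L + l] * Amax + a2] += 1.0;
      }
      for (int k = 0; k < K; ++k) {
        for (int a = 0; a < A; ++a)
          shape[a] = lambda + cntP[(size_t)k * Amax + a];
        rdirichlet(shape.data(), &P[((size_t)k * L + l) * Amax], A);
      }
    }
    // update Q | Z
    for (int i = 0; i < n; ++i) {
      std::fill(cntQ.begin(), cntQ.end(), alpha);
      for (int l = 0; l < L; ++l) {
        if (A1(i, l) >= 0) cntQ[Z1[(size_t)i * L + l]] += 1.0;
        if (A2(i, l) >= 0) cntQ[Z2[(size_t)i * L + l]] += 1.0;
      }
      rdirichlet(cntQ.data(), &Q[(size_t)i * K], K);
    }
    // optional Metropolis step on the symmetric Dirichlet concentration
    if (infer_alpha && K > 1) {
      double sum_logQ = 0.0;
      for (size_t t = 0; t < Q.size(); ++t)
        sum_logQ += std::log(std::max(Q[t], 1e-300));
      double prop = alpha * std::exp(0.1 * norm_rand());
      if (prop > 1e-4 && prop < 10.0) {
        double cur_lp = n * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha)) +
                        (alpha - 1.0) * sum_logQ;
        double new_lp = n * (R::lgammafn(K * prop) - K * R::lgammafn(prop)) +
                        (prop - 1.0) * sum_logQ;
        // log-normal proposal: include the Jacobian (random walk on log alpha)
        if (std::log(unif_rand()) <
            new_lp - cur_lp + std::log(prop) - std::log(alpha))
          alpha = prop;
      }
    }
    // update Z | P, Q and accumulate the data log-likelihood
    double lnL = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        const int a1 = A1(i, l), a2 = A2(i, l);
        if (a1 >= 0) {
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            w[k] = Q[(size_t)i * K + k] * P[((size_t)k * L + l) * Amax + a1];
            tot += w[k];
          }
          Z1[(size_t)i * L + l] = sample_cat(w.data(), K);
          lnL += std::log(std::max(tot, 1e-300));
        }
        if (a2 >= 0) {
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            w[k] = Q[(size_t)i * K + k] * P[((size_t)k * L + l) * Amax + a2];
            tot += w[k];
          }
          Z2[(size_t)i * L + l] = sample_cat(w.data(), K);
          lnL += std::log(std::max(tot, 1e-300));
        }
      }
    }
    if (sw >= burn_in) {
      for (size_t t = 0; t < Q.size(); ++t) Qsum[t] += Q[t];
      for (size_t t = 0; t < P.size(); ++t) Psum[t] += P[t];
      lnL_sum += lnL;
      lnL_trace.push_back(lnL);
      ++kept;
    }
  }

  NumericMatrix Qmean(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k)
      Qmean(i, k) = Qsum[(size_t)i * K + k] / kept;
  List Pmean(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix M(K, n_alleles[l]);
    for (int k = 0; k < K; ++k)
      for (int a = 0; a < n_alleles[l]; ++a)
        M(k, a) = Psum[((size_t)k * L + l) * Amax + a] / kept;
    Pmean[l] = M;
  }
  return List::create(_["Q"] = Qmean, _["P"] = Pmean,
                      _["lnL"] = lnL_sum / kept,
                      _["lnL_trace"] = NumericVector(lnL_trace.begin(),
                                                     lnL_trace.end()),
                      _["alpha"] = alpha);
}
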