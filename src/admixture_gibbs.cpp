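#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the haploid admixture model on binary band profiles.
//
// Model: per individual x, ancestry q_x ~ Dirichlet(alpha * 1_K); per
// locus l a latent origin z_xl ~ Categorical(q_x); the band
// x_l ~ Bernoulli(p_{z,l}) with cluster band frequencies
// p_{k,l} ~ Beta(1,1). alpha is shared across clusters and updated by
// random-walk Metropolis on log(alpha) with a uniform prior on
// (0, alpha_max].
//
// Uses R's RNG throughout, so set.seed() on the R side makes runs
// reproducible.

// [[Rcpp::export]]
List gibbs_admixture_cpp(IntegerMatrix X, int K, int burn_in, int n_iter,
                         double alpha_init, bool update_alpha,
                         double alpha_step, double alpha_max, int thin) {
  const int n = X.nrow(), L = X.ncol();
  RNGScope scope;

  NumericMatrix Q(n, K), P(K, L);
  NumericMatrix Qsum(n, K), Psum(K, L);
  IntegerMatrix z(n, L);
  double alpha = alpha_init;
  double alpha_sum = 0.0;

  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Q(i, k) = 1.0 / K;
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) P(k, l) = R::rbeta(1.0, 1.0);

  const int total = burn_in + n_iter;
  std::vector<double> lnl_trace;
  lnl_trace.reserve(n_iter / thin + 2);

  std::vector<double> probs(K);
  // allele/cluster count accumulators
  IntegerMatrix a_cnt(K, L), b_cnt(K, L);
  NumericMatrix nz(n, K);

  for (int it = 1; it <= total; ++it) {
    std::fill(a_cnt.begin(), a_cnt.end(), 0);
    std::fill(b_cnt.begin(), b_cnt.end(), 0);
    std::fill(nz.begin(), nz.end(), 0.0);

    // z | Q, P
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        double tot = 0.0;
        const int xv = X(i, l);
        for (int k = 0; k < K; ++k) {
          double pr = Q(i, k) * (xv ? P(k, l) : 1.0 - P(k, l));
          probs[k] = pr;
          tot += pr;
        }
        double u = unif_rand() * tot, cum = 0.0;
        int zk = K - 1;
        for (int k = 0; k < K; ++k) {
          cum += probs[k];
          if (u <= cum) { zk = k; break; }
        }
        z(i, l) = zk;
        nz(i, zk) += 1.0;
        if (xv) a_cnt(zk, l) += 1; else b_cnt(zk, l) += 1;
      }
    }

    // P | z, X
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l)
        P(k, l) = R::rbeta(1.0 + a_cnt(k, l), 1.0 + b_cnt(k, l));

    // Q | z  (Dirichlet via gamma draws)
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha + nz(i, k), 1.0);
        if (g < 1e-300) g = 1e-300;
        Q(i, k) = g;
        s += g;
      }
      for (int k = 0; k < K; ++k) Q(i, k) /= s;
    }

    // alpha | Q  (RW Metropolis on log alpha)
    if (update_alpha && K > 1) {
      double la = std::log(alpha);
      double la_new = la + norm_rand() * alpha_step;
      double alpha_new = std::exp(la_new);
      if (alpha_new > 0.0 && alpha_new <= alpha_max) {
        double slq = 0.0;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k) slq += std::log(Q(i, k));
        auto lpost = [&](double a) {
          return n * (R::lgammafn(K * a) - K * R::lgammafn(a)) +
                 (a - 1.0) * slq;
        };
        // Jacobian of the log transform: + log(alpha)
        double lr = lpost(alpha_new) - lpost(alpha) + la_new - la;
        if (std::log(unif_rand()) < lr) alpha = alpha_new;
      }
    }

    if (it > burn_in) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l) Psum(k, l) += P(k, l);
      alpha_sum += alpha;
      if ((it - burn_in) % thin == 0) {
        double lnl = 0.0;
        for (int i = 0; i < n; ++i) {
          for (int l = 0; l < L; ++l) {
            double mix = 0.0;
            const int xv = X(i, l);
            for (int k = 0; k < K; ++k)
              mix += Q(i, k) * (xv ? P(k, l) : 1.0 - P(k, l));
            lnl += std::log(mix);
          }
        }
        lnl_trace.push_back(lnl);
      }
    }
  }

  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= n_iter;
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) Psum(k, l) /= n_iter;

  return List::create(_["Q"] = Qsum, _["P"] = Psum,
                      _["lnL_trace"] = NumericVector(lnl_trace.begin(),
                                                     lnl_trace.end()),
                      _["alpha"] = alpha_sum / n_iter);
}
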