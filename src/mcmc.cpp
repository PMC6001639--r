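// Metropolis-within-Gibbs kernel for the latent Gaussian NMA models.
//
// The latent state is the internal component vector alpha (diagonal prior
// precision: fixed-effect slots at a constant precision, random-effect
// components at mult / tau^2 or mult / kappa^2), plus log-sd updates for
// tau and kappa.  Scalar random-walk proposals with incremental
// linear-predictor updates; step sizes adapt toward ~35% acceptance
// during burn-in only, so detailed balance holds for the retained draws.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

inline double arm_loglik(int family, double y, double size, double scale2,
                         double eta) {
  switch (family) {
  case 0:  // binomial: y events out of size, logit link (constants dropped)
    return y * eta - size * std::log1p(std::exp(eta));
  case 1:  // normal arm mean with known variance scale2
    return -0.5 * (y - eta) * (y - eta) / scale2;
  default: // poisson with exposure `size`, log link (constants dropped)
    return y * eta - size * std::exp(eta);
  }
}

} // namespace

// [[Rcpp::export(name = ".mwg_sample")]]
List mwg_sample(int family, NumericVector y, NumericVector size,
                NumericVector scale2, NumericMatrix X,
                IntegerVector prec_class, NumericVector prec_mult,
                double fixed_prec,
                bool has_tau, double tau_lo, double tau_hi,
                bool has_kappa, double kappa_lo, double kappa_hi,
                int iterations, int burnin, int thin,
                NumericVector init_alpha, double init_tau,
                double init_kappa) {
  const int N = X.nrow(), P = X.ncol();
  if (iterations <= burnin) stop("iterations must exceed burnin");

  // sparse column structure of X
  std::vector<std::vector<int> > rows(P);
  std::vector<std::vector<double> > vals(P);
  for (int j = 0; j < P; ++j)
    for (int i = 0; i < N; ++i)
      if (X(i, j) != 0.0) {
        rows[j].push_back(i);
        vals[j].push_back(X(i, j));
      }

  std::vector<double> alpha(init_alpha.begin(), init_alpha.end());
  std::vector<double> eta(N, 0.0);
  for (int j = 0; j < P; ++j)
    for (size_t k = 0; k < rows[j].size(); ++k)
      eta[rows[j][k]] += vals[j][k] * alpha[j];

  double ltau = std::log(init_tau), lkap = std::log(init_kappa);

  const int n_blocks = P + (has_tau ? 1 : 0) + (has_kappa ? 1 : 0);
  std::vector<double> step(n_blocks, 0.4);
  std::vector<int> acc(n_blocks, 0), tries(n_blocks, 0);
  std::vector<long> acc_post(n_blocks, 0), tries_post(n_blocks, 0);

  const int n_keep = (iterations - burnin) / thin;
  const int n_par = P + (has_tau ? 1 : 0) + (has_kappa ? 1 : 0);
  NumericMatrix draws(n_keep, n_par);

  // current prior precision per component
  std::vector<double> prec(P);
  auto refresh_prec = [&]() {
    double t2 = std::exp(2 * ltau), k2 = std::exp(2 * lkap);
    for (int j = 0; j < P; ++j) {
      if (prec_class[j] == 0) prec[j] = fixed_prec;
      else if (prec_class[j] == 1) prec[j] = prec_mult[j] / t2;
      else prec[j] = prec_mult[j] / k2;
    }
  };
  refresh_prec();

  RNGScope scope;
  int kept = 0;
  for (int it = 0; it < iterations; ++it) {
    // latent scalars
    for (int j = 0; j < P; ++j) {
      double delta = step[j] * norm_rand();
      double dll = 0.0;
      const std::vector<int> &rj = rows[j];
      const std::vector<double> &vj = vals[j];
      for (size_t k = 0; k < rj.size(); ++k) {
        int i = rj[k];
        dll += arm_loglik(family, y[i], size[i], scale2[i],
                          eta[i] + vj[k] * delta) -
               arm_loglik(family, y[i], size[i], scale2[i], eta[i]);
      }
      double a = alpha[j];
      dll += -0.5 * prec[j] * ((a + delta) * (a + delta) - a * a);
      ++tries[j];
      if (std::log(unif_rand()) < dll) {
        alpha[j] = a + delta;
        for (size_t k = 0; k < rj.size(); ++k)
          eta[rj[k]] += vj[k] * delta;
        ++acc[j];
        if (it >= burnin) ++acc_post[j];
      }
      if (it >= burnin) ++tries_post[j];
    }

    // hyperparameters on the log-sd scale; uniform prior on the sd scale
    // contributes the Jacobian exp(lsd)
    auto update_hyper = [&](double &lsd, double lo, double hi, int cls,
                            int b) {
      double prop = lsd + step[b] * norm_rand();
      double sd_new = std::exp(prop);
      ++tries[b];
      if (it >= burnin) ++tries_post[b];
      if (sd_new < lo || sd_new > hi) return;
      double dlp = prop - lsd;  // Jacobian ratio
      double v_old = std::exp(2 * lsd), v_new = std::exp(2 * prop);
      for (int j = 0; j < P; ++j)
        if (prec_class[j] == cls) {
          double q_old = prec_mult[j] / v_old,
                 q_new = prec_mult[j] / v_new;
          dlp += 0.5 * std::log(q_new / q_old) -
                 0.5 * alpha[j] * alpha[j] * (q_new - q_old);
        }
      if (std::log(unif_rand()) < dlp) {
        lsd = prop;
        refresh_prec();
        ++acc[b];
        if (it >= burnin) ++acc_post[b];
      }
    };
    int b = P;
    if (has_tau) { update_hyper(ltau, tau_lo, tau_hi, 1, b); ++b; }
    if (has_kappa) { update_hyper(lkap, kappa_lo, kappa_hi, 2, b); ++b; }

    // step-size adaptation during burn-in only
    if (it < burnin && (it + 1) % 50 == 0) {
      for (int k = 0; k < n_blocks; ++k) {
        if (tries[k] > 0) {
          double rate = double(acc[k]) / tries[k];
          step[k] *= std::exp(rate - 0.35);
          if (step[k] < 1e-5) step[k] = 1e-5;
          if (step[k] > 50) step[k] = 50;
        }
        acc[k] = 0; tries[k] = 0;
      }
    }

    if (it >= burnin && (it - burnin) % thin == 0 && kept < n_keep) {
      for (int j = 0; j < P; ++j) draws(kept, j) = alpha[j];
      int c = P;
      if (has_tau) draws(kept, c++) = std::exp(ltau);
      if (has_kappa) draws(kept, c++) = std::exp(lkap);
      ++kept;
    }
  }

  NumericVector rate(n_blocks), steps(n_blocks);
  for (int k = 0; k < n_blocks; ++k) {
    rate[k] = tries_post[k] > 0 ?
      double(acc_post[k]) / tries_post[k] : NA_REAL;
    steps[k] = step[k];
  }
  return List::create(_["draws"] = draws, _["acceptance"] = rate,
                      _["steps"] = steps, _["kept"] = kept);
}
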