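#include <Rcpp.h>
using namespace Rcpp;

// Multinomial log-likelihood of one SNP's 9-cell paired genotype table
// under the additive-risk paired probability model. counts is length 9 in
// row-major (normal genotype i, tumor genotype j) order.
static double paired_ll(const double* n9, double R, double A, double M) {
  double g0 = (1.0 - A) * (1.0 - A), g1 = 2.0 * A * (1.0 - A), g2 = A * A;
  double t00 = (1.0 - M) * (1.0 - M), t01 = 2.0 * M * (1.0 - M), t02 = M * M;
  double t10 = M * (1.0 - M), t11 = M * M + (1.0 - M) * (1.0 - M);
  double r1 = (R + 1.0) / 2.0;
  double w[9] = {
    g0 * t00,        g0 * t01 * r1,  g0 * t02 * R,
    g1 * t10,        g1 * t11 * r1,  g1 * t10 * R,
    g2 * t02,        g2 * t01 * r1,  g2 * t00 * R
  };
  double q = 0.0;
  for (int k = 0; k < 9; ++k) q += w[k];
  double ll = 0.0;
  for (int k = 0; k < 9; ++k) {
    if (n9[k] > 0) {
      double p = w[k] / q;
      if (p <= 0) return R_NegInf;
      ll += n9[k] * std::log(p);
    }
  }
  return ll;
}

// Conditional log prior of one component of theta_j given H_j.
// prior row layout: k0, rate0, k1, rate1, aA0, bA0, aA1, bA1, aM0, bM0, aM1, bM1
static double lprior_R(const double* pr, int H, double R) {
  return H ? R::dgamma(R, pr[2], 1.0 / pr[3], 1)
           : R::dgamma(R, pr[0], 1.0 / pr[1], 1);
}
static double lprior_A(const double* pr, int H, double A) {
  return H ? R::dbeta(A, pr[6], pr[7], 1) : R::dbeta(A, pr[4], pr[5], 1);
}
static double lprior_M(const double* pr, int H, double M) {
  return H ? R::dbeta(M, pr[10], pr[11], 1) : R::dbeta(M, pr[8], pr[9], 1);
}

// One Gibbs-within-Metropolis chain for a SNP set.
// Schedule per iteration: MH on (log R_j, logit A_j, logit M_j) for every
// SNP, then Gibbs draws of H_j, G, b. Uses the R RNG, so set.seed() in R
// governs determinism.
// counts: 9 x J (one column per SNP); prior: 12 x J (one column per SNP) —
// columns are contiguous in memory.
// [[Rcpp::export]]
List mcmc_gene_cpp(NumericMatrix counts, NumericMatrix prior,
                   double p0, double p1, double alpha_b, double beta_b,
                   NumericVector initR, NumericVector initA,
                   NumericVector initM, IntegerVector initH,
                   int initG, double initb,
                   int n_iter, int n_burnin, int thin,
                   NumericVector scales) {
  int J = counts.ncol();
  std::vector<double> R(initR.begin(), initR.end());
  std::vector<double> A(initA.begin(), initA.end());
  std::vector<double> M(initM.begin(), initM.end());
  std::vector<int> H(initH.begin(), initH.end());
  int G = initG;
  double b = initb;

  std::vector<double> ll(J);
  for (int j = 0; j < J; ++j)
    ll[j] = paired_ll(&counts(0, j), R[j], A[j], M[j]);

  int n_keep = (n_iter - n_burnin) / thin;
  NumericMatrix drawsR(n_keep, J), drawsA(n_keep, J), drawsM(n_keep, J);
  IntegerMatrix drawsH(n_keep, J);
  IntegerVector drawsG(n_keep);
  NumericVector drawsb(n_keep);
  NumericMatrix acc(3, J);
  double lp0 = std::log(p0), l1p0 = std::log1p(-p0);
  double lp1 = std::log(p1), l1p1 = std::log1p(-p1);

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    for (int j = 0; j < J; ++j) {
      const double* n9 = &counts(0, j);
      const double* pr = &prior(0, j);
      // R_j on the log scale
      {
        double x = std::log(R[j]);
        double xp = x + scales[0] * norm_rand();
        double Rp = std::exp(xp);
        double llp = paired_ll(n9, Rp, A[j], M[j]);
        double num = llp + lprior_R(pr, H[j], Rp) + xp;
        double den = ll[j] + lprior_R(pr, H[j], R[j]) + x;
        if (R_FINITE(num) && std::log(unif_rand()) < num - den) {
          R[j] = Rp; ll[j] = llp; acc(0, j) += 1.0;
        }
      }
      // A_j on the logit scale
      {
        double y = std::log(A[j] / (1.0 - A[j]));
        double yp = y + scales[1] * norm_rand();
        double Ap = 1.0 / (1.0 + std::exp(-yp));
        if (Ap > 0.0 && Ap < 1.0) {
          double llp = paired_ll(n9, R[j], Ap, M[j]);
          double num = llp + lprior_A(pr, H[j], Ap) +
            std::log(Ap) + std::log1p(-Ap);
          double den = ll[j] + lprior_A(pr, H[j], A[j]) +
            std::log(A[j]) + std::log1p(-A[j]);
          if (R_FINITE(num) && std::log(unif_rand()) < num - den) {
            A[j] = Ap; ll[j] = llp; acc(1, j) += 1.0;
          }
        }
      }
      // M_j on the logit scale
      {
        double y = std::log(M[j] / (1.0 - M[j]));
        double yp = y + scales[2] * norm_rand();
        double Mp = 1.0 / (1.0 + std::exp(-yp));
        if (Mp > 0.0 && Mp < 1.0) {
          double llp = paired_ll(n9, R[j], A[j], Mp);
          double num = llp + lprior_M(pr, H[j], Mp) +
            std::log(Mp) + std::log1p(-Mp);
          double den = ll[j] + lprior_M(pr, H[j], M[j]) +
            std::log(M[j]) + std::log1p(-M[j]);
          if (R_FINITE(num) && std::log(unif_rand()) < num - den) {
            M[j] = Mp; ll[j] = llp; acc(2, j) += 1.0;
          }
        }
      }
      // Gibbs draw of H_j given theta_j and G
      {
        const double* prj = &prior(0, j);
        double lpg1 = G ? lp1 : lp0;
        double lpg0 = G ? l1p1 : l1p0;
        double l1 = lpg1 + lprior_R(prj, 1, R[j]) + lprior_A(prj, 1, A[j]) +
          lprior_M(prj, 1, M[j]);
        double l0 = lpg0 + lprior_R(prj, 0, R[j]) + lprior_A(prj, 0, A[j]) +
          lprior_M(prj, 0, M[j]);
        if (!R_FINITE(l1) && !R_FINITE(l0))
          stop("both association branches have zero prior density");
        double p = 1.0 / (1.0 + std::exp(l0 - l1));
        H[j] = (unif_rand() < p) ? 1 : 0;
      }
    }
    // Gibbs draw of G given H and b
    {
      double la = std::log(b), l0g = std::log1p(-b);
      for (int j = 0; j < J; ++j) {
        la += H[j] ? lp1 : l1p1;
        l0g += H[j] ? lp0 : l1p0;
      }
      double p = 1.0 / (1.0 + std::exp(l0g - la));
      G = (unif_rand() < p) ? 1 : 0;
    }
    // Gibbs draw of b given G (Beta conjugacy)
    b = R::rbeta(alpha_b + G, beta_b + 1 - G);

    if (it >= n_burnin && ((it - n_burnin) % thin == 0) && kept < n_keep) {
      for (int j = 0; j < J; ++j) {
        drawsR(kept, j) = R[j];
        drawsA(kept, j) = A[j];
        drawsM(kept, j) = M[j];
        drawsH(kept, j) = H[j];
      }
      drawsG[kept] = G;
      drawsb[kept] = b;
      ++kept;
    }
  }
  for (int j = 0; j < J; ++j)
    for (int k = 0; k < 3; ++k) acc(k, j) /= (double)n_iter;
  return List::create(_["R"] = drawsR, _["A"] = drawsA, _["M"] = drawsM,
                      _["H"] = drawsH, _["G"] = drawsG, _["b"] = drawsb,
                      _["accept"] = acc);
}
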