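# Independent oracles used across tests.

# Brute-force posterior P(H = 1) for a single-SNP set by quadrature:
# marginal likelihood per association branch via a quantile-midpoint rule
# under the branch priors (K points per parameter), combined over the
# discrete (H, G) grid with the b hyperprior integrated on a quantile grid.
oracle_posterior_H <- function(counts, priors, K = 20, Kb = 10) {
  qs <- (seq_len(K) - 0.5) / K
  marglik <- function(H) {
    p <- priors$params[, 1]
    Rg <- if (H) qgamma(qs, p["k1"], rate = p["rate1"]) else
      qgamma(qs, p["k0"], rate = p["rate0"])
    Ag <- if (H) qbeta(qs, p["aA1"], p["bA1"]) else qbeta(qs, p["aA0"], p["bA0"])
    Mg <- if (H) qbeta(qs, p["aM1"], p["bM1"]) else qbeta(qs, p["aM0"], p["bM0"])
    ll <- numeric(K^3)
    idx <- 1
    for (i in seq_len(K)) for (j in seq_len(K)) for (k in seq_len(K)) {
      ll[idx] <- paired_loglik(Rg[i], Ag[j], Mg[k], counts)
      idx <- idx + 1
    }
    m <- max(ll)
    log(mean(exp(ll - m))) + m
  }
  l1 <- marglik(1)
  l0 <- marglik(0)
  bg <- qbeta((seq_len(Kb) - 0.5) / Kb, priors$alpha_b, priors$beta_b)
  pg1 <- mean(bg)  # P(G = 1) integrating the b hyperprior
  s <- exp(l1 - l0)
  num <- s * (priors$p1 * pg1 + priors$p0 * (1 - pg1))
  den <- num + (1 - priors$p1) * pg1 + (1 - priors$p0) * (1 - pg1)
  num / den
}

# Bisection root of f(x) = target on (0, 1), for cross-checking the
# closed-form enrichment solvers.
bisect01 <- function(f, target, tol = 1e-12) {
  lo <- 1e-12; hi <- 1 - 1e-12
  flo <- f(lo) - target; fhi <- f(hi) - target
  if (flo * fhi > 0) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if ((f(mid) - target) * flo <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Random interior model parameters for property sweeps.
random_params <- function(n) {
  tibble::tibble(
    R = exp(runif(n, log(0.3), log(5))),
    A = runif(n, 0.02, 0.98),
    M = runif(n, 0.001, 0.6)
  )
}
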