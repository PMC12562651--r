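# Hierarchical Bayesian SNP-set model: priors, joint density, MCMC.

test_that("gene priors anchor at the observed and enrichment-corrected values", {
  set.seed(31)
  gene <- simulate_gene(n_snps = 3, n = 3000, R = 3, A = 0.2, M = 0.005)
  pr <- build_gene_priors(gene)
  p <- pr$params
  # neutral branch Beta means sit at the observed values
  expect_equal(as.numeric(p["aA0", ] / (p["aA0", ] + p["bA0", ])),
               as.numeric(pr$a_hat), tolerance = 1e-10)
  expect_equal(as.numeric(p["aM0", ] / (p["aM0", ] + p["bM0", ])),
               as.numeric(pr$m_hat), tolerance = 1e-10)
  # neutral relative-risk prior has mean one
  expect_equal(as.numeric(p["k0", 1] / p["rate0", 1]), 1)
  # associated branch: R prior mean anchored at the MLE average
  expect_equal(as.numeric(p["k1", 1] / p["rate1", 1]), pr$r_mean1)
  expect_gte(pr$r_mean1, 1.1)
  # associated-branch A mean solves the enrichment fixed point
  a1 <- as.numeric(p["aA1", 1] / (p["aA1", 1] + p["bA1", 1]))
  expect_lt(abs(expected_allele_freq(pr$r_mean1, a1, pr$m_hat[1]) -
                  pr$a_hat[1]), 1e-6)
})

test_that("the prior mean floor engages on null-looking genes", {
  set.seed(32)
  gene <- simulate_gene(n_snps = 4, n = 3000, R = 1, A = 0.2, M = 0.005)
  pr <- build_gene_priors(gene, prior_config(anchor = "moment"))
  expect_equal(pr$r_mean1, 1.1)
})

test_that("log joint matches independently computed density terms", {
  set.seed(33)
  gene <- simulate_gene(n_snps = 2, n = 500, R = 2, A = 0.3, M = 0.01)
  pr <- build_gene_priors(gene)
  p <- pr$params
  R <- c(1.5, 0.9); A <- c(0.28, 0.33); M <- c(0.012, 0.008)
  H <- c(1L, 0L); G <- 1L; b <- 0.3
  manual <- sum(vapply(1:2, function(j) {
    paired_loglik(R[j], A[j], M[j], gene[j, ]) +
      (if (H[j]) dgamma(R[j], p["k1", j], rate = p["rate1", j], log = TRUE) +
         dbeta(A[j], p["aA1", j], p["bA1", j], log = TRUE) +
         dbeta(M[j], p["aM1", j], p["bM1", j], log = TRUE)
       else dgamma(R[j], p["k0", j], rate = p["rate0", j], log = TRUE) +
         dbeta(A[j], p["aA0", j], p["bA0", j], log = TRUE) +
         dbeta(M[j], p["aM0", j], p["bM0", j], log = TRUE)) +
      H[j] * log(pr$p1) + (1 - H[j]) * log(1 - pr$p1)
  }, numeric(1))) + log(b) + dbeta(b, pr$alpha_b, pr$beta_b, log = TRUE)
  expect_equal(log_joint(R, A, M, H, G, b, gene, pr), manual,
               tolerance = 1e-10)
  # separability: changing only b shifts only the G and b terms
  delta <- log_joint(R, A, M, H, G, 0.6, gene, pr) -
    log_joint(R, A, M, H, G, b, gene, pr)
  expect_equal(delta,
               (log(0.6) + dbeta(0.6, pr$alpha_b, pr$beta_b, log = TRUE)) -
                 (log(b) + dbeta(b, pr$alpha_b, pr$beta_b, log = TRUE)),
               tolerance = 1e-10)
  expect_identical(log_joint(R, A, M, H, G, 1.5, gene, pr), -Inf)
})

test_that("the G conditional from the joint matches the closed-form odds", {
  set.seed(34)
  gene <- simulate_gene(n_snps = 4, n = 200, R = 1, A = 0.2, M = 0.01)
  pr <- build_gene_priors(gene)
  R <- rep(1.2, 4); A <- rep(0.2, 4); M <- rep(0.01, 4)
  H <- rep(1L, 4); b <- 0.2
  l1 <- log_joint(R, A, M, H, 1L, b, gene, pr)
  l0 <- log_joint(R, A, M, H, 0L, b, gene, pr)
  pG <- 1 / (1 + exp(l0 - l1))
  # all four SNPs flagged: odds = b/(1-b) * (p1/p0)^4 = 0.25 * 6561
  expect_equal(pG, 1640.25 / 1641.25, tolerance = 1e-10)
})

test_that("the H conditional from the joint matches the branch-density ratio", {
  set.seed(35)
  gene <- simulate_gene(n_snps = 1, n = 300, R = 2, A = 0.25, M = 0.01)
  pr <- build_gene_priors(gene)
  p <- pr$params
  R <- 1.8; A <- 0.22; M <- 0.012; G <- 0L; b <- 0.15
  l1 <- log_joint(R, A, M, 1L, G, b, gene, pr)
  l0 <- log_joint(R, A, M, 0L, G, b, gene, pr)
  lr <- dgamma(R, p["k1", 1], rate = p["rate1", 1], log = TRUE) -
    dgamma(R, p["k0", 1], rate = p["rate0", 1], log = TRUE) +
    dbeta(A, p["aA1", 1], p["bA1", 1], log = TRUE) -
    dbeta(A, p["aA0", 1], p["bA0", 1], log = TRUE) +
    dbeta(M, p["aM1", 1], p["bM1", 1], log = TRUE) -
    dbeta(M, p["aM0", 1], p["bM0", 1], log = TRUE) +
    log(pr$p0) - log(1 - pr$p0)
  expect_equal(l1 - l0, lr, tolerance = 1e-10)
})

test_that("MCMC is deterministic given the seed and accepts everything for tiny proposals", {
  set.seed(36)
  gene <- simulate_gene(n_snps = 2, n = 500, R = 2, A = 0.2, M = 0.01)
  cfg <- mcmc_config(n_iter = 600, n_burnin = 100, thin = 2, n_restarts = 2)
  set.seed(99); f1 <- fit_bayes(gene, mcmc = cfg)
  set.seed(99); f2 <- fit_bayes(gene, mcmc = cfg)
  expect_identical(f1$draws, f2$draws)
  set.seed(100)
  tiny <- fit_bayes(gene, mcmc = mcmc_config(n_iter = 500, n_burnin = 100,
                                             thin = 1, n_restarts = 1,
                                             proposal_scale = 1e-7))
  expect_true(all(tiny$accept > 0.99))
})

test_that("single-marker posterior P(H=1) matches the quadrature oracle", {
  set.seed(37)
  for (rep in 1:3) {
    g <- simulate_gene(n_snps = 1, n = 50, R = 2, A = 0.3, M = 0.05)
    pr <- build_gene_priors(g)
    po <- oracle_posterior_H(g, pr)
    # long pooled chains keep the Monte Carlo error well inside the bound
    fit <- fit_bayes(g, priors = pr,
                     mcmc = mcmc_config(n_iter = 20000, n_burnin = 2000,
                                        thin = 5, n_restarts = 2))
    expect_lt(abs(fit$snp$H_mean - po), 0.05)
  }
})

test_that("posterior summaries follow the draw medians and means", {
  set.seed(38)
  gene <- simulate_gene(n_snps = 2, n = 3000, R = 3, A = 0.2, M = 0.005)
  fit <- fit_bayes(gene)
  expect_equal(fit$snp$H_mean, colMeans(fit$draws$H))
  expect_equal(fit$snp$R_median, apply(fit$draws$R, 2, median))
  expect_equal(fit$set$G_mean, mean(fit$draws$G))
  expect_true(all(fit$snp$H_mean >= 0 & fit$snp$H_mean <= 1))
  expect_equal(fit$snp$H_median,
               as.integer(apply(fit$draws$H, 2, median) > 0.5))
  td <- tidy(fit)
  expect_identical(td, fit$snp)
  gl <- glance(fit)
  expect_equal(gl$n_snps, 2)
})

test_that("set-level evidence grows with the number of associated SNPs", {
  set.seed(39)
  mean_G <- vapply(c(1, 2, 4), function(J) {
    mean(replicate(12, {
      g <- simulate_gene(n_snps = J, n = 1000, R = 3, A = 0.2, M = 0.005)
      fit_bayes(g, mcmc = mcmc_config(n_iter = 2000, n_burnin = 500,
                                      thin = 2, n_restarts = 2))$set$G_mean
    }))
  }, numeric(1))
  expect_true(mean_G[3] >= mean_G[1])
})

test_that("fitting many sets splits and labels results per set", {
  set.seed(40)
  d <- dplyr::bind_rows(
    simulate_gene(2, 500, 1, 0.2, 0.01, gene_id = "gA"),
    simulate_gene(2, 500, 1, 0.2, 0.01, gene_id = "gB")
  )
  res <- fit_bayes_sets(d, mcmc = mcmc_config(n_iter = 600, n_burnin = 200,
                                              thin = 2, n_restarts = 1))
  expect_equal(nrow(res$snp), 4)
  expect_setequal(unique(res$set$gene_id), c("gA", "gB"))
})
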