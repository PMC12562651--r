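# Hierarchical Bayesian model for a SNP set (gene or gene segment).
#
# Latent structure: G in {0,1} is the set-level association status with
# prior P(G=1) = b, b ~ Beta(alpha_b, beta_b); H_j in {0,1} is the per-SNP
# status with P(H_j=1 | G) = p1^G p0^(1-G); given H_j, the SNP parameters
# (R_j, A_j, M_j) get spike/slab-style Gamma and Beta priors anchored at
# the empirical estimates (H_j = 0) or their enrichment-corrected versions
# (H_j = 1). Inference is Gibbs-within-Metropolis MCMC.

#' Hyperparameter configuration of the hierarchical model
#'
#' @param alpha_b,beta_b Beta hyperprior of the set-level prior probability
#'   `b`; the default `(1, 4)` has mean 0.2, encoding that only a small
#'   fraction of genes is expected to be associated.
#' @param p0,p1 `P(H_j = 1 | G = 0)` and `P(H_j = 1 | G = 1)`.
#' @param r_shape0,r_rate0 Gamma prior of `R_j` for a neutral SNP; the
#'   default `(3, 3)` has mean 1.
#' @param r_shape1 Gamma shape of `R_j` for an associated SNP; its rate is
#'   set to `r_shape1 / mean` so the prior mean equals the average of the
#'   per-SNP relative-risk estimates (floored at `r_mean_floor`), unless
#'   `r_rate1` is given explicitly.
#' @param r_rate1 Optional fixed Gamma rate for the associated-SNP `R`
#'   prior, overriding the data-anchored mean.
#' @param r_mean_floor Lower bound for the anchored prior mean of `R` under
#'   association.
#' @param kappa Concentration of the Beta priors on `A_j` and `M_j`
#'   (shapes `mean * kappa` and `(1 - mean) * kappa`).
#' @param anchor `"mle"` anchors the associated-SNP prior means at the
#'   penalized MLE average; `"moment"` uses the observed frequencies with
#'   `R` from the MLE-free moment start (faster, less calibrated).
#' @return List of class `prior_config`.
#' @export
prior_config <- function(alpha_b = 1, beta_b = 4, p0 = 0.1, p1 = 0.9,
                         r_shape0 = 3, r_rate0 = 3, r_shape1 = 3,
                         r_rate1 = NULL, r_mean_floor = 1.1, kappa = 50,
                         anchor = c("mle", "moment")) {
  stopifnot(alpha_b > 0, beta_b > 0, p0 > 0, p1 < 1, p0 < p1,
            r_shape0 > 0, r_rate0 > 0, r_shape1 > 0, kappa > 0)
  structure(list(alpha_b = alpha_b, beta_b = beta_b, p0 = p0, p1 = p1,
                 r_shape0 = r_shape0, r_rate0 = r_rate0,
                 r_shape1 = r_shape1, r_rate1 = r_rate1,
                 r_mean_floor = r_mean_floor, kappa = kappa,
                 anchor = match.arg(anchor)),
            class = "prior_config")
}

#' MCMC schedule configuration
#'
#' @param n_iter Iterations per restart.
#' @param n_burnin Burn-in iterations discarded per restart.
#' @param thin Thinning interval for stored draws.
#' @param n_restarts Independent restarts; post-burn-in draws are pooled.
#' @param proposal_scale Random-walk standard deviations on the
#'   transformed scale for `(log R, logit A, logit M)`; recycled to
#'   length 3.
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 6000, n_burnin = 1000, thin = 5,
                        n_restarts = 3, proposal_scale = 0.3) {
  stopifnot(n_iter > n_burnin, thin >= 1, n_restarts >= 1)
  structure(list(n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 n_restarts = as.integer(n_restarts),
                 proposal_scale = rep_len(proposal_scale, 3)),
            class = "mcmc_config")
}

beta_shapes <- function(mean, kappa) c(mean * kappa, (1 - mean) * kappa)

#' Build the per-SNP prior specification for a SNP set
#'
#' For every SNP: the neutral (`H = 0`) priors are `Gamma(r_shape0,
#' r_rate0)` on `R` (mean 1) and Beta priors on `A` and `M` with means at
#' the observed allele frequency and mutation rate; the associated
#' (`H = 1`) priors put the `R` mean at the average of the per-SNP
#' relative-risk estimates (floored) and the `A`/`M` means at the
#' enrichment-corrected values from [solve_enriched_af()] and
#' [solve_enriched_mr()].
#'
#' @param data Tibble with one row per SNP carrying the count columns.
#' @param config A [prior_config()].
#' @return List with `params` (12 x J matrix of Gamma/Beta parameters),
#'   the hyperparameters, and per-SNP anchor estimates.
#' @export
build_gene_priors <- function(data, config = prior_config()) {
  stopifnot(is.data.frame(data), all(COUNT_COLS %in% names(data)))
  J <- nrow(data)
  cts <- lapply(seq_len(J), function(j) as_paired_counts(data[j, ]))
  N <- vapply(cts, sum, numeric(1))
  clip <- function(x, n) pmin(pmax(x, 1 / (2 * n)), 1 - 1 / (2 * n))
  a_hat <- vapply(seq_len(J),
                  function(j) clip(observed_allele_freq(cts[[j]]), N[j]),
                  numeric(1))
  m_hat <- vapply(seq_len(J),
                  function(j) clip(observed_mutation_rate(cts[[j]]), N[j]),
                  numeric(1))
  r_hat <- if (config$anchor == "mle") {
    vapply(cts, function(ct) paired_mle(ct)$R, numeric(1))
  } else {
    rep(1, J)
  }
  r_mean1 <- max(mean(r_hat), config$r_mean_floor)
  r_rate1 <- if (is.null(config$r_rate1)) config$r_shape1 / r_mean1 else
    config$r_rate1

  params <- matrix(0, nrow = 12, ncol = J)
  rownames(params) <- c("k0", "rate0", "k1", "rate1", "aA0", "bA0", "aA1",
                        "bA1", "aM0", "bM0", "aM1", "bM1")
  for (j in seq_len(J)) {
    a1 <- clip(solve_enriched_af(a_hat[j], r_mean1, m_hat[j]), N[j])
    m1 <- clip(solve_enriched_mr(m_hat[j], r_mean1, a_hat[j]), N[j])
    params[, j] <- c(config$r_shape0, config$r_rate0,
                     config$r_shape1, r_rate1,
                     beta_shapes(a_hat[j], config$kappa),
                     beta_shapes(a1, config$kappa),
                     beta_shapes(m_hat[j], config$kappa),
                     beta_shapes(m1, config$kappa))
  }
  list(params = params, alpha_b = config$alpha_b, beta_b = config$beta_b,
       p0 = config$p0, p1 = config$p1, a_hat = a_hat, m_hat = m_hat,
       r_hat = r_hat, r_mean1 = r_mean1, n = N)
}

# Log density of one component's conditional prior given H.
lprior_component <- function(priors, j, which, value, H) {
  p <- priors$params[, j]
  switch(which,
    R = if (H) stats::dgamma(value, p["k1"], rate = p["rate1"], log = TRUE)
        else stats::dgamma(value, p["k0"], rate = p["rate0"], log = TRUE),
    A = if (H) stats::dbeta(value, p["aA1"], p["bA1"], log = TRUE)
        else stats::dbeta(value, p["aA0"], p["bA0"], log = TRUE),
    M = if (H) stats::dbeta(value, p["aM1"], p["bM1"], log = TRUE)
        else stats::dbeta(value, p["aM0"], p["bM0"], log = TRUE)
  )
}

#' Log joint density of the hierarchical model
#'
#' Sum of the per-SNP multinomial log-likelihood, the conditional Gamma /
#' Beta log-priors of `(R_j, A_j, M_j)` given `H_j`, the Bernoulli terms
#' of `H_j` given `G` and of `G` given `b`, and the Beta hyperprior of
#' `b`. Returns `-Inf` outside the domain.
#'
#' @param R,A,M Numeric vectors of length `J`.
#' @param H Integer vector of per-SNP indicators in `{0, 1}`.
#' @param G Set-level indicator in `{0, 1}`.
#' @param b Prior association probability in `(0, 1)`.
#' @param data Counts tibble, one row per SNP.
#' @param priors Output of [build_gene_priors()].
#' @return Scalar log joint density (unnormalized posterior).
#' @export
log_joint <- function(R, A, M, H, G, b, data, priors) {
  J <- nrow(data)
  stopifnot(length(R) == J, length(H) == J, G %in% 0:1, all(H %in% 0:1))
  if (b <= 0 || b >= 1 || any(R <= 0) || any(A <= 0) || any(A >= 1) ||
      any(M <= 0) || any(M >= 1)) {
    return(-Inf)
  }
  ll <- 0
  for (j in seq_len(J)) {
    ll <- ll + paired_loglik(R[j], A[j], M[j], data[j, ]) +
      lprior_component(priors, j, "R", R[j], H[j]) +
      lprior_component(priors, j, "A", A[j], H[j]) +
      lprior_component(priors, j, "M", M[j], H[j])
    pG <- if (G == 1) priors$p1 else priors$p0
    ll <- ll + H[j] * log(pG) + (1 - H[j]) * log(1 - pG)
  }
  ll + G * log(b) + (1 - G) * log(1 - b) +
    stats::dbeta(b, priors$alpha_b, priors$beta_b, log = TRUE)
}

#' Fit the hierarchical Bayesian model to one SNP set
#'
#' Runs Gibbs-within-Metropolis MCMC: component-wise Gaussian random-walk
#' Metropolis updates of `(log R_j, logit A_j, logit M_j)` and conjugate /
#' discrete Gibbs draws of `H_j`, `G` and `b`. The first restart starts at
#' the null-anchored moment estimates (`R = 1`, observed `A` and `M`,
#' `H = 0`, `G = 0`, `b` at its prior mean); further restarts start from
#' prior draws. Post-burn-in thinned draws are pooled across restarts.
#' With a single row this is the single-marker model.
#'
#' @param data Tibble with one row per SNP of the set, carrying the nine
#'   count columns (see [count_cols()]); an optional `snp_id` column names
#'   the SNPs.
#' @param priors A [prior_config()], or a prebuilt [build_gene_priors()]
#'   list.
#' @param mcmc An [mcmc_config()].
#' @return Object of class `paired_bayes` with elements `snp` (per-SNP
#'   posterior summaries: `H_mean`, `H_median`, `R_median`, `A_median`,
#'   `M_median`), `set` (posterior `G_mean`, `G_median`, `b_mean`),
#'   `draws` (pooled draws), `accept` (MH acceptance rates), `priors` and
#'   `mcmc`.
#' @export
#' @examples
#' set.seed(1)
#' gene <- simulate_gene(n_snps = 4, n = 3000, R = 3, A = 0.2, M = 0.005)
#' fit <- fit_bayes(gene, mcmc = mcmc_config(n_iter = 1500, n_burnin = 500))
#' tidy(fit)
#' glance(fit)
fit_bayes <- function(data, priors = prior_config(), mcmc = mcmc_config()) {
  stopifnot(is.data.frame(data), nrow(data) >= 1,
            all(COUNT_COLS %in% names(data)))
  if (inherits(priors, "prior_config")) priors <- build_gene_priors(data, priors)
  J <- nrow(data)
  counts <- vapply(seq_len(J), function(j) as_paired_counts(data[j, ]),
                   numeric(9))   # 9 x J
  pm <- priors$params
  b_mean <- priors$alpha_b / (priors$alpha_b + priors$beta_b)

  draws <- vector("list", mcmc$n_restarts)
  accept <- matrix(0, 3, J)
  for (r in seq_len(mcmc$n_restarts)) {
    if (r == 1) {
      init <- list(R = rep(1, J), A = priors$a_hat, M = priors$m_hat,
                   H = rep(0L, J), G = 0L, b = b_mean)
    } else {
      G0 <- stats::rbinom(1, 1, b_mean)
      pG <- if (G0 == 1) priors$p1 else priors$p0
      H0 <- stats::rbinom(J, 1, pG)
      k <- function(row) ifelse(H0 == 1, pm[row[2], ], pm[row[1], ])
      init <- list(
        R = stats::rgamma(J, k(c("k0", "k1")), rate = k(c("rate0", "rate1"))),
        A = stats::rbeta(J, k(c("aA0", "aA1")), k(c("bA0", "bA1"))),
        M = stats::rbeta(J, k(c("aM0", "aM1")), k(c("bM0", "bM1"))),
        H = as.integer(H0), G = as.integer(G0),
        b = stats::rbeta(1, priors$alpha_b, priors$beta_b)
      )
      eps <- 1e-9
      init$A <- pmin(pmax(init$A, eps), 1 - eps)
      init$M <- pmin(pmax(init$M, eps), 1 - eps)
      init$R <- pmax(init$R, eps)
    }
    ch <- mcmc_gene_cpp(counts, pm, priors$p0, priors$p1, priors$alpha_b,
                        priors$beta_b, init$R, init$A, init$M, init$H,
                        init$G, init$b, mcmc$n_iter, mcmc$n_burnin,
                        mcmc$thin, mcmc$proposal_scale)
    draws[[r]] <- ch
    accept <- accept + ch$accept / mcmc$n_restarts
  }
  pool <- function(name) do.call(rbind, lapply(draws, `[[`, name))
  R_d <- pool("R"); A_d <- pool("A"); M_d <- pool("M"); H_d <- pool("H")
  G_d <- unlist(lapply(draws, `[[`, "G"))
  b_d <- unlist(lapply(draws, `[[`, "b"))

  snp_id <- if ("snp_id" %in% names(data)) data$snp_id else
    paste0("snp", seq_len(J))
  snp <- tibble::tibble(
    snp_id = snp_id,
    H_mean = colMeans(H_d),
    H_median = as.integer(apply(H_d, 2, stats::median) > 0.5),
    R_median = apply(R_d, 2, stats::median),
    A_median = apply(A_d, 2, stats::median),
    M_median = apply(M_d, 2, stats::median)
  )
  set <- tibble::tibble(G_mean = mean(G_d),
                        G_median = as.integer(stats::median(G_d) > 0.5),
                        b_mean = mean(b_d))
  structure(list(snp = snp, set = set,
                 draws = list(R = R_d, A = A_d, M = M_d, H = H_d,
                              G = G_d, b = b_d),
                 accept = accept, priors = priors, mcmc = mcmc),
            class = "paired_bayes")
}

#' Fit the hierarchical model to many SNP sets
#'
#' Splits `data` by a grouping column (gene or segment identifier) and
#' fits [fit_bayes()] to each set.
#'
#' @param data Counts tibble with a set-identifier column.
#' @param set Name of the grouping column (default `"gene_id"`).
#' @inheritParams fit_bayes
#' @return List with `snp` (per-SNP summaries with the set id) and `set`
#'   (per-set posterior summaries) tibbles, plus the list of fits.
#' @export
fit_bayes_sets <- function(data, set = "gene_id", priors = prior_config(),
                           mcmc = mcmc_config()) {
  stopifnot(set %in% names(data))
  groups <- split(tibble::as_tibble(data), data[[set]])
  fits <- purrr::map(groups, fit_bayes, priors = priors, mcmc = mcmc)
  snp <- purrr::imap(fits, function(f, id) {
    dplyr::mutate(f$snp, "{set}" := id, .before = 1)
  }) |> dplyr::bind_rows()
  sets <- purrr::imap(fits, function(f, id) {
    dplyr::mutate(f$set, "{set}" := id, .before = 1)
  }) |> dplyr::bind_rows()
  list(snp = snp, set = sets, fits = fits)
}

#' @export
print.paired_bayes <- function(x, ...) {
  cat("Hierarchical Bayesian SNP-set fit (", nrow(x$snp), "SNPs,",
      nrow(x$draws$R), "pooled draws )\n")
  cat(sprintf("  P(G = 1 | data) = %.3f   E(b | data) = %.3f\n",
              x$set$G_mean, x$set$b_mean))
  print(x$snp, ...)
  invisible(x)
}
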